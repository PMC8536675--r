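#' Guide design parameters
#'
#' Controls PAM scanning and spacer extraction. The Cas12a PAM is `TTTV`
#' (V = A, C or G) 5' of the protospacer; the seed region is the
#' PAM-proximal stretch of the spacer (positions 1-5 by default, counting
#' the base next to the PAM as position 1), where mismatches are least
#' tolerated.
#'
#' @param pam IUPAC PAM pattern (default `"TTTV"`; `"TTTN"` is a common
#'   relaxed alternative).
#' @param spacer_len Spacer length in nt (18-24; default 21).
#' @param seed_window Integer vector of 1-based spacer positions forming the
#'   seed region (default `1:5`).
#' @param scan_both_strands Scan the reverse strand too (default `TRUE`).
#' @return List of class `design_params`.
#' @export
design_params <- function(pam = "TTTV", spacer_len = 21L,
                          seed_window = 1:5, scan_both_strands = TRUE) {
  pam <- validate_seq(pam, allow_gap = FALSE, what = "pam pattern")
  spacer_len <- as.integer(spacer_len)
  seed_window <- as.integer(seed_window)
  stopifnot(spacer_len >= 18L, spacer_len <= 24L,
            all(seed_window >= 1L), max(seed_window) <= spacer_len)
  structure(list(pam = pam, spacer_len = spacer_len,
                 seed_window = seed_window,
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "design_params")
}

#' Scan a sequence for PAM sites with room for a full spacer
#'
#' Reports every position (on both strands unless disabled) where the PAM
#' pattern matches under IUPAC set-intersection semantics and a full-length
#' spacer fits immediately 3' of the PAM on that strand. Minus-strand hits
#' are reported in plus-strand coordinates (`start` = leftmost base of the
#' PAM on the plus strand) with the PAM string as read 5'->3' on the minus
#' strand.
#'
#' @param seq Ungapped nucleotide string.
#' @param params A [design_params()] object.
#' @return Tibble with columns `strand`, `start` (0-based), `pam`.
#' @examples
#' scan_pams(paste0("TTTA", strrep("C", 25)))
#' @export
scan_pams <- function(seq, params = design_params()) {
  seq <- validate_seq(seq, allow_gap = FALSE, what = "sequence")
  plen <- nchar(params$pam)
  slen <- params$spacer_len
  L <- nchar(seq)
  empty <- tibble::tibble(strand = character(), start = integer(), pam = character())
  if (L < plen + slen) {
    warning("sequence shorter than PAM + spacer; no sites possible")
    return(empty)
  }
  pat <- seq_bits(params$pam)
  scan_one <- function(bits) {
    n_win <- L - plen - slen + 1L
    if (n_win < 1L) return(integer(0))
    hits <- integer(0)
    for (i in seq_len(n_win)) {
      if (all(bits_match(bits[i:(i + plen - 1L)], pat))) hits <- c(hits, i - 1L)
    }
    hits
  }
  bits_f <- seq_bits(seq)
  out <- list()
  hf <- scan_one(bits_f)
  if (length(hf)) {
    out[[1]] <- tibble::tibble(
      strand = "+", start = hf,
      pam = substring(seq, hf + 1L, hf + plen))
  }
  if (params$scan_both_strands) {
    rc <- revcomp(seq)
    hr <- scan_one(seq_bits(rc))
    if (length(hr)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        strand = "-", start = L - hr - plen,
        pam = substring(rc, hr + 1L, hr + plen))
    }
  }
  if (!length(out)) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$strand)
}

# ungapped plus-strand residue positions of PAM and spacer, in strand order
# (5'->3' on the designated strand, PAM-proximal spacer base first)
.window_positions <- function(hit_strand, hit_start, plen, slen) {
  if (hit_strand == "+") {
    list(pam = hit_start:(hit_start + plen - 1L),
         spacer = (hit_start + plen):(hit_start + plen + slen - 1L))
  } else {
    list(pam = (hit_start + plen - 1L):hit_start,
         spacer = (hit_start - 1L):(hit_start - slen))
  }
}

#' Enumerate candidate guides on the target species of an alignment
#'
#' Scans the (ungapped) target sequence for PAM+spacer windows and records
#' each candidate with its spacer (PAM-proximal base first, so spacer
#' position 1 is seed position 1) and the alignment columns it occupies.
#' Windows interrupted by an alignment gap in the target row are excluded;
#' when the target species has several rows, windows at which the rows
#' disagree are excluded.
#'
#' @param msa A `barcode_msa` ([star_msa()] or [as_barcode_msa()]).
#' @param params A [design_params()] object.
#' @param target Target species label (defaults to the alignment's
#'   `target_species` attribute).
#' @return Tibble of class `guide_candidates`: `guide_id`, `target_species`,
#'   `strand`, `pam_start` (0-based ungapped), `pam_seq`, `spacer_seq`,
#'   `win_start`/`win_end` (0-based half-open ungapped window on the plus
#'   strand), and list-columns `pam_cols`, `spacer_cols` (0-based alignment
#'   columns in strand order).
#' @export
enumerate_candidates <- function(msa, params = design_params(), target = NULL) {
  target <- target %||% attr(msa, "target_species")
  if (is.null(target)) stop("no target species given")
  t_rows <- which(msa$species == target)
  if (!length(t_rows)) stop("target species '", target, "' not in alignment")
  first_id <- msa$id[t_rows[1]]
  seq <- gsub("-", "", msa$aligned[t_rows[1]], fixed = TRUE)
  hits <- scan_pams(seq, params)
  plen <- nchar(params$pam)
  slen <- params$spacer_len
  other_bits <- lapply(t_rows[-1], function(r) seq_bits(msa$aligned[r]))
  cand <- list()
  for (h in seq_len(nrow(hits))) {
    w <- .window_positions(hits$strand[h], hits$start[h], plen, slen)
    all_pos <- c(w$pam, w$spacer)
    cols <- msa_project(msa, first_id, all_pos)
    span <- range(cols)
    if (span[2] - span[1] + 1L != length(cols)) next  # gap inside window
    # additional target rows must agree over the window
    if (length(other_bits)) {
      ref_bits <- seq_bits(msa$aligned[t_rows[1]])[cols + 1L]
      ok <- all(vapply(other_bits, function(b) {
        all(b[cols + 1L] != 0L) && all(bits_match(b[cols + 1L], ref_bits))
      }, logical(1)))
      if (!ok) next
    }
    win_start <- min(all_pos)
    win_end <- max(all_pos) + 1L
    spacer_plus <- substring(seq, min(w$spacer) + 1L, max(w$spacer) + 1L)
    spacer_seq <- if (hits$strand[h] == "+") spacer_plus else revcomp(spacer_plus)
    cand[[length(cand) + 1L]] <- tibble::tibble(
      guide_id = sprintf("g%s%03d", ifelse(hits$strand[h] == "+", "p", "m"),
                         hits$start[h]),
      target_species = target,
      strand = hits$strand[h],
      pam_start = hits$start[h],
      pam_seq = hits$pam[h],
      spacer_seq = spacer_seq,
      win_start = win_start,
      win_end = win_end,
      pam_cols = list(cols[seq_len(plen)]),
      spacer_cols = list(cols[plen + seq_len(slen)])
    )
  }
  out <- if (length(cand)) dplyr::bind_rows(cand) else tibble::tibble(
    guide_id = character(), target_species = character(), strand = character(),
    pam_start = integer(), pam_seq = character(), spacer_seq = character(),
    win_start = integer(), win_end = integer(),
    pam_cols = list(), spacer_cols = list())
  class(out) <- c("guide_candidates", class(out))
  out
}

# complement of an IUPAC bitmask (A<->T, C<->G bit swap); gap stays gap
.COMP_BITS <- vapply(0:15, function(b) {
  bitwOr(bitwOr(if (bitwAnd(b, 1L)) 8L else 0L, if (bitwAnd(b, 2L)) 4L else 0L),
         bitwOr(if (bitwAnd(b, 4L)) 2L else 0L, if (bitwAnd(b, 8L)) 1L else 0L))
}, integer(1))

#' Assess candidate guides against every other species
#'
#' For each candidate and each non-target species (several records of one
#' species are collapsed to a column-wise IUPAC consensus first), classifies
#' the PAM window as `canonical` (matches the PAM pattern), `absent` (an
#' alignment gap falls in the PAM window) or `variant`, and counts spacer
#' mismatches under set-intersection semantics. Mismatches at seed positions
#' count as `seed_mismatches`, the rest as `distal_mismatches`; alignment
#' gaps inside the window are counted in `gap_positions` and a gapped spacer
#' position also counts as a mismatch there.
#'
#' @param msa A `barcode_msa` containing the candidate's columns.
#' @param candidates Output of [enumerate_candidates()] (or a subset).
#' @param params The [design_params()] used for design.
#' @return Tibble: `guide_id`, `species`, `pam_status`, `pam_obs`,
#'   `seed_mismatches`, `distal_mismatches`, `gap_positions`,
#'   `spacer_identical`.
#' @export
assess_candidates <- function(msa, candidates, params = design_params()) {
  target <- candidates$target_species[1] %||% attr(msa, "target_species")
  species <- setdiff(unique(msa$species), target)
  if (!length(species)) stop("alignment has no non-target species")
  cons <- lapply(species, function(sp) .species_consensus_bits(msa, sp))
  names(cons) <- species
  pat <- seq_bits(params$pam)
  seed <- params$seed_window
  res <- list()
  for (i in seq_len(nrow(candidates))) {
    minus <- candidates$strand[i] == "-"
    pam_cols <- candidates$pam_cols[[i]]
    sp_cols <- candidates$spacer_cols[[i]]
    spacer_bits <- seq_bits(candidates$spacer_seq[i])
    for (sp in species) {
      b <- cons[[sp]]
      pam_obs_bits <- b[pam_cols + 1L]
      sp_obs_bits <- b[sp_cols + 1L]
      if (minus) {
        pam_obs_bits <- .COMP_BITS[pam_obs_bits + 1L]
        sp_obs_bits <- .COMP_BITS[sp_obs_bits + 1L]
      }
      pam_status <- if (any(pam_obs_bits == 0L)) "absent"
        else if (all(bits_match(pam_obs_bits, pat))) "canonical"
        else "variant"
      sp_gap <- sp_obs_bits == 0L
      mm <- sp_gap | !bits_match(sp_obs_bits, spacer_bits)
      pos <- seq_along(mm)  # spacer position, PAM-proximal = 1
      seed_mm <- sum(mm[pos %in% seed])
      distal_mm <- sum(mm[!(pos %in% seed)])
      res[[length(res) + 1L]] <- tibble::tibble(
        guide_id = candidates$guide_id[i],
        species = sp,
        pam_status = pam_status,
        pam_obs = bits_to_seq(pam_obs_bits),
        seed_mismatches = as.integer(seed_mm),
        distal_mismatches = as.integer(distal_mm),
        gap_positions = as.integer(sum(pam_obs_bits == 0L) + sum(sp_gap)),
        spacer_identical = seed_mm == 0L && distal_mm == 0L && !any(sp_gap))
    }
  }
  dplyr::bind_rows(res)
}

#' Default T7 promoter and LbCas12a direct-repeat scaffold
#'
#' Editable defaults for [build_construct()]; the direct repeat is the
#' constant crRNA scaffold that Cas12a recognises (sometimes loosely called
#' the tracrRNA part of the guide, although Cas12a needs no separate
#' tracrRNA).
#' @export
construct_defaults <- function() {
  list(t7 = "TAATACGACTCACTATAG",
       scaffold = "AATTTCTACTAAGTGTAGAT")
}

#' Build the crRNA and its IVT dsDNA template for a candidate
#'
#' The in-vitro-transcription template has three parts: T7 promoter,
#' direct-repeat scaffold, and the spacer. The crRNA is the scaffold plus
#' spacer rendered as RNA (T -> U).
#'
#' @param candidate One row of [enumerate_candidates()] output (or any list
#'   with a `spacer_seq`), or a spacer string.
#' @param t7 T7 promoter DNA.
#' @param scaffold Direct-repeat scaffold DNA.
#' @return List with `crRNA`, `top` (template top strand) and `bottom`
#'   (reverse complement of `top`).
#' @export
build_construct <- function(candidate,
                            t7 = construct_defaults()$t7,
                            scaffold = construct_defaults()$scaffold) {
  spacer <- if (is.character(candidate)) candidate else candidate$spacer_seq
  spacer <- validate_seq(spacer[[1]], allow_gap = FALSE, what = "spacer")
  if (is.null(scaffold) || !nzchar(scaffold)) stop("empty scaffold sequence")
  t7 <- validate_seq(t7, allow_gap = FALSE, what = "T7 promoter")
  scaffold <- validate_seq(scaffold, allow_gap = FALSE, what = "scaffold")
  top <- paste0(t7, scaffold, spacer)
  list(crRNA = chartr("T", "U", paste0(scaffold, spacer)),
       top = top,
       bottom = revcomp(top))
}
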
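#' Specification for a synthetic barcode panel
#'
#' Describes a panel of homologous barcode loci: one random target sequence
#' with a planted PAM+spacer window, and off-target species derived from it
#' by controlled edits placed in named zones of that window (`"pam"`,
#' `"seed"`, `"distal"`) or anywhere else (`"neutral"`), plus uniform
#' background divergence outside the window. Because every edit is placed
#' deliberately, the generator knows the exact per-species assessment it
#' implies and returns it as ground truth — the construction is its own
#' oracle.
#'
#' @param seed RNG seed; the same spec and seed give a bit-identical panel.
#' @param n_species Number of species (target is `species1`).
#' @param locus_len Locus length in nt (default 400, a typical short plant
#'   barcode such as trnL).
#' @param guide_pos 0-based plus-strand position of the planted PAM's
#'   leftmost base.
#' @param guide_strand `"+"` or `"-"`.
#' @param offtarget_edits Named list (by species) of data frames with
#'   columns `zone` (`pam`/`seed`/`distal`/`neutral`), `offset` (1-based
#'   position within the zone: PAM position, spacer position counted
#'   PAM-proximal-first, or an absolute 0-based position for `neutral`),
#'   and optional `new` (replacement base, or `"-"` for a gap; `NA` picks
#'   an appropriate base: one violating the PAM pattern in the `pam` zone,
#'   any differing base elsewhere).
#' @param background_divergence Per-site substitution probability outside
#'   the guide window (default 0.02, of the order of intra-genus barcode
#'   divergence).
#' @param indels Allow background indels (default `FALSE`; off so that
#'   window assessments are exactly checkable without alignment
#'   ambiguity).
#' @param params A [design_params()] object fixing PAM pattern, spacer
#'   length and seed window.
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(seed = 1L, n_species = 4L, locus_len = 400L,
                       guide_pos = 150L, guide_strand = "+",
                       offtarget_edits = list(),
                       background_divergence = 0.02, indels = FALSE,
                       params = design_params()) {
  stopifnot(n_species >= 2L, guide_strand %in% c("+", "-"))
  plen <- nchar(params$pam)
  slen <- params$spacer_len
  win <- if (guide_strand == "+") c(guide_pos, guide_pos + plen + slen)
         else c(guide_pos - slen, guide_pos + plen)
  if (win[1] < 0L || win[2] > locus_len) stop("guide window out of bounds")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 locus_len = as.integer(locus_len),
                 guide_pos = as.integer(guide_pos),
                 guide_strand = guide_strand,
                 offtarget_edits = offtarget_edits,
                 background_divergence = background_divergence,
                 indels = isTRUE(indels), params = params,
                 win_start = win[1], win_end = win[2]),
            class = "panel_spec")
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# plus-strand 0-based position of a zone offset
.edit_position <- function(spec, zone, offset) {
  plen <- nchar(spec$params$pam)
  gp <- spec$guide_pos
  if (zone == "neutral") return(as.integer(offset))
  if (spec$guide_strand == "+") {
    switch(zone,
           pam = gp + offset - 1L,
           seed = ,
           distal = gp + plen + offset - 1L)
  } else {
    switch(zone,
           pam = gp + plen - offset,
           seed = ,
           distal = gp - offset)
  }
}

# Make the planted window exclusive: remove every pattern-compatible PAM
# frame (either strand) whose PAM+spacer window overlaps the planted one,
# except the planted frame itself. Without this, a frame overlapping the
# planted window shares its discriminating edits and can compete with it.
# Each offending frame is broken by substituting one PAM base outside the
# planted PAM; repeat until no such frame remains.
.scrub_overlapping_frames <- function(chars, spec) {
  p <- spec$params
  plen <- nchar(p$pam)
  slen <- p$spacer_len
  L <- length(chars)
  pat <- strsplit(p$pam, "", fixed = TRUE)[[1]]
  rc_pat <- strsplit(revcomp(p$pam), "", fixed = TRUE)[[1]]
  sets <- Biostrings::IUPAC_CODE_MAP
  in_set <- function(base, code) grepl(base, sets[[code]], fixed = TRUE)
  planted_pam <- spec$guide_pos:(spec$guide_pos + plen - 1L)
  break_frame <- function(chars, frame_start, pattern_chars) {
    for (k in seq_len(plen)) {
      pos <- frame_start + k - 1L
      if (pos %in% planted_pam) next
      forbidden <- setdiff(c("C", "G", "A", "T"),
                           strsplit(sets[[pattern_chars[k]]], "", fixed = TRUE)[[1]])
      chars[pos + 1L] <- forbidden[1]
      return(chars)
    }
    chars
  }
  for (iter in 1:100) {
    changed <- FALSE
    for (fs in 0:(L - plen)) {
      if (fs == spec$guide_pos) next  # the planted frame, either strand
      win <- chars[(fs + 1L):(fs + plen)]
      # plus-strand frame: spacer 3' of the PAM
      if (fs + plen + slen <= L &&
          all(mapply(in_set, win, pat)) &&
          max(spec$win_start, fs) < min(spec$win_end, fs + plen + slen)) {
        chars <- break_frame(chars, fs, pat)
        changed <- TRUE
        next
      }
      # minus-strand frame: plus-strand window matches the pattern's
      # reverse complement, spacer to the left
      if (fs - slen >= 0L &&
          all(mapply(in_set, win, rc_pat)) &&
          max(spec$win_start, fs - slen) < min(spec$win_end, fs + plen)) {
        chars <- break_frame(chars, fs, rc_pat)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  chars
}

# a concrete base violating the PAM pattern at 1-based PAM position k,
# as read on the designated strand
.pam_breaking_base <- function(pattern, k) {
  allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[substring(pattern, k, k)]],
                      "", fixed = TRUE)[[1]]
  forbidden <- setdiff(c("A", "C", "G", "T"), allowed)
  forbidden[1]
}

#' Generate a synthetic barcode panel with planted ground truth
#'
#' @param spec A [panel_spec()].
#' @return List with `panel` (a [barcode_panel()], gap-free sequences),
#'   `msa` (the true alignment as a `barcode_msa`; identical to the
#'   sequences unless gap edits were specified), and `truth`: the planted
#'   guide (`strand`, `pam_start`, `win_start`, `win_end`) and
#'   `expected` — a tibble of the per-species seed/distal mismatch counts,
#'   PAM status and gap counts the edits imply.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  p <- spec$params
  plen <- nchar(p$pam)
  slen <- p$spacer_len
  .with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    tgt <- sample(bases, spec$locus_len, replace = TRUE)
    # plant a concrete PAM instance (first base of each IUPAC set)
    pam_concrete <- vapply(seq_len(plen), function(k) {
      strsplit(Biostrings::IUPAC_CODE_MAP[[substring(p$pam, k, k)]],
               "", fixed = TRUE)[[1]][1]
    }, character(1))
    pam_plus <- if (spec$guide_strand == "+") pam_concrete
                else rev(chartr("ACGT", "TGCA", pam_concrete))
    tgt[(spec$guide_pos + 1L):(spec$guide_pos + plen)] <- pam_plus
    tgt <- .scrub_overlapping_frames(tgt, spec)
    species <- paste0("species", seq_len(spec$n_species))
    rows <- list(tgt)
    expected <- list()
    for (s in species[-1]) {
      row <- tgt
      edits <- spec$offtarget_edits[[s]]
      seed_mm <- 0L; distal_mm <- 0L; pam_sub <- 0L; pam_gap <- 0L; sp_gap <- 0L
      used_pos <- integer(0)
      if (!is.null(edits) && nrow(edits)) {
        for (e in seq_len(nrow(edits))) {
          zone <- edits$zone[e]
          pos <- .edit_position(spec, zone, edits$offset[e])
          if (pos %in% used_pos) stop("contradictory edits at position ", pos,
                                      " for ", s)
          used_pos <- c(used_pos, pos)
          new <- if (!is.null(edits$new) && !is.na(edits$new[e])) edits$new[e]
                 else NA_character_
          if (is.na(new)) {
            new <- if (zone == "pam") {
              b <- .pam_breaking_base(p$pam, edits$offset[e])
              # translate to the plus strand for a minus-strand guide
              if (spec$guide_strand == "-") chartr("ACGT", "TGCA", b) else b
            } else {
              sample(setdiff(bases, row[pos + 1L]), 1L)
            }
          } else if (new != "-" && zone == "pam" && spec$guide_strand == "-") {
            new <- chartr("ACGT", "TGCA", new)
          }
          row[pos + 1L] <- new
          if (zone == "pam") {
            if (new == "-") pam_gap <- pam_gap + 1L else pam_sub <- pam_sub + 1L
          } else if (zone == "seed") {
            seed_mm <- seed_mm + 1L
            if (new == "-") sp_gap <- sp_gap + 1L
          } else if (zone == "distal") {
            distal_mm <- distal_mm + 1L
            if (new == "-") sp_gap <- sp_gap + 1L
          }
        }
      }
      if (spec$background_divergence > 0) {
        outside <- setdiff(seq_len(spec$locus_len) - 1L,
                           spec$win_start:(spec$win_end - 1L))
        hit <- outside[stats::runif(length(outside)) < spec$background_divergence]
        for (pos in hit) {
          if (pos %in% used_pos) next
          row[pos + 1L] <- sample(setdiff(bases, row[pos + 1L]), 1L)
        }
      }
      rows[[length(rows) + 1L]] <- row
      expected[[length(expected) + 1L]] <- tibble::tibble(
        species = s,
        pam_status = if (pam_gap > 0L) "absent"
                     else if (pam_sub > 0L) "variant" else "canonical",
        seed_mismatches = seed_mm, distal_mismatches = distal_mm,
        gap_positions = pam_gap + sp_gap,
        spacer_identical = seed_mm == 0L && distal_mm == 0L && sp_gap == 0L)
    }
    aligned <- vapply(rows, paste, character(1), collapse = "")
    recs <- tibble::tibble(id = species, species = species,
                           seq = gsub("-", "", aligned, fixed = TRUE))
    msa <- as_barcode_msa(
      tibble::tibble(id = species, species = species, aligned = aligned),
      target_species = species[1])
    truth <- list(
      guide = tibble::tibble(strand = spec$guide_strand,
                             pam_start = spec$guide_pos,
                             win_start = spec$win_start,
                             win_end = spec$win_end),
      expected = dplyr::bind_rows(expected))
    list(panel = barcode_panel(recs, target_species = species[1]),
         msa = msa, truth = truth)
  })
}
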
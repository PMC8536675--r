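#' Alignment scoring parameters
#'
#' Linear gap penalty scoring for global (Needleman-Wunsch) alignment and
#' the center-star multiple alignment built on it.
#'
#' @param match Score for a matching pair (IUPAC set-intersection match).
#' @param mismatch Score for a mismatching pair; must be below `match`.
#' @param gap Per-position gap score; must be negative.
#' @return List of class `aln_params`.
#' @export
aln_params <- function(match = 1, mismatch = -1, gap = -2) {
  stopifnot(match > mismatch, gap < 0)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "aln_params")
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with a linear gap penalty and deterministic traceback
#' (ties resolved diagonal first, then gap-in-`b`, then gap-in-`a`).
#' Empty sequences are allowed and align against all-gaps.
#'
#' @param a,b Ungapped nucleotide strings.
#' @param params An [aln_params()] object.
#' @return List with elements `score`, `a` (gapped `a`), `b` (gapped `b`).
#' @examples
#' nw_align("ACGT", "AGT")
#' @export
nw_align <- function(a, b, params = aln_params()) {
  a <- if (nzchar(a)) validate_seq(a, allow_gap = FALSE, what = "a") else ""
  b <- if (nzchar(b)) validate_seq(b, allow_gap = FALSE, what = "b") else ""
  nw_align_cpp(a, b, params$match, params$mismatch, params$gap)
}

new_barcode_msa <- function(rows, target = NULL) {
  widths <- nchar(rows$aligned)
  if (length(unique(widths)) > 1L) stop("aligned rows have unequal widths")
  structure(tibble::as_tibble(rows[c("id", "species", "aligned")]),
            ncol = unname(widths[1]),
            target_species = target,
            class = c("barcode_msa", class(tibble::tibble())))
}

#' Treat pre-aligned (gapped) records as a multiple alignment
#'
#' Bypass for users who align with an external tool (MAFFT, MultAlin, ...)
#' and load the gapped FASTA via [read_barcode_fasta()].
#'
#' @param records Data frame with `id`, `species` and gapped sequences in a
#'   `seq` or `aligned` column; all rows must have equal width.
#' @param target_species Optional target label to carry along.
#' @return A `barcode_msa` tibble (`id`, `species`, `aligned`) with
#'   attribute `ncol`.
#' @export
as_barcode_msa <- function(records, target_species = NULL) {
  stopifnot(is.data.frame(records))
  aligned <- if ("aligned" %in% names(records)) records$aligned else records$seq
  rows <- tibble::tibble(id = records$id, species = records$species,
                         aligned = toupper(aligned))
  tgt <- target_species %||% attr(records, "target_species")
  new_barcode_msa(rows, target = tgt)
}

#' @export
print.barcode_msa <- function(x, ...) {
  cat("<barcode_msa> ", nrow(x), " rows x ", attr(x, "ncol"), " columns",
      if (!is.null(attr(x, "target_species")))
        paste0("; target: ", attr(x, "target_species")) else "", "\n", sep = "")
  NextMethod()
}

# merge a new pairwise alignment of the center into the running master
# gapping, honouring "once a gap, always a gap"
.merge_star <- function(master, rows, center_gapped, other_gapped) {
  mi <- strsplit(master, "", fixed = TRUE)[[1]]
  cg <- strsplit(center_gapped, "", fixed = TRUE)[[1]]
  og <- strsplit(other_gapped, "", fixed = TRUE)[[1]]
  out_master <- character(0)
  out_new <- character(0)
  keep <- integer(0)   # for existing rows: index into old master, or NA = insert gap
  i <- 1L; j <- 1L
  nm <- length(mi); nc <- length(cg)
  while (i <= nm || j <= nc) {
    m_gap <- i <= nm && mi[i] == "-"
    c_gap <- j <= nc && cg[j] == "-"
    if (i <= nm && j <= nc && !m_gap && !c_gap) {
      out_master <- c(out_master, mi[i]); out_new <- c(out_new, og[j])
      keep <- c(keep, i); i <- i + 1L; j <- j + 1L
    } else if (m_gap && c_gap) {
      out_master <- c(out_master, "-"); out_new <- c(out_new, og[j])
      keep <- c(keep, i); i <- i + 1L; j <- j + 1L
    } else if (m_gap) {
      out_master <- c(out_master, "-"); out_new <- c(out_new, "-")
      keep <- c(keep, i); i <- i + 1L
    } else { # c_gap or master exhausted
      out_master <- c(out_master, "-"); out_new <- c(out_new, og[j])
      keep <- c(keep, NA_integer_); j <- j + 1L
    }
  }
  rows <- lapply(rows, function(r) {
    rc <- strsplit(r, "", fixed = TRUE)[[1]]
    paste(ifelse(is.na(keep), "-", rc[ifelse(is.na(keep), 1L, keep)]), collapse = "")
  })
  list(master = paste(out_master, collapse = ""),
       rows = rows,
       new = paste(out_new, collapse = ""))
}

#' Center-star multiple alignment of a barcode panel
#'
#' The center sequence is the record maximising its summed pairwise
#' alignment score against all others (ties broken by input order); the
#' remaining records are merged around it under "once a gap, always a gap".
#' Row order follows the input panel. Barcode loci are short (hundreds of
#' nt), so the quadratic cost is negligible.
#'
#' @param panel A [barcode_panel()] (or data frame with `id`, `species`,
#'   `seq`; gaps in the input are stripped before aligning).
#' @param params An [aln_params()] object.
#' @return A `barcode_msa` tibble.
#' @export
star_msa <- function(panel, params = aln_params()) {
  stopifnot(is.data.frame(panel))
  seqs <- gsub("-", "", panel$seq, fixed = TRUE)
  k <- length(seqs)
  if (k == 1L) {
    warning("single-record panel: returning trivial one-row alignment")
    return(new_barcode_msa(
      tibble::tibble(id = panel$id, species = panel$species, aligned = seqs),
      target = attr(panel, "target_species")))
  }
  scores <- matrix(0, k, k)
  aln <- vector("list", k * k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      al <- nw_align(seqs[i], seqs[j], params)
      scores[i, j] <- scores[j, i] <- al$score
      aln[[(i - 1L) * k + j]] <- al
    }
  }
  center <- which.max(rowSums(scores))  # which.max takes the first on ties
  master <- seqs[center]
  rows <- list()
  order_added <- integer(0)
  for (j in setdiff(seq_len(k), center)) {
    al <- if (center < j) aln[[(center - 1L) * k + j]] else {
      a0 <- aln[[(j - 1L) * k + center]]
      list(score = a0$score, a = a0$b, b = a0$a)
    }
    mg <- .merge_star(master, rows, al$a, al$b)
    master <- mg$master
    rows <- mg$rows
    rows[[length(rows) + 1L]] <- mg$new
    order_added <- c(order_added, j)
  }
  aligned <- character(k)
  aligned[center] <- master
  aligned[order_added] <- unlist(rows)
  new_barcode_msa(
    tibble::tibble(id = panel$id, species = panel$species, aligned = aligned),
    target = attr(panel, "target_species"))
}

.msa_row <- function(msa, id) {
  hit <- which(msa$id == id)
  if (length(hit) == 0L) stop("row '", id, "' not in alignment")
  msa$aligned[hit[1]]
}

#' Project an ungapped residue position onto an alignment column
#'
#' @param msa A `barcode_msa`.
#' @param id Row identifier.
#' @param pos 0-based residue index on the ungapped row sequence.
#' @return 0-based alignment column index holding that residue.
#' @export
msa_project <- function(msa, id, pos) {
  chars <- strsplit(.msa_row(msa, id), "", fixed = TRUE)[[1]]
  res_cols <- which(chars != "-")
  if (any(pos < 0L) || any(pos >= length(res_cols))) {
    stop("position out of range for row '", id, "'")
  }
  res_cols[pos + 1L] - 1L
}

#' Residue index at an alignment column
#'
#' Inverse of [msa_project()]; `NA` at gap columns of the row.
#'
#' @inheritParams msa_project
#' @param col 0-based alignment column.
#' @return 0-based residue index on the ungapped row, or `NA` at a gap.
#' @export
msa_residue_at <- function(msa, id, col) {
  chars <- strsplit(.msa_row(msa, id), "", fixed = TRUE)[[1]]
  if (any(col < 0L) || any(col >= length(chars))) stop("column out of range")
  res_idx <- cumsum(chars != "-") - 1L
  out <- res_idx[col + 1L]
  out[chars[col + 1L] == "-"] <- NA_integer_
  out
}

# column-wise IUPAC consensus bits for one species (union of base sets;
# a column where any record of the species is gapped is treated as a gap)
.species_consensus_bits <- function(msa, species) {
  rows <- msa$aligned[msa$species == species]
  if (length(rows) == 0L) stop("species '", species, "' not in alignment")
  mats <- lapply(rows, seq_bits)
  bits <- Reduce(bitwOr, mats)
  any_gap <- Reduce(`|`, lapply(mats, function(b) b == 0L))
  bits[any_gap] <- 0L
  bits
}
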
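#' RPA primer pair
#'
#' The defaults are universal trnL RPA primers for the Phyllanthus barcode
#' assay (forward 35 nt, reverse 34 nt). RPA tolerates some primer-template
#' mismatch; `max_mm` sets the per-primer tolerance used when locating
#' binding sites.
#'
#' @param fwd Forward primer, 5'->3', binds the plus strand as given.
#' @param rev Reverse primer, 5'->3'; its reverse complement is searched on
#'   the plus strand.
#' @param max_mm Maximum mismatches tolerated per primer site (default 2).
#' @return List of class `primer_set`.
#' @export
primer_set <- function(fwd = "TGTTGTCAATATTGACATGTAGAATGGGACTCTAT",
                       rev = "GCAGAGACTCAATGGAAGCTGTTCTAACAAACGG",
                       max_mm = 2L) {
  structure(list(fwd = validate_seq(fwd, allow_gap = FALSE, what = "fwd primer"),
                 rev = validate_seq(rev, allow_gap = FALSE, what = "rev primer"),
                 max_mm = as.integer(max_mm)),
            class = "primer_set")
}

#' Locate primer binding sites in a sequence
#'
#' Slides the primer (forward orientation: as given; reverse orientation:
#' its reverse complement) along the plus strand and reports every window
#' within the mismatch tolerance, under IUPAC set-intersection matching.
#'
#' @param seq Ungapped nucleotide string.
#' @param primer Primer 5'->3'.
#' @param orientation `"fwd"` or `"rev"`.
#' @param max_mm Maximum mismatches.
#' @return Tibble with 0-based half-open spans: `start`, `end`,
#'   `mismatches`, sorted by `start`.
#' @export
locate_primer <- function(seq, primer, orientation = c("fwd", "rev"),
                          max_mm = 2L) {
  orientation <- match.arg(orientation)
  seq <- validate_seq(seq, allow_gap = FALSE, what = "sequence")
  primer <- validate_seq(primer, allow_gap = FALSE, what = "primer")
  probe <- if (orientation == "fwd") primer else revcomp(primer)
  pl <- nchar(probe)
  L <- nchar(seq)
  empty <- tibble::tibble(start = integer(), end = integer(), mismatches = integer())
  if (pl > L) return(empty)
  sbits <- seq_bits(seq)
  pbits <- seq_bits(probe)
  hits <- list()
  for (i in 0:(L - pl)) {
    mm <- sum(!bits_match(sbits[(i + 1L):(i + pl)], pbits))
    if (mm <= max_mm) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        start = i, end = i + pl, mismatches = as.integer(mm))
    }
  }
  if (!length(hits)) return(empty)
  dplyr::bind_rows(hits)
}

#' Predict RPA amplicons from a primer pair
#'
#' Pairs every forward site with every reverse site downstream of it
#' (non-overlapping, amplicon no longer than `max_len`) and reports the
#' predicted product including both primer footprints, the gel convention
#' for amplicon size. When a guide candidate is supplied, flags whether its
#' whole PAM+spacer window lies strictly between the primer footprints.
#'
#' @param seq Ungapped template string (or a one-row data frame with a
#'   `seq` column).
#' @param primers A [primer_set()].
#' @param guide Optional single-row candidate from
#'   [enumerate_candidates()]; its `win_start`/`win_end` are interpreted on
#'   the supplied template.
#' @param max_len Maximum amplicon length considered (default 1500 nt).
#' @return Tibble of hits: `fwd_start`, `fwd_end`, `rev_start`, `rev_end`
#'   (0-based half-open), `length`, and `contains_guide` when a guide was
#'   given.
#' @export
predict_amplicon <- function(seq, primers = primer_set(), guide = NULL,
                             max_len = 1500L) {
  if (is.data.frame(seq)) seq <- seq$seq[[1]]
  fwd <- locate_primer(seq, primers$fwd, "fwd", primers$max_mm)
  rev <- locate_primer(seq, primers$rev, "rev", primers$max_mm)
  out <- tidyr::crossing(
    dplyr::rename(fwd, fwd_start = "start", fwd_end = "end",
                  fwd_mm = "mismatches"),
    dplyr::rename(rev, rev_start = "start", rev_end = "end",
                  rev_mm = "mismatches"))
  out <- dplyr::filter(out, .data$fwd_end <= .data$rev_start,
                       .data$rev_end - .data$fwd_start <= max_len)
  out <- dplyr::mutate(out, length = .data$rev_end - .data$fwd_start)
  out <- dplyr::arrange(out, .data$fwd_start, .data$rev_start)
  if (!is.null(guide)) {
    ws <- guide$win_start[[1]]
    we <- guide$win_end[[1]]
    out$contains_guide <- out$fwd_end <= ws & we <= out$rev_start
  }
  out[c("fwd_start", "fwd_end", "rev_start", "rev_end", "length",
        intersect("contains_guide", names(out)),
        "fwd_mm", "rev_mm")]
}
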
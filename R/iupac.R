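# IUPAC nucleotide utilities shared across modules.
#
# Every base comparison in the package uses set-intersection semantics:
# two IUPAC codes match when the base sets they denote share at least one
# base. The gap character "-" denotes the empty set and matches nothing.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L,
  `-` = 0L
)

.IUPAC_CHARS <- names(.IUPAC_BITS)

# bitmask -> canonical IUPAC character (index = bitmask + 1)
.BITS_TO_CHAR <- {
  out <- character(16)
  out[1] <- "-"
  for (ch in setdiff(.IUPAC_CHARS, "-")) out[.IUPAC_BITS[[ch]] + 1L] <- ch
  out
}

#' Convert a nucleotide string to a vector of IUPAC bitmasks
#'
#' @param seq Single nucleotide string (IUPAC codes, `-` allowed).
#' @return Integer vector, one bitmask per position (`-` is 0).
#' @keywords internal
#' @noRd
seq_bits <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% .IUPAC_CHARS)
  if (any(bad)) {
    stop("invalid nucleotide character '", chars[which(bad)[1]],
         "' at position ", which(bad)[1], call. = FALSE)
  }
  unname(.IUPAC_BITS[chars])
}

bits_to_seq <- function(bits) paste(.BITS_TO_CHAR[bits + 1L], collapse = "")

#' Validate a nucleotide string over the IUPAC alphabet
#'
#' @param seq Character scalar.
#' @param allow_gap Permit the gap character `-`.
#' @param what Label used in error messages.
#' @return The uppercased, validated string (with `U` converted to `T`),
#'   invisibly usable in pipelines.
#' @keywords internal
#' @noRd
validate_seq <- function(seq, allow_gap = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single string", call. = FALSE)
  }
  s <- chartr("u", "T", chartr("U", "T", toupper(gsub("[[:space:]]", "", seq))))
  if (nchar(s) == 0L) stop(what, " is empty", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  alpha <- if (allow_gap) .IUPAC_CHARS else setdiff(.IUPAC_CHARS, "-")
  bad <- !(chars %in% alpha)
  if (any(bad)) {
    stop("invalid character '", chars[which(bad)[1]], "' at position ",
         which(bad)[1], " of ", what, call. = FALSE)
  }
  s
}

# TRUE where the two bitmask vectors share a base; gaps never match.
bits_match <- function(a, b) bitwAnd(a, b) != 0L

#' Does a sequence window match an IUPAC pattern?
#'
#' Position-wise set-intersection match; both arguments may carry ambiguity
#' codes. Lengths must be equal.
#' @keywords internal
#' @noRd
iupac_window_match <- function(window_bits, pattern_bits) {
  length(window_bits) == length(pattern_bits) &&
    all(bits_match(window_bits, pattern_bits))
}
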
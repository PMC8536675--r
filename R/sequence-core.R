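#' Build a barcode panel from species-labelled sequences
#'
#' A barcode panel is the central input container: one row per sequence record
#' of a homologous barcode locus (e.g. chloroplast trnL), each labelled with
#' the species it came from, plus the designated target species the assay is
#' meant to authenticate.
#'
#' @param records Data frame with columns `id`, `species`, `seq`. Sequences
#'   are uppercased and validated over the IUPAC alphabet; `U` is converted
#'   to `T`.
#' @param target_species Species label to design guides for. Must be present
#'   among `records$species`.
#' @return A tibble of class `barcode_panel` with columns `id`, `species`,
#'   `seq` and attribute `target_species`.
#' @examples
#' panel <- barcode_panel(
#'   tibble::tibble(
#'     id = c("a1", "b1"),
#'     species = c("speciesA", "speciesB"),
#'     seq = c("TTTACCCGGGTTTACCCGGGACGTACGTA", "TTTACCCGGGTTTACCCGGGACGTACGTA")
#'   ),
#'   target_species = "speciesA"
#' )
#' @export
barcode_panel <- function(records, target_species) {
  stopifnot(is.data.frame(records))
  need <- c("id", "species", "seq")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lacks column(s): ", paste(miss, collapse = ", "))
  rec <- tibble::as_tibble(records)[need]
  if (nrow(rec) == 0L) stop("panel has no records")
  if (any(is.na(rec$species)) || any(!nzchar(rec$species))) {
    stop("every record needs a non-empty species label")
  }
  rec$seq <- vapply(seq_len(nrow(rec)), function(i) {
    validate_seq(rec$seq[i], allow_gap = TRUE, what = paste0("record '", rec$id[i], "'"))
  }, character(1))
  if (length(unique(rec$species)) < 2L) {
    stop("panel needs at least 2 distinct species")
  }
  if (!target_species %in% rec$species) {
    stop("target species '", target_species, "' not present in panel")
  }
  structure(rec,
            target_species = target_species,
            class = c("barcode_panel", class(rec)))
}

#' @export
print.barcode_panel <- function(x, ...) {
  cat("<barcode_panel> ", nrow(x), " records, ",
      length(unique(x$species)), " species; target: ",
      attr(x, "target_species"), "\n", sep = "")
  NextMethod()
}

#' Target species of a panel, alignment or design
#' @param x A `barcode_panel`, `barcode_msa` or `cas12a_design`.
#' @return Character scalar.
#' @export
target_species <- function(x) attr(x, "target_species")

#' Read species-labelled sequences from a FASTA file
#'
#' The species label is taken from the second whitespace-separated token of
#' each FASTA header (the first token is the record id), or from
#' `species_map` when supplied. Gapped (aligned) FASTA is accepted; gaps are
#' preserved so aligned input can be passed straight to [as_barcode_msa()].
#'
#' @param path FASTA file.
#' @param species_map Optional named character vector `id -> species`
#'   overriding header-derived labels.
#' @return Tibble with columns `id`, `species`, `seq` (uppercase IUPAC).
#' @export
read_barcode_fasta <- function(path, species_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as raw strings so invalid characters reach our validator instead
  # of being silently dropped
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA parse error: no records in '", path, "'")
  headers <- names(set)
  toks <- strsplit(headers, "[[:space:]]+")
  ids <- vapply(toks, `[`, character(1), 1L)
  species <- vapply(toks, function(t) if (length(t) >= 2L) t[2L] else NA_character_,
                    character(1))
  if (!is.null(species_map)) {
    mapped <- unname(species_map[ids])
    species <- ifelse(is.na(mapped), species, mapped)
  }
  if (anyNA(species)) {
    stop("no species label for record '", ids[which(is.na(species))[1]],
         "': add a second header token or supply species_map")
  }
  seqs <- vapply(seq_along(set), function(i) {
    validate_seq(as.character(set[[i]]), allow_gap = TRUE,
                 what = paste0("record '", ids[i], "'"))
  }, character(1))
  tibble::tibble(id = ids, species = species, seq = seqs)
}

#' Write species-labelled sequences to FASTA
#'
#' Headers are written as `id species`; sequence lines wrap at 60 columns.
#' `read_barcode_fasta()` after `write_barcode_fasta()` is the identity on
#' (`id`, `species`, `seq`).
#'
#' @param records Data frame with `id`, `species`, `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    # degenerate but legal: an empty FASTA file
    cat("", file = path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- paste(records$id, records$species)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' IUPAC-aware (e.g. the complement of `V` is `B`); gaps map to gaps. An
#' involution: `revcomp(revcomp(s)) == s`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TTTA")  # "TAAA"
#' @export
revcomp <- function(seq) {
  s <- vapply(seq, validate_seq, character(1), allow_gap = TRUE, USE.NAMES = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Positions where two equal-length sequences mismatch
#'
#' Comparison uses IUPAC set-intersection semantics: positions match when
#' the two codes share at least one concrete base (so `A` vs `R` is a
#' match). Gaps are not allowed here; gapped windows are handled by the
#' guide-assessment routines.
#'
#' @param a,b Equal-length ungapped nucleotide strings.
#' @return Integer vector of 0-based mismatch positions.
#' @examples
#' hamming_mismatches("ACGT", "AAGT")  # 1
#' @export
hamming_mismatches <- function(a, b) {
  a <- validate_seq(a, allow_gap = FALSE, what = "a")
  b <- validate_seq(b, allow_gap = FALSE, what = "b")
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")")
  }
  which(!bits_match(seq_bits(a), seq_bits(b))) - 1L
}
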
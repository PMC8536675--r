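#' Panel manifest: which sample is truly which species
#'
#' @param samples Data frame with columns `sample_id`, `true_species`.
#' @param target_species The species the assay authenticates.
#' @return Tibble of class `panel_manifest` with attribute
#'   `target_species`.
#' @export
panel_manifest <- function(samples, target_species) {
  stopifnot(is.data.frame(samples))
  need <- c("sample_id", "true_species")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  m <- tibble::as_tibble(samples)[need]
  if (nrow(m) == 0L) stop("manifest has no samples")
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id: ", m$sample_id[anyDuplicated(m$sample_id)])
  }
  structure(m, target_species = target_species,
            class = c("panel_manifest", class(m)))
}

#' Read a manifest from TSV (`sample_id<TAB>true_species`)
#'
#' @param path TSV file with a header line.
#' @param target_species Target species label.
#' @return A [panel_manifest()].
#' @export
read_panel_manifest <- function(path, target_species) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  panel_manifest(df, target_species)
}

# round half up to two decimals, matching reported-percentage convention
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Confusion matrix of a binary authentication panel
#'
#' Counts each sample as TP (target species called positive), FP
#' (non-target called positive), TN (non-target called negative) or FN
#' (target called negative), and derives:
#' accuracy = 100 * (TP + TN) / total (correctly predicted over all
#' samples), precision = 100 * TP / (TP + FP) (true target among samples
#' predicted as target), recall = 100 * TP / (TP + FN). Percentages are
#' rounded half-up to two decimals; precision is `NA` (not applicable,
#' distinct from 0) when nothing was called positive.
#'
#' @param manifest A [panel_manifest()].
#' @param calls Named character vector or data frame
#'   (`sample_id`, `call`) of `"positive"`/`"negative"` calls covering
#'   every manifest sample exactly once.
#' @return Object of class `confusion_matrix`: list with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy_pct`, `precision_pct`, `recall_pct`,
#'   `target_species`, and `by_species` (per-true-species call counts).
#' @export
confusion_matrix <- function(manifest, calls) {
  if (is.data.frame(calls)) {
    calls <- stats::setNames(calls$call, calls$sample_id)
  }
  miss <- setdiff(manifest$sample_id, names(calls))
  if (length(miss)) stop("no call for sample '", miss[1], "'")
  extra <- setdiff(names(calls), manifest$sample_id)
  if (length(extra)) stop("call for unknown sample '", extra[1], "'")
  cl <- unname(calls[manifest$sample_id])
  if (!all(cl %in% c("positive", "negative"))) {
    stop("calls must be 'positive' or 'negative'")
  }
  target <- attr(manifest, "target_species")
  is_t <- manifest$true_species == target
  pos <- cl == "positive"
  tp <- sum(is_t & pos); fp <- sum(!is_t & pos)
  tn <- sum(!is_t & !pos); fn <- sum(is_t & !pos)
  total <- tp + fp + tn + fn
  by_species <- dplyr::count(
    tibble::tibble(true_species = manifest$true_species, call = cl),
    .data$true_species, .data$call, name = "n")
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy_pct = .round2(100 * (tp + tn) / total),
    precision_pct = if (tp + fp > 0) .round2(100 * tp / (tp + fp)) else NA_real_,
    recall_pct = if (tp + fn > 0) .round2(100 * tp / (tp + fn)) else NA_real_,
    target_species = target,
    by_species = by_species),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> target:", x$target_species, "\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.2f%%  precision %s  recall %s\n",
              x$accuracy_pct,
              if (is.na(x$precision_pct)) "n/a" else sprintf("%.2f%%", x$precision_pct),
              if (is.na(x$recall_pct)) "n/a" else sprintf("%.2f%%", x$recall_pct)))
  invisible(x)
}

#' Evaluate a blinded sample panel in silico
#'
#' Aligns every sample sequence with a target reference, designs (or
#' selects) a guide on the reference, predicts the per-sample call from
#' each sample's own assessment, optionally gates calls on the guide lying
#' inside a predicted RPA amplicon of that sample, and tabulates the
#' confusion matrix against the manifest.
#'
#' @param samples Data frame with `id` (matching manifest sample ids) and
#'   `seq`. If every sequence has equal width and contains gaps it is taken
#'   as pre-aligned (together with the reference, which must then be
#'   aligned too); otherwise sequences are aligned by [star_msa()].
#' @param manifest A [panel_manifest()].
#' @param reference Target reference sequence (the sequence the guide is
#'   designed on), gapped consistently when `samples` are pre-aligned.
#' @param guide_id Optional guide id to evaluate; default picks the
#'   top-ranked candidate.
#' @param params A [design_params()] object.
#' @param rules An [activity_rules()] object.
#' @param primers Optional [primer_set()]: samples whose predicted
#'   amplicons do not contain the guide window are called negative
#'   (`"no_amplicon"` rationale).
#' @param aln An [aln_params()] object for the alignment step.
#' @return List with `predictions` (tibble: `sample_id`, `true_species`,
#'   `score`, `rationale`, `call`), `confusion` (a `confusion_matrix`),
#'   `candidate` (the guide used) and `msa`.
#' @export
evaluate_panel <- function(samples, manifest, reference, guide_id = NULL,
                           params = design_params(),
                           rules = activity_rules("strict"),
                           primers = NULL, aln = aln_params()) {
  stopifnot(is.data.frame(samples), inherits(manifest, "panel_manifest"))
  miss <- setdiff(manifest$sample_id, samples$id)
  if (length(miss)) stop("no sequence for sample '", miss[1], "'")
  target <- attr(manifest, "target_species")
  ref_id <- ".target_ref"
  # each sample is assessed individually: give it its own species label
  recs <- tibble::tibble(
    id = c(ref_id, samples$id),
    species = c(target, samples$id),
    seq = c(reference, samples$seq))
  widths <- nchar(recs$seq)
  prealigned <- length(unique(widths)) == 1L && any(grepl("-", recs$seq, fixed = TRUE))
  msa <- if (prealigned) {
    as_barcode_msa(recs, target_species = target)
  } else {
    star_msa(structure(recs, target_species = target), aln)
  }
  candidates <- enumerate_candidates(msa, params, target)
  if (nrow(candidates) == 0L) stop("no candidate guide on the reference")
  cand <- if (is.null(guide_id)) {
    ranked <- rank_candidates(msa, candidates, params, rules)
    candidates[candidates$guide_id == ranked$guide_id[1], ]
  } else {
    sel <- candidates[candidates$guide_id == guide_id, ]
    if (nrow(sel) == 0L) stop("guide '", guide_id, "' not among candidates")
    sel
  }
  preds <- predict_signal(assess_candidates(msa, cand, params), rules)
  preds <- dplyr::rename(preds, sample_id = "species")
  preds <- preds[match(manifest$sample_id, preds$sample_id), ]
  if (!is.null(primers)) {
    cols <- sort(c(cand$pam_cols[[1]], cand$spacer_cols[[1]]))
    for (i in seq_len(nrow(preds))) {
      sid <- preds$sample_id[i]
      row_seq <- gsub("-", "", msa$aligned[msa$id == sid][1], fixed = TRUE)
      res <- suppressWarnings(msa_residue_at(msa, sid, cols))
      if (anyNA(res)) {
        covered <- FALSE
      } else {
        amp <- predict_amplicon(row_seq, primers)
        covered <- nrow(amp) > 0 &&
          any(amp$fwd_end <= min(res) & max(res) + 1L <= amp$rev_start)
      }
      if (!covered && preds$call[i] == "positive") {
        preds$call[i] <- "negative"
        preds$rationale[i] <- paste(preds$rationale[i], "no_amplicon", sep = ";")
      }
    }
  }
  predictions <- tibble::tibble(
    sample_id = manifest$sample_id,
    true_species = manifest$true_species,
    score = preds$score,
    rationale = preds$rationale,
    call = preds$call)
  conf <- confusion_matrix(manifest,
                           stats::setNames(predictions$call, predictions$sample_id))
  list(predictions = predictions, confusion = conf, candidate = cand, msa = msa)
}
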
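#' Activity rules for qualitative signal prediction
#'
#' A penalty model for whether Cas12a collateral cleavage fires on a given
#' species: seed mismatches are penalised most, distal mismatches least,
#' and a non-canonical (variant) PAM adds a penalty; a gap-disrupted
#' (absent) PAM is a hard negative, and a spacer identical to the target's
#' forces a positive call even under a variant PAM. The call is negative
#' when the total penalty reaches `threshold`.
#'
#' Two named presets ship: `"strict"` (any seed mismatch alone is enough to
#' call negative) and `"permissive"` (a single seed mismatch with a
#' canonical PAM stays positive). The seed region is treated as
#' mismatch-intolerant by default, hence `strict`.
#'
#' @param preset `"strict"` or `"permissive"`, or `NULL` to use the
#'   explicit arguments.
#' @param seed_penalty Penalty per seed mismatch.
#' @param distal_penalty Penalty per distal (non-seed) mismatch.
#' @param pam_variant_penalty Penalty when the PAM window is present but
#'   does not match the PAM pattern.
#' @param pam_absent Hard negative when the PAM window is gap-disrupted.
#' @param identity_override Force a positive call when the spacer is
#'   identical (no mismatches, no gaps), regardless of a variant PAM.
#' @param threshold Total penalty at or above which the call is negative.
#' @return List of class `activity_rules`.
#' @export
activity_rules <- function(preset = c("strict", "permissive"),
                           seed_penalty = NULL, distal_penalty = 1,
                           pam_variant_penalty = 2, pam_absent = TRUE,
                           identity_override = TRUE, threshold = NULL) {
  if (is.character(preset)) {
    preset <- match.arg(preset)
    if (preset == "strict") {
      seed_penalty <- seed_penalty %||% 3
      threshold <- threshold %||% 3
    } else {
      seed_penalty <- seed_penalty %||% 2
      threshold <- threshold %||% 4
    }
  } else {
    preset <- "custom"
    seed_penalty <- seed_penalty %||% 3
    threshold <- threshold %||% 3
  }
  stopifnot(seed_penalty >= 0, distal_penalty >= 0, pam_variant_penalty >= 0,
            threshold > 0)
  structure(list(preset = preset, seed_penalty = seed_penalty,
                 distal_penalty = distal_penalty,
                 pam_variant_penalty = pam_variant_penalty,
                 pam_absent = isTRUE(pam_absent),
                 identity_override = isTRUE(identity_override),
                 threshold = threshold),
            class = "activity_rules")
}

#' Predict the qualitative fluorescence call per species
#'
#' Rule evaluation, per assessment row: a gap-disrupted PAM is negative
#' (when `pam_absent` is set); an identical spacer is positive (when
#' `identity_override` is set — this covers the case of a variant but
#' present PAM with a perfectly conserved protospacer); otherwise the call
#' is positive iff the total mismatch/PAM penalty stays below the
#' threshold. The `rationale` column lists the rules that fired, in order.
#'
#' @param assessments Output of [assess_candidates()].
#' @param rules An [activity_rules()] object.
#' @return The input tibble with `score`, `call` (`"positive"` /
#'   `"negative"`) and `rationale` columns added.
#' @export
predict_signal <- function(assessments, rules = activity_rules("strict")) {
  stopifnot(is.data.frame(assessments))
  a <- tibble::as_tibble(assessments)
  score <- rules$seed_penalty * a$seed_mismatches +
    rules$distal_penalty * a$distal_mismatches +
    rules$pam_variant_penalty * (a$pam_status == "variant")
  call <- character(nrow(a))
  rationale <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    fired <- character(0)
    if (a$pam_status[i] == "absent" && rules$pam_absent) {
      fired <- c(fired, "pam_absent")
      call[i] <- "negative"
    } else if (a$spacer_identical[i] && rules$identity_override) {
      fired <- c(fired, "identity_override")
      if (a$pam_status[i] == "variant") fired <- c(fired, "pam_variant_tolerated")
      call[i] <- "positive"
    } else {
      if (a$seed_mismatches[i] > 0) fired <- c(fired, "seed_mismatch")
      if (a$distal_mismatches[i] > 0) fired <- c(fired, "distal_mismatch")
      if (a$pam_status[i] == "variant") fired <- c(fired, "pam_variant")
      fired <- c(fired, if (score[i] < rules$threshold) "score_below_threshold"
                 else "score_at_threshold")
      call[i] <- if (score[i] < rules$threshold) "positive" else "negative"
    }
    rationale[i] <- paste(fired, collapse = ";")
  }
  a$score <- score
  a$call <- call
  a$rationale <- rationale
  a
}

#' Discrimination power of one candidate
#'
#' Fraction of off-target species predicted negative, provided the target
#' itself is predicted positive; a candidate whose target call is negative
#' is disqualified (`-Inf`).
#'
#' @param off_calls Character vector of off-target calls
#'   (`"positive"`/`"negative"`), one per non-target species.
#' @param target_call The target species' own call.
#' @return Numeric in `[0, 1]`, or `-Inf` when disqualified.
#' @export
discrimination_score <- function(off_calls, target_call) {
  if (!length(off_calls)) stop("no off-target predictions supplied")
  if (!identical(target_call, "positive")) return(-Inf)
  mean(off_calls == "negative")
}

# the target's own (identity) assessment of a candidate
.target_self_assessment <- function(candidates) {
  tibble::tibble(
    guide_id = candidates$guide_id,
    species = candidates$target_species,
    pam_status = "canonical",
    pam_obs = candidates$pam_seq,
    seed_mismatches = 0L, distal_mismatches = 0L, gap_positions = 0L,
    spacer_identical = TRUE)
}

#' Rank candidate guides by species discrimination
#'
#' Assesses and signal-predicts every candidate, then orders them by the
#' fraction of off-target species called negative (descending). Ties break
#' by larger total off-target penalty, then fewer off-target canonical
#' PAMs, then leftmost window, then input order (stable sort).
#'
#' @param msa A `barcode_msa`.
#' @param candidates Output of [enumerate_candidates()]; computed from
#'   `msa` when `NULL`.
#' @param params A [design_params()] object.
#' @param rules An [activity_rules()] object.
#' @return Tibble, one row per candidate in rank order: candidate columns
#'   plus `target_call`, `n_off`, `n_off_negative`, `discrimination`,
#'   `off_penalty_total`, `n_off_canonical_pam`, `rank`.
#' @export
rank_candidates <- function(msa, candidates = NULL, params = design_params(),
                            rules = activity_rules("strict")) {
  if (is.null(candidates)) candidates <- enumerate_candidates(msa, params)
  if (nrow(candidates) == 0L) {
    warning("no candidate guides to rank")
    return(tibble::tibble())
  }
  preds <- predict_signal(assess_candidates(msa, candidates, params), rules)
  target_preds <- predict_signal(.target_self_assessment(candidates), rules)
  per_cand <- dplyr::summarise(
    dplyr::group_by(preds, .data$guide_id),
    n_off = dplyr::n(),
    n_off_negative = sum(.data$call == "negative"),
    off_penalty_total = sum(.data$score),
    n_off_canonical_pam = sum(.data$pam_status == "canonical"),
    .groups = "drop")
  out <- dplyr::left_join(tibble::as_tibble(candidates), per_cand, by = "guide_id")
  out$target_call <- target_preds$call[match(out$guide_id, target_preds$guide_id)]
  out$discrimination <- ifelse(out$target_call == "positive",
                               out$n_off_negative / out$n_off, -Inf)
  out$.input_order <- seq_len(nrow(out))
  out <- dplyr::arrange(out, dplyr::desc(.data$discrimination),
                        dplyr::desc(.data$off_penalty_total),
                        .data$n_off_canonical_pam, .data$win_start,
                        .data$.input_order)
  out$rank <- seq_len(nrow(out))
  out$.input_order <- NULL
  out
}

#' Design species-discriminating guides end to end
#'
#' Convenience wrapper: aligns the panel (unless an alignment is given),
#' enumerates candidates on the target, assesses them against every other
#' species, predicts the per-species call, and ranks.
#'
#' @param x A [barcode_panel()] or a ready `barcode_msa`.
#' @param target Target species label (defaults to the panel's).
#' @param params A [design_params()] object.
#' @param rules An [activity_rules()] object.
#' @param aln An [aln_params()] object used when `x` needs aligning.
#' @return Object of class `cas12a_design`: list with `msa`, `candidates`,
#'   `assessments`, `predictions`, `ranking`, `params`, `rules`.
#' @export
design_guides <- function(x, target = NULL, params = design_params(),
                          rules = activity_rules("strict"),
                          aln = aln_params()) {
  msa <- if (inherits(x, "barcode_msa")) x else star_msa(x, aln)
  target <- target %||% attr(msa, "target_species")
  attr(msa, "target_species") <- target
  candidates <- enumerate_candidates(msa, params, target)
  if (nrow(candidates) == 0L) {
    assessments <- predictions <- tibble::tibble()
    ranking <- tibble::tibble()
    warning("no PAM sites with a full spacer found on the target")
  } else {
    assessments <- assess_candidates(msa, candidates, params)
    predictions <- predict_signal(assessments, rules)
    ranking <- rank_candidates(msa, candidates, params, rules)
  }
  structure(list(msa = msa, target_species = target, candidates = candidates,
                 assessments = assessments, predictions = predictions,
                 ranking = ranking, params = params, rules = rules),
            class = "cas12a_design")
}

#' @export
print.cas12a_design <- function(x, ...) {
  cat("<cas12a_design> target:", x$target_species, "-",
      nrow(x$candidates), "candidates on",
      length(unique(x$msa$species)) - 1L, "off-target species;",
      "rules:", x$rules$preset, "\n")
  if (nrow(x$ranking)) {
    top <- x$ranking[1, ]
    cat("top guide:", top$guide_id, sprintf("(strand %s, pam %s, discrimination %.2f)\n",
        top$strand, top$pam_seq, top$discrimination))
  }
  invisible(x)
}
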
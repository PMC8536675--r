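#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a guide design into one row per guide x species prediction
#'
#' @param x A `cas12a_design`.
#' @param ... Unused.
#' @return Tibble: `guide_id`, `species`, `pam_status`, mismatch counts,
#'   `score`, `call`, `rationale`.
#' @method tidy cas12a_design
#' @export
tidy.cas12a_design <- function(x, ...) {
  tibble::as_tibble(x$predictions)
}

#' One-row summary of a guide design
#'
#' @param x A `cas12a_design`.
#' @param ... Unused.
#' @return Tibble with candidate counts and the top-ranked guide.
#' @method glance cas12a_design
#' @export
glance.cas12a_design <- function(x, ...) {
  if (!nrow(x$ranking)) {
    return(tibble::tibble(target_species = x$target_species, n_candidates = 0L))
  }
  top <- x$ranking[1, ]
  tibble::tibble(
    target_species = x$target_species,
    n_candidates = nrow(x$candidates),
    n_species = length(unique(x$msa$species)),
    rules = x$rules$preset,
    top_guide = top$guide_id,
    top_discrimination = top$discrimination,
    n_perfect = sum(x$ranking$discrimination == 1, na.rm = TRUE))
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    outcome = c("tp", "fp", "tn", "fn"),
    n = c(x$tp, x$fp, x$tn, x$fn))
}

#' One-row confusion-matrix metrics
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    accuracy_pct = x$accuracy_pct,
    precision_pct = x$precision_pct,
    recall_pct = x$recall_pct)
}

#' Heatmap of predicted calls per guide and species
#'
#' Guides on the y axis (rank order when available), species on the x
#' axis, tiles coloured by the predicted call and labelled with the
#' penalty score.
#'
#' @param object A `cas12a_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cas12a_design
#' @export
autoplot.cas12a_design <- function(object, ...) {
  preds <- object$predictions
  if (!nrow(preds)) stop("design has no predictions to plot")
  if (nrow(object$ranking)) {
    preds$guide_id <- factor(preds$guide_id,
                             levels = rev(object$ranking$guide_id))
  }
  ggplot2::ggplot(preds,
                  ggplot2::aes(x = .data$species, y = .data$guide_id,
                               fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$score), size = 3) +
    ggplot2::scale_fill_manual(values = c(positive = "#2c8c55",
                                          negative = "#cccccc")) +
    ggplot2::labs(x = "species", y = "guide",
                  title = paste("Predicted Cas12a readout per species, target:",
                                object$target_species)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix tile plot (actual species by call)
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  ggplot2::ggplot(object$by_species,
                  ggplot2::aes(x = .data$call, y = .data$true_species,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "predicted call", y = "actual species",
                  title = sprintf("accuracy %.2f%%, precision %s",
                                  object$accuracy_pct,
                                  ifelse(is.na(object$precision_pct), "n/a",
                                         sprintf("%.2f%%", object$precision_pct)))) +
    ggplot2::theme_minimal()
}
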
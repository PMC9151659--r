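#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method print chord_result
#' @export
print.chord_result <- function(x, ...) {
  cat("<chord_result>\n")
  cat(sprintf("  %d cells, doublet rate %.4f, %d called doublets\n",
              nrow(x$scores), x$doubletrate, sum(x$calls)))
  cat(sprintf("  features: %s\n", paste(x$model$feature_names, collapse = ", ")))
  cat(sprintf("  overkill removed %d cells; booster best iteration %d (train AUROC %.3f)\n",
              length(x$removed_overkill), x$model$best_iteration,
              x$model$train_auc))
  invisible(x)
}

#' Tidy a chord result into one row per cell
#'
#' @param x A `chord_result`.
#' @param ... Unused.
#' @return Tibble: `cell_id`, one column per base/external method, `chord`,
#'   `is_doublet_call`.
#' @method tidy chord_result
#' @export
tidy.chord_result <- function(x, ...) {
  dplyr::mutate(x$scores, is_doublet_call = x$calls)
}

#' One-row summary of a chord result
#'
#' @param x A `chord_result`.
#' @param ... Unused.
#' @method glance chord_result
#' @export
glance.chord_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$scores),
    doubletrate = x$doubletrate,
    n_called = sum(x$calls),
    n_overkill_removed = length(x$removed_overkill),
    n_simulated_doublets = sum(x$training_set$labels == 1L),
    best_iteration = x$model$best_iteration,
    train_auc = x$model$train_auc)
}

#' @method print chord_model
#' @export
print.chord_model <- function(x, ...) {
  cat("<chord_model>\n")
  cat(sprintf("  boosted stumps over [%s]; best iteration %d; train AUROC %.3f\n",
              paste(x$feature_names, collapse = ", "), x$best_iteration,
              x$train_auc))
  invisible(x)
}

#' @method glance chord_model
#' @export
glance.chord_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names),
                 best_iteration = x$best_iteration,
                 train_auc = x$train_auc)
}

#' @method print chord_truth
#' @export
print.chord_truth <- function(x, ...) {
  cat("<chord_truth>\n")
  cat(sprintf("  %d genes x %d cells (%d doublets, %.1f%%)\n",
              nrow(x$counts), ncol(x$counts), sum(x$cells$is_doublet),
              100 * mean(x$cells$is_doublet)))
  n_deg <- sum(x$genes$deg != "none")
  if (n_deg > 0) cat(sprintf("  %d DEG-labelled genes\n", n_deg))
  if ("pseudotime" %in% names(x$cells) && any(!is.na(x$cells$pseudotime))) {
    cat(sprintf("  trajectory design, %d lineages\n",
                length(unique(stats::na.omit(x$cells$lineage)))))
  }
  invisible(x)
}

#' Tidy a truth dataset's per-cell labels
#'
#' @param x A `chord_truth`.
#' @param ... Unused.
#' @method tidy chord_truth
#' @export
tidy.chord_truth <- function(x, ...) x$cells

#' Score distributions of a chord run, split by call
#'
#' @param object A `chord_result`.
#' @param ... Unused.
#' @return A ggplot: per-method score densities, doublet calls highlighted.
#' @method autoplot chord_result
#' @export
autoplot.chord_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              cols = -c("cell_id", "is_doublet_call"),
                              names_to = "method", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score,
                                     fill = .data$is_doublet_call)) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::labs(x = "doublet score", y = "cells", fill = "called doublet") +
    ggplot2::theme_minimal()
}

#' ROC curves for a score table against truth labels
#'
#' @param scores Score tibble (`cell_id` + one column per method).
#' @param labels Binary truth labels aligned to the table rows.
#' @return A ggplot of ROC curves with AUROC annotations.
#' @export
plot_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  curves <- purrr::map_dfr(setdiff(names(scores), "cell_id"), function(mname) {
    s <- scores[[mname]]
    ord <- order(-s)
    y <- labels[ord]
    tibble::tibble(
      method = sprintf("%s (AUC %.3f)", mname, auroc(s, labels)),
      fpr = c(0, cumsum(!y) / sum(!labels)),
      tpr = c(0, cumsum(y) / sum(labels)))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
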
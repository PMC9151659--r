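#' Chord pipeline configuration
#'
#' Collects every tunable of the ensemble pipeline. The defaults reproduce
#' the published settings: 1000 boosting trees at shrinkage 0.01 with 5-fold
#' CV for the meta-learner, k-means with k = 20 on 30 PCs for the training
#' simulation, N(1, 0.1) biological weights on simulated doublet members, and
#' an overkill rate of 1.
#'
#' @param doubletrate Expected doublet fraction in (0, 1), or `"auto"` to use
#'   the loading-based rule of 0.9% per 1000 cells ([estimate_doublet_rate()]).
#' @param overkillrate Multiplier on the doublet rate for the pre-filter that
#'   removes each base detector's top-scoring cells before training-set
#'   simulation. 0 disables the overkill step.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_variable_genes Variable genes kept in the preprocessing chain.
#' @param n_pcs_cluster Principal components used before k-means clustering.
#' @param kmeans_k Number of k-means clusters for cell-type stratification.
#' @param gbm_n_trees,gbm_shrinkage,gbm_cv_folds Boosted-tree meta-learner
#'   settings (rounds, learning rate, CV folds).
#' @param weight_sd Standard deviation of the N(1, sd) biological weights
#'   applied to each member of a simulated training doublet.
#' @return A `chord_config` list.
#' @export
chord_config <- function(doubletrate = "auto", overkillrate = 1, seed = 1L,
                         n_variable_genes = 2000L, n_pcs_cluster = 30L,
                         kmeans_k = 20L, gbm_n_trees = 1000L,
                         gbm_shrinkage = 0.01, gbm_cv_folds = 5L,
                         weight_sd = 0.1) {
  if (!identical(doubletrate, "auto")) {
    stopifnot(is.numeric(doubletrate), length(doubletrate) == 1,
              doubletrate > 0, doubletrate < 1)
  }
  stopifnot(overkillrate >= 0, n_variable_genes >= 1, n_pcs_cluster >= 1,
            kmeans_k >= 1, gbm_n_trees >= 1, gbm_shrinkage > 0,
            gbm_cv_folds >= 2, weight_sd >= 0)
  structure(list(
    doubletrate = doubletrate, overkillrate = overkillrate,
    seed = as.integer(seed), n_variable_genes = as.integer(n_variable_genes),
    n_pcs_cluster = as.integer(n_pcs_cluster), kmeans_k = as.integer(kmeans_k),
    gbm_n_trees = as.integer(gbm_n_trees), gbm_shrinkage = gbm_shrinkage,
    gbm_cv_folds = as.integer(gbm_cv_folds), weight_sd = weight_sd
  ), class = "chord_config")
}

#' Base-detector parameters
#'
#' Defaults mirror the published built-in settings: `ntop = 500` and
#' `binThresh = 0` for the co-expression score, `pN = 0.25` and 10 PCs for
#' the artificial-nearest-neighbour score.
#'
#' @param ntop Genes kept by binarized variance (co-expression and boosted
#'   detectors).
#' @param binThresh Count threshold for binarization (expressed = count >
#'   binThresh).
#' @param pN Fraction of the merged dataset that is artificial doublets in
#'   the kNN detector: `n_sim = round(pN / (1 - pN) * n_cells)`.
#' @param n_pcs_knn PCA components for the kNN embedding.
#' @param pK_grid Neighbourhood-size fractions swept when auto-selecting pK
#'   by bimodality coefficient.
#' @param boost_rounds Boosting rounds for the real-vs-artificial classifier.
#' @return A `detector_params` list.
#' @export
detector_params <- function(ntop = 500L, binThresh = 0L, pN = 0.25,
                            n_pcs_knn = 10L,
                            pK_grid = c(0.005, 0.01, 0.02, 0.03, 0.05,
                                        0.1, 0.15, 0.2, 0.25, 0.3),
                            boost_rounds = 200L) {
  stopifnot(ntop >= 2, binThresh >= 0, pN > 0, pN < 1,
            n_pcs_knn >= 1, all(pK_grid > 0), all(pK_grid < 1),
            boost_rounds >= 1)
  structure(list(
    ntop = as.integer(ntop), binThresh = binThresh, pN = pN,
    n_pcs_knn = as.integer(n_pcs_knn), pK_grid = pK_grid,
    boost_rounds = as.integer(boost_rounds)
  ), class = "detector_params")
}
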
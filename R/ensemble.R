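#' Loading-based expected doublet rate
#'
#' Droplet platforms produce doublets at a rate roughly linear in the number
#' of loaded cells: 0.9% per 1000 cells captured. The estimate is capped at
#' 0.5 (with a warning) for implausibly large inputs.
#'
#' @param n_cells Number of cells in the sample.
#' @return Expected doublet fraction.
#' @export
estimate_doublet_rate <- function(n_cells) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 0) {
    abort("n_cells must be a single non-negative number")
  }
  rate <- 0.009 * n_cells / 1000
  if (rate > 0.5) {
    warn(sprintf("estimated doublet rate %.3f capped at 0.5", rate))
    rate <- 0.5
  }
  rate
}

#' Overkill pre-filter
#'
#' Coarsely removes likely doublets before the training set is simulated, so
#' real doublets do not pollute the "singlet" training class. For each score
#' column independently, the top `round(d * overkillrate * n_cells)` cells
#' are marked; the union of marked cells is removed. Ties at the cutoff are
#' broken by lower cell index.
#'
#' @param m Count matrix (genes x cells).
#' @param base_scores Score tibble aligned to `m` (`cell_id` + one column
#'   per method).
#' @param d Doublet rate in \[0, 1).
#' @param overkillrate Multiplier on `d`; 0 disables filtering.
#' @return A list: `counts` (prefiltered matrix), `removed` (cell ids).
#' @export
overkill_filter <- function(m, base_scores, d, overkillrate = 1) {
  stopifnot(d >= 0, d * overkillrate < 1)
  aligned <- align_scores(base_scores, colnames(m))
  n <- ncol(m)
  n_rm <- round(d * overkillrate * n)
  marked <- integer(0)
  for (col in names(aligned)[-1]) {
    marked <- union(marked, top_n_by_score(aligned[[col]], n_rm))
  }
  if (length(marked) >= n) {
    abort("overkill would remove every cell; lower overkillrate or the doublet rate")
  }
  keep <- setdiff(seq_len(n), marked)
  list(counts = m[, keep, drop = FALSE],
       removed = colnames(m)[sort(marked)])
}

#' Simulate training doublets from prefiltered data
#'
#' Clusters the prefiltered cells (normalize, variable genes, scale, PCA to
#' `n_pcs_cluster`, k-means with `kmeans_k`), then draws
#' `round(N * d / (1 - d))` artificial doublets: for a doublet attributed to
#' cluster c, the first member is sampled uniformly from c and the second
#' uniformly from the other clusters (avoiding same-type pairs). Each
#' member's raw profile is weighted by an independent N(1, weight_sd) draw
#' (truncated at 0) to mimic biological/experimental variation, and the
#' doublet profile is the elementwise mean of the two weighted profiles,
#' left real-valued. Per-cluster counts `round(s_c * d/(1-d))` are adjusted
#' at the largest clusters so the global count is exact.
#'
#' @param prefiltered Count matrix after [overkill_filter()].
#' @param d Doublet rate used for the simulation ratio `d/(1-d)`.
#' @param cfg A [chord_config()].
#' @param seed RNG seed.
#' @param homotypic Also allow same-cluster pairs (off by default).
#' @return A `chord_training_set`: list with `counts` (real + simulated),
#'   `labels` (1 = simulated doublet), `provenance` (tibble: doublet id,
#'   both member ids and weights), `clusters`.
#' @export
simulate_training_doublets <- function(prefiltered, d, cfg = chord_config(),
                                       seed = cfg$seed, homotypic = FALSE) {
  stopifnot(d >= 0, d < 1)
  n <- ncol(prefiltered)
  if (d == 0) {
    return(structure(list(
      counts = prefiltered, labels = rep(0L, n),
      provenance = tibble::tibble(doublet_id = character(), member1 = character(),
                                  member2 = character(), w1 = numeric(),
                                  w2 = numeric()),
      clusters = NULL), class = "chord_training_set"))
  }
  emb <- preprocess_embed(prefiltered, cfg$n_variable_genes,
                          cfg$n_pcs_cluster, seed = seed)
  cl <- kmeans_clusters(emb, k = cfg$kmeans_k,
                        seed = derive_seed(seed, "kmeans"))
  labels <- cl$labels
  occupied <- sort(unique(labels))
  if (length(occupied) < 2 && !homotypic) {
    abort("training-doublet simulation needs >= 2 occupied clusters for cross-type pairing")
  }
  sizes <- table(labels)
  n_total <- round(n * d / (1 - d))
  n_c <- round(as.numeric(sizes) * d / (1 - d))
  names(n_c) <- names(sizes)
  # adjust at the largest clusters so the global count is exact
  delta <- n_total - sum(n_c)
  ord <- order(-as.numeric(sizes))
  i <- 1
  while (delta != 0) {
    j <- ord[(i - 1) %% length(ord) + 1]
    step <- sign(delta)
    if (n_c[j] + step >= 0) {
      n_c[j] <- n_c[j] + step
      delta <- delta - step
    }
    i <- i + 1
  }
  sim <- with_seed(seed, {
    m1 <- integer(n_total)
    m2 <- integer(n_total)
    pos <- 1
    for (cname in names(n_c)) {
      cnt <- n_c[[cname]]
      if (cnt == 0) next
      inside <- which(labels == as.integer(cname))
      outside <- if (homotypic) seq_len(n) else which(labels != as.integer(cname))
      m1[pos:(pos + cnt - 1)] <- inside[sample.int(length(inside), cnt, replace = TRUE)]
      m2[pos:(pos + cnt - 1)] <- outside[sample.int(length(outside), cnt, replace = TRUE)]
      pos <- pos + cnt
    }
    w1 <- pmax(0, stats::rnorm(n_total, 1, cfg$weight_sd))
    w2 <- pmax(0, stats::rnorm(n_total, 1, cfg$weight_sd))
    list(m1 = m1, m2 = m2, w1 = w1, w2 = w2)
  })
  prof <- (prefiltered[, sim$m1, drop = FALSE] %*% Matrix::Diagonal(x = sim$w1) +
           prefiltered[, sim$m2, drop = FALSE] %*% Matrix::Diagonal(x = sim$w2)) / 2
  prof <- as(prof, "CsparseMatrix")
  dbl_ids <- paste0("simdbl_", seq_len(n_total))
  dimnames(prof) <- list(rownames(prefiltered), dbl_ids)
  structure(list(
    counts = cbind(prefiltered, prof),
    labels = c(rep(0L, n), rep(1L, n_total)),
    provenance = tibble::tibble(
      doublet_id = dbl_ids,
      member1 = colnames(prefiltered)[sim$m1],
      member2 = colnames(prefiltered)[sim$m2],
      w1 = sim$w1, w2 = sim$w2),
    clusters = cl), class = "chord_training_set")
}

#' Score a training set with the built-in detectors
#'
#' Runs the same detectors, at the same settings, that will score the
#' original matrix, so training features and prediction features share one
#' schema. External score columns (ChordP mode) are appended after the
#' built-ins, in their given order.
#'
#' @param ts A `chord_training_set`.
#' @param params A [detector_params()].
#' @param seed RNG seed.
#' @param external_train Optional external score tibble covering every
#'   training-set cell.
#' @return Score tibble: `cell_id`, `coexpression`, `knn`, `boosted`, then
#'   external columns.
#' @export
score_training_set <- function(ts, params = detector_params(), seed = 1L,
                               external_train = NULL) {
  scores <- base_detector_scores(ts$counts, params, seed = seed)
  if (!is.null(external_train)) {
    ext <- align_scores(external_train, colnames(ts$counts))
    scores <- dplyr::bind_cols(scores, ext[, -1, drop = FALSE])
  }
  scores
}

#' Train the gradient-boosted stacking model
#'
#' Fits depth-1 gradient-boosted trees (logistic deviance loss) on the base
#' detectors' scores, simulated doublets as positives and retained cells as
#' negatives: 1000 rounds at shrinkage 0.01, with the best iteration chosen
#' by 5-fold stratified cross-validated deviance.
#'
#' @param features Score tibble (`cell_id` + >= 2 numeric columns).
#' @param labels Binary vector (1 = simulated doublet), both classes present.
#' @param cfg A [chord_config()].
#' @param seed RNG seed.
#' @return A `chord_model`: `feature_names`, `booster`, `best_iteration`,
#'   `train_auc`.
#' @export
train_ensemble <- function(features, labels, cfg = chord_config(),
                           seed = cfg$seed) {
  feature_names <- setdiff(names(features), "cell_id")
  if (length(feature_names) < 2) abort("stacking needs >= 2 feature columns")
  if (length(unique(labels)) < 2) abort("both classes must be present in the labels")
  X <- as.matrix(features[, feature_names, drop = FALSE])
  y <- as.integer(labels)
  folds <- with_seed(seed, make_stratified_folds(y, cfg$gbm_cv_folds))
  par <- xgboost::xgb.params(objective = "binary:logistic", max_depth = 1,
                             eta = cfg$gbm_shrinkage, nthread = 1, seed = seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  cv <- xgboost::xgb.cv(params = par, data = dtrain, nrounds = cfg$gbm_n_trees,
                        nfold = cfg$gbm_cv_folds, folds = folds,
                        metrics = "logloss", verbose = FALSE)
  el <- as.data.frame(cv$evaluation_log)
  best_iteration <- which.min(el$test_logloss_mean)
  booster <- xgboost::xgb.train(params = par, data = dtrain,
                                nrounds = best_iteration, verbose = 0)
  train_pred <- stats::predict(booster, dtrain)
  structure(list(
    feature_names = feature_names, booster = booster,
    best_iteration = as.integer(best_iteration),
    train_auc = auroc(train_pred, y)
  ), class = "chord_model")
}

#' Predict ensemble doublet scores
#'
#' @param model A `chord_model` from [train_ensemble()].
#' @param features Score tibble with exactly the model's feature columns.
#' @return Numeric per-cell probability vector in [0, 1].
#' @export
predict_scores <- function(model, features) {
  have <- setdiff(names(features), "cell_id")
  missing <- setdiff(model$feature_names, have)
  extra <- setdiff(have, model$feature_names)
  if (length(missing) || length(extra)) {
    abort(sprintf(
      "feature schema mismatch: missing [%s], extra [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
  }
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Threshold scores at the expected doublet rate
#'
#' Flags exactly `round(d * n)` top-scoring cells; ties at the cutoff are
#' broken by lower cell index.
#'
#' @param scores Numeric per-cell scores.
#' @param d Expected doublet fraction in \[0, 1\].
#' @return Logical vector of doublet calls.
#' @export
call_doublets <- function(scores, d) {
  stopifnot(d >= 0, d <= 1)
  n <- length(scores)
  calls <- rep(FALSE, n)
  calls[top_n_by_score(scores, round(d * n))] <- TRUE
  calls
}

#' Run the full ensemble doublet-detection pipeline
#'
#' The three-step workflow: (1) score the original matrix with the base
#' detectors and remove the overkill union of their top-scoring cells;
#' (2) simulate labelled training doublets from the prefiltered data, score
#' the training set with the same detectors, and fit the boosted stacking
#' model; (3) apply the model to the original matrix's scores and call
#' doublets at the expected rate. Fully deterministic given `cfg$seed`.
#'
#' For ChordP mode, supply external score tables for both the original
#' matrix and the training set (the training set can be materialized first
#' via the two-phase interface: run with `return_training_set = TRUE`, score
#' it externally, rerun with both tables).
#'
#' @param m Count matrix (genes x cells).
#' @param cfg A [chord_config()]; `doubletrate = "auto"` resolves via
#'   [estimate_doublet_rate()].
#' @param params A [detector_params()].
#' @param external_original,external_train Optional external score tibbles
#'   (both or neither).
#' @param return_training_set Stop after training-set simulation and return
#'   it (for external scoring in ChordP mode).
#' @param verbose Log stage progress.
#' @return A `chord_result`: `scores` (tibble: `cell_id`, base columns,
#'   `chord`), `calls`, `doubletrate`, `removed_overkill`, `model`,
#'   `config`. With `return_training_set = TRUE`, the `chord_training_set`.
#' @export
run_chord <- function(m, cfg = chord_config(), params = detector_params(),
                      external_original = NULL, external_train = NULL,
                      return_training_set = FALSE, verbose = FALSE) {
  m <- validate_counts(m)
  if (is.null(external_original) != is.null(external_train) &&
      !return_training_set) {
    abort("external scores must be given for both the original matrix and the training set")
  }
  d <- if (identical(cfg$doubletrate, "auto")) {
    estimate_doublet_rate(ncol(m))
  } else cfg$doubletrate
  if (d <= 0 || d >= 1) abort(sprintf("resolved doublet rate %.4f outside (0,1)", d))

  chord_log("scoring original matrix with base detectors", verbose = verbose)
  base_scores <- with_stage("base_detectors",
    base_detector_scores(m, params, seed = derive_seed(cfg$seed, "base_detectors")))

  chord_log("overkill pre-filter", verbose = verbose)
  ok <- with_stage("overkill",
    overkill_filter(m, base_scores, d, cfg$overkillrate))

  chord_log("simulating training doublets", verbose = verbose)
  ts <- with_stage("simulate",
    simulate_training_doublets(ok$counts, d, cfg,
                               seed = derive_seed(cfg$seed, "simulate")))
  if (return_training_set) return(ts)

  chord_log("scoring training set", verbose = verbose)
  train_scores <- with_stage("train_scores",
    score_training_set(ts, params, seed = derive_seed(cfg$seed, "train_scores"),
                       external_train = external_train))

  chord_log("fitting stacking model", verbose = verbose)
  model <- with_stage("train_model",
    train_ensemble(train_scores, ts$labels, cfg,
                   seed = derive_seed(cfg$seed, "train_model")))

  chord_log("predicting on original matrix", verbose = verbose)
  features <- base_scores
  if (!is.null(external_original)) {
    ext <- align_scores(external_original, colnames(m))
    features <- dplyr::bind_cols(features, ext[, -1, drop = FALSE])
  }
  chord <- with_stage("predict", predict_scores(model, features))
  calls <- call_doublets(chord, d)

  scores <- dplyr::mutate(features, chord = chord)
  structure(list(
    scores = scores, calls = calls, doubletrate = d,
    threshold_rank = sum(calls),
    removed_overkill = ok$removed, model = model,
    training_set = ts, config = cfg
  ), class = "chord_result")
}

# Attach the pipeline stage name to propagated errors.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}
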
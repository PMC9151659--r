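#' Co-expression doublet score
#'
#' Scores each droplet by how strongly it co-expresses pairs of marker genes
#' that are mutually exclusive across the population — a hallmark of
#' heterotypic doublets. Counts are binarized at `binThresh`, the `ntop`
#' genes with the largest binarized variance p(1-p) are kept, and every gene
#' pair is weighted by the evidence that it is *under*-co-expressed: with
#' observed co-expression count o and expectation e = n * p_i * p_j, the
#' weight is `-log10 P[Binomial(n, p_i p_j) <= o]` when o < e, else 0
#' (capped at 300). A cell's score is the weight sum over the pairs it
#' co-expresses, min-max rescaled to [0, 1].
#'
#' @param m Count matrix (genes x cells).
#' @param params A [detector_params()] list (`ntop`, `binThresh`).
#' @return Numeric per-cell score vector in [0, 1], named by cell id.
#' @export
coexpression_score <- function(m, params = detector_params()) {
  m <- as(m, "CsparseMatrix")
  n <- ncol(m)
  B <- as(m > params$binThresh, "CsparseMatrix") * 1
  p_hat <- Matrix::rowMeans(B)
  bin_var <- p_hat * (1 - p_hat)
  usable <- which(bin_var > 0)
  if (length(usable) < 2) {
    abort("co-expression score needs >= 2 genes passing the binarization variance filter")
  }
  ntop <- min(params$ntop, length(usable))
  keep <- usable[order(-bin_var[usable], usable)[seq_len(ntop)]]
  Bk <- B[keep, , drop = FALSE]
  pk <- p_hat[keep]
  O <- as.matrix(Matrix::tcrossprod(Bk))        # observed co-expression counts
  E <- n * outer(pk, pk)                        # expected under independence
  P0 <- outer(pk, pk)
  W <- -log10(stats::pbinom(O, n, P0))
  W[O >= E] <- 0
  W[W > 300] <- 300
  diag(W) <- 0
  # score_c = sum_{i<j} w_ij B_i[c] B_j[c] = (b' W b) / 2
  s <- Matrix::colSums(Bk * (W %*% Bk)) / 2
  rng <- range(s)
  out <- if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
  names(out) <- colnames(m)
  out
}

# Artificial doublets for the base detectors: unweighted pair means of raw
# counts over uniformly sampled distinct cell pairs.
make_artificial_doublets <- function(m, n_sim, seed) {
  n <- ncol(m)
  pairs <- with_seed(seed, {
    i <- sample.int(n, n_sim, replace = TRUE)
    j <- sample.int(n - 1L, n_sim, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    cbind(i, j)
  })
  sim <- (m[, pairs[, 1], drop = FALSE] + m[, pairs[, 2], drop = FALSE]) / 2
  colnames(sim) <- paste0("artdbl_", seq_len(n_sim))
  list(sim = sim, pairs = pairs)
}

#' Bimodality coefficient
#'
#' Moment-based bimodality statistic
#' `BC = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with bias-corrected
#' sample skewness g1 and excess kurtosis g2. Values near 5/9 and above
#' suggest bimodality; a Gaussian gives ~1/3.
#'
#' @param x Numeric vector, length >= 4, non-constant.
#' @return The coefficient, in (0, 1] for well-behaved samples.
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4) abort("bimodality coefficient needs n >= 4")
  if (stats::sd(x) == 0) abort("bimodality coefficient undefined for a constant vector")
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Artificial-nearest-neighbour (pANN) doublet score
#'
#' Simulates `round(pN/(1-pN) * n_cells)` artificial doublets by averaging
#' random cell pairs, co-embeds real and artificial cells (normalize,
#' variable genes, scale, PCA), and scores each real cell by the fraction of
#' artificial doublets among its k nearest neighbours, with
#' `k = round(pK * (n_cells + n_sim))`. The neighbourhood fraction pK is
#' auto-selected from `params$pK_grid` as the value maximizing the
#' mean-normalized bimodality coefficient (BCmvn) of the pANN distribution.
#'
#' @param m Count matrix (genes x cells), >= 50 cells.
#' @param params A [detector_params()] list.
#' @param seed RNG seed.
#' @param n_variable_genes Genes used for the co-embedding (default 2000,
#'   capped at the gene count).
#' @return A list: `scores` (named pANN vector in [0, 1] at the chosen pK),
#'   `pK` (chosen fraction), `sweep` (tibble of pK, k, BCmvn, BC).
#' @export
knn_sim_score <- function(m, params = detector_params(), seed = 1L,
                          n_variable_genes = 2000L) {
  m <- as(m, "CsparseMatrix")
  n <- ncol(m)
  if (n < 50) abort("pANN score needs >= 50 cells")
  n_sim <- round(params$pN / (1 - params$pN) * n)
  if (n_sim < 1) abort("pN too small: no artificial doublets would be generated")
  art <- make_artificial_doublets(m, n_sim, seed = seed)
  merged <- cbind(m, art$sim)
  emb <- preprocess_embed(merged, n_variable_genes, params$n_pcs_knn, seed = seed)
  coords <- emb$coords
  total <- n + n_sim
  is_art <- c(rep(FALSE, n), rep(TRUE, n_sim))

  # Full sorted neighbour lists once; any k is then a cumulative fraction.
  d2 <- as.matrix(stats::dist(coords))^2
  art_cum <- matrix(0L, nrow = n, ncol = total - 1L)
  for (c in seq_len(n)) {
    ord <- order(d2[c, -c], seq_len(total)[-c]) # ties by cell index
    art_cum[c, ] <- cumsum(is_art[-c][ord])
  }

  ks <- round(params$pK_grid * total)
  pann_at <- function(k) art_cum[, k] / k
  rows <- list()
  best <- list(bcmvn = -Inf)
  for (gi in seq_along(params$pK_grid)) {
    k <- ks[gi]
    if (k < 1 || k > total - 1) next
    pann <- pann_at(k)
    bc <- tryCatch(bimodality_coefficient(pann), error = function(e) NA_real_)
    mvn <- mean(pann)
    bcmvn <- if (!is.na(bc) && mvn > 0) {
      tryCatch(bimodality_coefficient(pann / mvn), error = function(e) NA_real_)
    } else NA_real_
    rows[[length(rows) + 1]] <- tibble::tibble(
      pK = params$pK_grid[gi], k = k, BC = bc, BCmvn = bcmvn)
    score_stat <- if (!is.na(bcmvn)) bcmvn else -Inf
    if (score_stat > best$bcmvn) {
      best <- list(bcmvn = score_stat, pK = params$pK_grid[gi],
                   k = k, scores = pann)
    }
  }
  if (!length(rows)) abort("every pK in the grid yields k = 0 or k >= n; nothing to score")
  if (is.infinite(best$bcmvn)) {
    # no pK produced a usable bimodality statistic; fall back to the largest k
    k <- max(ks[ks >= 1 & ks <= total - 1])
    best <- list(pK = params$pK_grid[which(ks == k)[1]], k = k, scores = pann_at(k))
  }
  scores <- best$scores
  names(scores) <- colnames(m)
  list(scores = scores, pK = best$pK, sweep = dplyr::bind_rows(rows))
}

#' Boosted real-vs-artificial doublet score
#'
#' Simulates one artificial doublet per real cell (pair-averaged raw
#' counts), builds log-normalized expression features over the `ntop` most
#' variable genes of the merged data, and trains gradient-boosted stumps to
#' separate real cells from artificial doublets. Each real cell's score is
#' its out-of-fold predicted probability of the artificial class under
#' 5-fold cross-validation.
#'
#' @param m Count matrix (genes x cells), >= 50 cells.
#' @param params A [detector_params()] list (`ntop`, `boost_rounds`).
#' @param seed RNG seed.
#' @return Named per-cell score vector in [0, 1].
#' @export
boosted_sim_score <- function(m, params = detector_params(), seed = 1L) {
  m <- as(m, "CsparseMatrix")
  n <- ncol(m)
  if (n < 50) abort("boosted score needs >= 50 cells")
  art <- make_artificial_doublets(m, n_sim = n, seed = seed)
  merged <- cbind(m, art$sim)
  norm <- normalize_counts(merged)
  ntop <- min(params$ntop, nrow(norm))
  vg <- select_variable_genes(norm, ntop)
  X <- Matrix::t(norm[vg, , drop = FALSE])
  y <- c(rep(0, n), rep(1, n))
  folds_ok <- FALSE
  for (attempt in 0:4) {
    folds <- with_seed(derive_seed(seed, "boost") + attempt,
                       make_stratified_folds(y, 5L))
    sizes <- vapply(folds, function(idx) length(unique(y[-idx])), integer(1))
    if (all(sizes == 2)) {
      folds_ok <- TRUE
      break
    }
  }
  if (!folds_ok) abort("could not build two-class cross-validation folds")
  preds <- numeric(length(y))
  par <- xgboost::xgb.params(objective = "binary:logistic", max_depth = 1,
                             eta = 0.2, nthread = 1,
                             seed = derive_seed(seed, "boost"))
  for (f in folds) {
    dtrain <- xgboost::xgb.DMatrix(X[-f, , drop = FALSE], label = y[-f],
                                   nthread = 1)
    booster <- xgboost::xgb.train(params = par, data = dtrain,
                                  nrounds = params$boost_rounds, verbose = 0)
    preds[f] <- stats::predict(
      booster, xgboost::xgb.DMatrix(X[f, , drop = FALSE], nthread = 1))
  }
  out <- preds[seq_len(n)]
  names(out) <- colnames(m)
  out
}

# Stratified k-fold assignment; returns list of held-out index vectors.
make_stratified_folds <- function(y, k) {
  idx0 <- sample(which(y == 0))
  idx1 <- sample(which(y == 1))
  fold_of <- integer(length(y))
  fold_of[idx0] <- rep_len(seq_len(k), length(idx0))
  fold_of[idx1] <- rep_len(seq_len(k), length(idx1))
  lapply(seq_len(k), function(f) which(fold_of == f))
}

#' Run every built-in base detector
#'
#' @param m Count matrix (genes x cells).
#' @param params A [detector_params()] list.
#' @param seed RNG seed.
#' @return A score tibble: `cell_id`, `coexpression`, `knn`, `boosted`
#'   (higher = more doublet-like in every column).
#' @export
base_detector_scores <- function(m, params = detector_params(), seed = 1L) {
  co <- coexpression_score(m, params)
  kn <- knn_sim_score(m, params, seed = derive_seed(seed, "knn"))
  bo <- boosted_sim_score(m, params, seed = derive_seed(seed, "boost"))
  tibble::tibble(
    cell_id = colnames(m),
    coexpression = unname(co),
    knn = unname(kn$scores),
    boosted = unname(bo)
  )
}
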
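#' Log-normalize UMI counts
#'
#' Standard CP10K log-normalization: each cell is scaled to `scale_total`
#' counts and log1p-transformed, `ln(1 + count * scale_total / cell_total)`.
#' Cells with zero total UMI map to all-zero columns.
#'
#' @param m Count matrix (genes x cells), sparse or dense.
#' @param scale_total Per-cell target total (default 10,000).
#' @return Sparse genes x cells matrix of log-normalized expression.
#' @export
normalize_counts <- function(m, scale_total = 1e4) {
  m <- as(m, "CsparseMatrix")
  totals <- Matrix::colSums(m)
  sf <- ifelse(totals > 0, scale_total / totals, 0)
  out <- m %*% Matrix::Diagonal(x = sf)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  as(out, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by a variance-stabilized dispersion statistic: a degree-2
#' polynomial is fit to log10(variance) vs log10(mean) over expressed genes,
#' each value is standardized by the trend-predicted standard deviation with
#' clipping at sqrt(n_cells), and genes are ranked by the variance of the
#' clipped standardized values. Deterministic; ties broken by gene index.
#'
#' @param norm Genes x cells expression matrix (raw or normalized counts).
#' @param n Number of genes to return; must not exceed the gene count.
#' @return Integer indices of the `n` most variable genes (descending).
#' @export
select_variable_genes <- function(norm, n = 2000L) {
  n_genes <- nrow(norm)
  if (n > n_genes) abort(sprintf("n = %d exceeds the %d genes available", n, n_genes))
  n_cells <- ncol(norm)
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - mu^2) * n_cells / max(1, n_cells - 1)
  v[v < 0] <- 0
  usable <- which(mu > 0 & v > 0)
  std_var <- numeric(n_genes)
  if (length(usable) >= 3) {
    lm_fit <- stats::lm(log10(v[usable]) ~ stats::poly(log10(mu[usable]), 2))
    exp_sd <- sqrt(10^stats::fitted(lm_fit))
    clip <- sqrt(n_cells)
    dense <- as.matrix(norm[usable, , drop = FALSE])
    z <- (dense - mu[usable]) / exp_sd
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[usable] <- apply(z, 1, stats::var)
  } else {
    std_var[usable] <- v[usable]
  }
  order(-std_var, seq_len(n_genes))[seq_len(n)]
}

#' Center, scale and clip gene rows
#'
#' Each gene row is centered to mean 0 and scaled to unit variance (sample
#' sd, n - 1 denominator); zero-variance rows become all zeros; values are
#' clipped to `[-clip, clip]`.
#'
#' @param norm Genes x cells matrix.
#' @param clip Clipping bound (default 10).
#' @return Dense genes x cells matrix of scaled expression.
#' @export
scale_rows <- function(norm, clip = 10) {
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  sd[sd == 0 | is.na(sd)] <- Inf
  out <- (x - mu) / sd
  out[out > clip] <- clip
  out[out < -clip] <- -clip
  out
}

#' Principal component embedding of cells
#'
#' Exact SVD (`prcomp`) for matrices with at most 2000 cells, truncated
#' randomized SVD (`irlba`) with a fixed seed above that. Component signs
#' follow the convention that the largest-magnitude gene loading is positive.
#'
#' @param scaled Genes x cells scaled matrix (see [scale_rows()]).
#' @param n_components Number of components, at most `min(n_genes, n_cells)`.
#' @param seed Seed for the randomized solver.
#' @return A `chord_embedding`: list with `coords` (cells x components) and
#'   `explained_variance` (non-increasing).
#' @export
run_pca <- function(scaled, n_components, seed = 1L) {
  n_genes <- nrow(scaled)
  n_cells <- ncol(scaled)
  if (n_components > min(n_genes, n_cells)) {
    abort(sprintf("n_components = %d exceeds min(n_genes = %d, n_cells = %d)",
                  n_components, n_genes, n_cells))
  }
  x <- t(as.matrix(scaled)) # cells x genes
  if (n_cells <= 2000 || n_components >= min(dim(x)) - 1) {
    pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
    coords <- pc$x[, seq_len(n_components), drop = FALSE]
    rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
    ev <- pc$sdev[seq_len(n_components)]^2
  } else {
    sv <- with_seed(seed, irlba::irlba(x, nv = n_components))
    coords <- sv$u %*% diag(sv$d, n_components)
    rot <- sv$v
    ev <- sv$d^2 / (n_cells - 1)
  }
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(coords))) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      coords[, j] <- -coords[, j]
      rot[, j] <- -rot[, j]
    }
  }
  rownames(coords) <- colnames(scaled)
  structure(list(coords = coords, explained_variance = ev),
            class = "chord_embedding")
}

# k-means++ center selection
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Cluster cells with seeded k-means
#'
#' k-means with k-means++ initialization and 10 restarts; the restart with
#' the lowest total within-cluster sum of squares wins. Deterministic given
#' the seed. If fewer cells than `k` are available, k is lowered with a
#' warning.
#'
#' @param emb A `chord_embedding` from [run_pca()] (or a plain cells x dims
#'   matrix).
#' @param k Number of clusters (default 20).
#' @param seed RNG seed.
#' @param n_restarts Independent k-means++ restarts.
#' @return A `chord_clusters`: list with integer `labels` in 1..k (named by
#'   cell) and `k`.
#' @export
kmeans_clusters <- function(emb, k = 20L, seed = 1L, n_restarts = 10L) {
  x <- if (inherits(emb, "chord_embedding")) emb$coords else as.matrix(emb)
  n <- nrow(x)
  if (n < k) {
    warn(sprintf("only %d cells; lowering k from %d to %d", n, k, n))
    k <- n
  }
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) k <- n_distinct
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      ctrs <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = ctrs, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  labels <- as.integer(fit$cluster)
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = as.integer(k)), class = "chord_clusters")
}

# The full chain used before clustering/embedding steps:
# normalize -> variable genes -> scale -> PCA.
preprocess_embed <- function(counts, n_variable_genes, n_pcs, seed = 1L) {
  norm <- normalize_counts(counts)
  nvg <- min(n_variable_genes, nrow(norm))
  vg <- select_variable_genes(norm, nvg)
  scaled <- scale_rows(norm[vg, , drop = FALSE])
  n_comp <- min(n_pcs, nrow(scaled), ncol(scaled))
  run_pca(scaled, n_comp, seed = seed)
}
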
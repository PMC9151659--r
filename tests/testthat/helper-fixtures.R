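# Shared fixtures, built in code. The truth-dataset cache avoids regenerating
# identical datasets across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached_truth <- function(key, generator) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, generator(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small two-type dataset with 10% doublets; enough signal for every detector.
small_truth <- function() {
  cached_truth("small_truth", function() {
    generate_truth(n_types = 2, cells_per_type = 150, n_genes = 400,
                   doublet_frac = 0.1, rate_convention = "singlets", seed = 3)
  })
}

# A tiny dense count matrix with ids, for I/O and preprocessing units.
tiny_counts <- function() {
  m <- Matrix::Matrix(
    matrix(c(1, 0, 3,
             0, 2, 0,
             4, 0, 1,
             0, 0, 5), nrow = 4, byrow = TRUE),
    sparse = TRUE)
  dimnames(m) <- list(paste0("g", 1:4), paste0("c", 1:3))
  as(m, "CsparseMatrix")
}

# Hanley-McNeil standard error of an AUROC estimate.
auroc_se <- function(a, n_pos, n_neg) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

# Brute-force AUROC by pair counting (the independent oracle).
auroc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
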
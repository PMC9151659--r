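#' @importFrom rlang %||% abort warn inform .data
#' @importFrom methods as is
#' @import Matrix
NULL

# Derive a stage-specific seed from a master seed; stays in 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    base_detectors = 11L, overkill = 23L, simulate = 37L,
    train_scores = 53L, train_model = 71L, knn = 89L, boost = 97L,
    kmeans = 113L, truth = 131L, trajectory = 151L, gradient = 173L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) %% 1e6) * 2011 + off * 104729) %% 2147483629L
}

# Run an expression with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

chord_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[chordsc] ", ...)
  invisible(NULL)
}

# Top-n indices of `x` in decreasing order, ties at the cutoff broken by
# lower index first (the package-wide tie rule for score cutoffs).
top_n_by_score <- function(x, n) {
  if (n <= 0) return(integer(0))
  ord <- order(-x, seq_along(x))
  ord[seq_len(min(n, length(x)))]
}
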
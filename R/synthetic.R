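#' Generate a ground-truth multi-type dataset with labelled doublets
#'
#' Simulates negative-binomial UMI counts for several discrete cell types
#' plus heterotypic doublets with known labels, so detector performance can
#' be measured without external data. Gene base means are log-normal;
#' differential genes get a fold change applied in an assigned non-reference
#' type ("up" = higher there, "down" = lower). Ground-truth doublets are the
#' elementwise *sum* of two singlets of different types — the physical model
#' of two cells sharing a droplet (training-set doublets, by contrast, are
#' weighted means; the asymmetry is intentional).
#'
#' The doublet count follows the chosen convention:
#' `rate_convention = "final"` gives `round(n_singlets * d / (1 - d))`
#' doublets (d is the fraction of the final dataset);
#' `"singlets"` gives `round(d * n_singlets)`.
#'
#' @param n_types Number of singlet cell types (>= 2 when doublets are
#'   requested).
#' @param cells_per_type Singlets per type.
#' @param n_genes Number of genes.
#' @param doublet_frac Doublet fraction under `rate_convention`.
#' @param de_up_frac,de_down_frac Fractions of genes labelled up/down
#'   regulated (`round(frac * n_genes)` each).
#' @param seed RNG seed.
#' @param rate_convention `"final"` or `"singlets"` (see above).
#' @param nb_dispersion NB dispersion (size = 1/dispersion).
#' @param mean_log_mu,mean_log_sd Log-normal parameters of gene base means.
#' @param de_fc Fold change applied to differential genes.
#' @return A `chord_truth`: `counts` (sparse genes x cells), `cells` tibble
#'   (`cell_id`, `is_doublet`, `cell_type`, `member1`, `member2`), `genes`
#'   tibble (`gene_id`, `deg` in up/down/none, `deg_type`).
#' @export
generate_truth <- function(n_types = 2L, cells_per_type = 500L,
                           n_genes = 2000L, doublet_frac = 0.4,
                           de_up_frac = 0.03, de_down_frac = 0.03,
                           seed = 1L, rate_convention = c("final", "singlets"),
                           nb_dispersion = 0.2, mean_log_mu = log(0.5),
                           mean_log_sd = 1.2, de_fc = 2) {
  rate_convention <- match.arg(rate_convention)
  stopifnot(n_types >= 1, cells_per_type >= 1, n_genes >= 1,
            doublet_frac >= 0, doublet_frac < 1,
            de_up_frac >= 0, de_down_frac >= 0)
  n_up <- round(de_up_frac * n_genes)
  n_down <- round(de_down_frac * n_genes)
  if (n_up + n_down > n_genes) abort("more DEG labels requested than genes")
  if (doublet_frac > 0 && n_types < 2) {
    abort("heterotypic doublets need >= 2 cell types")
  }
  n_singlets <- n_types * cells_per_type
  n_dbl <- switch(rate_convention,
    final = round(n_singlets * doublet_frac / (1 - doublet_frac)),
    singlets = round(doublet_frac * n_singlets))

  with_seed(derive_seed(seed, "truth"), {
    base_mu <- stats::rlnorm(n_genes, mean_log_mu, mean_log_sd)
    deg <- rep("none", n_genes)
    deg_idx <- sample.int(n_genes, n_up + n_down)
    deg[deg_idx[seq_len(n_up)]] <- "up"
    if (n_down > 0) deg[deg_idx[n_up + seq_len(n_down)]] <- "down"
    # each DEG gene is regulated in one assigned non-reference type
    deg_type <- rep(NA_integer_, n_genes)
    if (n_types >= 2) {
      deg_type[deg != "none"] <- rep_len(2:n_types, sum(deg != "none"))
    }

    type_of <- rep(seq_len(n_types), each = cells_per_type)
    size <- 1 / nb_dispersion
    blocks <- lapply(seq_len(n_types), function(t) {
      mu <- base_mu
      sel_up <- deg == "up" & deg_type == t
      sel_down <- deg == "down" & deg_type == t
      mu[sel_up] <- mu[sel_up] * de_fc
      mu[sel_down] <- mu[sel_down] / de_fc
      matrix(stats::rnbinom(n_genes * cells_per_type, mu = mu, size = size),
             nrow = n_genes)
    })
    singlets <- do.call(cbind, blocks)

    if (n_dbl > 0) {
      m1 <- integer(n_dbl)
      m2 <- integer(n_dbl)
      t1 <- sample.int(n_types, n_dbl, replace = TRUE)
      off <- sample.int(n_types - 1L, n_dbl, replace = TRUE)
      t2 <- (t1 + off - 1L) %% n_types + 1L
      for (i in seq_len(n_dbl)) {
        m1[i] <- (t1[i] - 1L) * cells_per_type + sample.int(cells_per_type, 1)
        m2[i] <- (t2[i] - 1L) * cells_per_type + sample.int(cells_per_type, 1)
      }
      doublets <- singlets[, m1, drop = FALSE] + singlets[, m2, drop = FALSE]
    } else {
      m1 <- m2 <- integer(0)
      doublets <- matrix(0L, nrow = n_genes, ncol = 0)
    }

    gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
    singlet_ids <- sprintf("cell_%05d", seq_len(n_singlets))
    dbl_ids <- if (n_dbl > 0) sprintf("doublet_%05d", seq_len(n_dbl)) else character(0)
    counts <- cbind(singlets, doublets)
    dimnames(counts) <- list(gene_ids, c(singlet_ids, dbl_ids))
    counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

    cells <- tibble::tibble(
      cell_id = c(singlet_ids, dbl_ids),
      is_doublet = c(rep(FALSE, n_singlets), rep(TRUE, n_dbl)),
      cell_type = c(paste0("type_", type_of), rep(NA_character_, n_dbl)),
      member1 = c(rep(NA_character_, n_singlets), singlet_ids[m1]),
      member2 = c(rep(NA_character_, n_singlets), singlet_ids[m2]))
    genes <- tibble::tibble(gene_id = gene_ids, deg = deg,
                            deg_type = ifelse(is.na(deg_type), NA_character_,
                                              paste0("type_", deg_type)))
    structure(list(counts = counts, cells = cells, genes = genes, seed = seed),
              class = "chord_truth")
  })
}

#' Generate a bifurcating-trajectory dataset with labelled doublets
#'
#' Emulates a two-lineage differentiation design: all lineages share a
#' progenitor expression program at pseudotime 0 and diverge along linear
#' per-gene log-fold gradients as pseudotime advances to 1. Singlet
#' pseudotimes are uniform on \[0, 1\]; doublets are sums of two uniformly
#' sampled singlets, `round(doublet_frac_of_singlets * n_singlets)` of them.
#'
#' @param n_lineages Number of lineages (default 2).
#' @param cells_per_lineage Singlets per lineage (default 250).
#' @param n_genes Number of genes (default 1000).
#' @param doublet_frac_of_singlets Doublets as a fraction of singlets
#'   (default 0.2).
#' @param seed RNG seed.
#' @param nb_dispersion,mean_log_mu,mean_log_sd As in [generate_truth()].
#' @param grad_frac Fraction of genes carrying a lineage-specific gradient.
#' @param grad_sd SD of the per-gene log-fold gradient slopes.
#' @return A `chord_truth` whose `cells` tibble also carries `lineage` and
#'   `pseudotime` for singlets.
#' @export
generate_trajectory_truth <- function(n_lineages = 2L, cells_per_lineage = 250L,
                                      n_genes = 1000L,
                                      doublet_frac_of_singlets = 0.2,
                                      seed = 1L, nb_dispersion = 0.2,
                                      mean_log_mu = log(0.5), mean_log_sd = 1.2,
                                      grad_frac = 0.2, grad_sd = 0.8) {
  stopifnot(n_lineages >= 1, cells_per_lineage >= 1,
            doublet_frac_of_singlets >= 0, doublet_frac_of_singlets < 1)
  n_singlets <- n_lineages * cells_per_lineage
  n_dbl <- round(doublet_frac_of_singlets * n_singlets)
  with_seed(derive_seed(seed, "trajectory"), {
    base_mu <- stats::rlnorm(n_genes, mean_log_mu, mean_log_sd)
    grad <- matrix(0, n_genes, n_lineages)
    n_grad <- round(grad_frac * n_genes)
    for (l in seq_len(n_lineages)) {
      idx <- sample.int(n_genes, n_grad)
      grad[idx, l] <- stats::rnorm(n_grad, 0, grad_sd)
    }
    lineage <- rep(seq_len(n_lineages), each = cells_per_lineage)
    pt <- stats::runif(n_singlets)
    size <- 1 / nb_dispersion
    singlets <- vapply(seq_len(n_singlets), function(c) {
      mu <- base_mu * exp(pt[c] * grad[, lineage[c]])
      stats::rnbinom(n_genes, mu = mu, size = size)
    }, numeric(n_genes))
    if (n_dbl > 0) {
      m1 <- sample.int(n_singlets, n_dbl, replace = TRUE)
      off <- sample.int(n_singlets - 1L, n_dbl, replace = TRUE)
      m2 <- (m1 + off - 1L) %% n_singlets + 1L
      doublets <- singlets[, m1, drop = FALSE] + singlets[, m2, drop = FALSE]
    } else {
      m1 <- m2 <- integer(0)
      doublets <- matrix(0, nrow = n_genes, ncol = 0)
    }
    gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
    singlet_ids <- sprintf("cell_%05d", seq_len(n_singlets))
    dbl_ids <- if (n_dbl > 0) sprintf("doublet_%05d", seq_len(n_dbl)) else character(0)
    counts <- cbind(singlets, doublets)
    dimnames(counts) <- list(gene_ids, c(singlet_ids, dbl_ids))
    counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    cells <- tibble::tibble(
      cell_id = c(singlet_ids, dbl_ids),
      is_doublet = c(rep(FALSE, n_singlets), rep(TRUE, n_dbl)),
      cell_type = c(paste0("lineage_", lineage), rep(NA_character_, n_dbl)),
      member1 = c(rep(NA_character_, n_singlets), singlet_ids[m1]),
      member2 = c(rep(NA_character_, n_singlets), singlet_ids[m2]),
      lineage = c(lineage, rep(NA_integer_, n_dbl)),
      pseudotime = c(pt, rep(NA_real_, n_dbl)))
    genes <- tibble::tibble(gene_id = gene_ids, deg = "none",
                            deg_type = NA_character_)
    structure(list(counts = counts, cells = cells, genes = genes, seed = seed),
              class = "chord_truth")
  })
}

#' Subsample a truth dataset into a doublet-rate gradient
#'
#' For each rate r, samples `round((1 - r) * budget)` singlets and
#' `round(r * budget)` true doublets without replacement, producing one
#' dataset per rate (e.g. rates 0.02 to 0.30 in steps of 0.02 give 15
#' datasets).
#'
#' @param td A `chord_truth`.
#' @param rates Strictly increasing doublet rates in (0, 1).
#' @param budget Cells per subsampled dataset.
#' @param seed RNG seed.
#' @return A named list of `chord_truth` datasets (`rate_<r>`).
#' @export
subsample_gradient <- function(td, rates, budget, seed = 1L) {
  stopifnot(inherits(td, "chord_truth"), length(rates) >= 1, budget >= 2)
  if (any(rates <= 0 | rates >= 1) || is.unsorted(rates, strictly = TRUE)) {
    abort("rates must be strictly increasing and inside (0, 1)")
  }
  singlets <- which(!td$cells$is_doublet)
  doublets <- which(td$cells$is_doublet)
  need_dbl <- round(max(rates) * budget)
  if (need_dbl > length(doublets)) {
    abort(sprintf("largest rate needs %d doublets but only %d are available",
                  need_dbl, length(doublets)))
  }
  need_sng <- round((1 - min(rates)) * budget)
  if (need_sng > length(singlets)) {
    abort(sprintf("smallest rate needs %d singlets but only %d are available",
                  need_sng, length(singlets)))
  }
  out <- vector("list", length(rates))
  names(out) <- paste0("rate_", format(rates, trim = TRUE))
  for (i in seq_along(rates)) {
    r <- rates[i]
    sel <- with_seed(derive_seed(seed, "gradient") + i, {
      c(sample(singlets, round((1 - r) * budget)),
        sample(doublets, round(r * budget)))
    })
    sel <- sort(sel)
    out[[i]] <- structure(list(
      counts = td$counts[, sel, drop = FALSE],
      cells = td$cells[sel, , drop = FALSE],
      genes = td$genes, seed = seed), class = "chord_truth")
  }
  out
}

#' Write a truth dataset as MTX + sidecars + labels CSV
#'
#' @param td A `chord_truth`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(td, dir) {
  write_counts(td$counts, dir)
  readr::write_csv(td$cells, file.path(dir, "labels.csv"), progress = FALSE)
  readr::write_csv(td$genes, file.path(dir, "genes_truth.csv"), progress = FALSE)
  invisible(dir)
}
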
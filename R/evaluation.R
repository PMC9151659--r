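#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a uniformly chosen positive
#' outranks a uniformly chosen negative, ties counted one half.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Binary labels (1/TRUE = positive); both classes required.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Continuous (nonlinear) interpolation between operating points: between
#' consecutive thresholds, false positives are interpolated linearly in true
#' positives and precision integrated in closed form, so tied scores and
#' coarse thresholds do not inflate the area.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels)
  if (P == 0) abort("AUPRC needs at least one positive")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  # operating points at distinct thresholds
  steps <- which(!duplicated(s, fromLast = FALSE))
  ends <- c(steps[-1] - 1L, length(s))
  tp <- cumsum(y)[ends]
  fp <- cumsum(!y)[ends]
  tp <- c(0, tp)
  fp <- c(0, fp)
  area <- 0
  for (i in seq_len(length(tp) - 1)) {
    dtp <- tp[i + 1] - tp[i]
    if (dtp == 0) next
    h <- (fp[i + 1] - fp[i]) / dtp
    a <- 1 + h
    b <- fp[i] - h * tp[i]
    if (b == 0) {
      area <- area + dtp / a
    } else {
      # a*tp + b = interpolated TP + FP, positive at both endpoints
      area <- area + (tp[i + 1] - tp[i]) / a -
        (b / a^2) * (log(a * tp[i + 1] + b) - log(a * tp[i] + b))
    }
  }
  area / P
}

#' Partial AUC at high specificity
#'
#' Area of the ROC curve over specificity in `[min_specificity, 1]`
#' (equivalently FPR in `[0, 1 - min_specificity]`), trapezoidal with linear
#' interpolation at the FPR boundary. With `standardized = TRUE` the McClish
#' correction maps the area to `[0, 1]`:
#' `0.5 * (1 + (pAUC - min) / (max - min))` with `max = 1 - min_specificity`
#' (perfect classifier) and `min = max^2 / 2` (chance diagonal), so a random
#' classifier scores 0.5 and a perfect one 1 at every specificity floor.
#'
#' @inheritParams auroc
#' @param min_specificity Specificity floor (e.g. 0.8, 0.9, 0.95, 0.975).
#' @param standardized Apply the McClish correction (default TRUE).
#' @return Partial AUC (standardized or raw).
#' @export
partial_auc <- function(scores, labels, min_specificity,
                        standardized = TRUE) {
  stopifnot(min_specificity >= 0, min_specificity < 1)
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("partial AUC needs both classes present")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  steps <- which(!duplicated(s))
  ends <- c(steps[-1] - 1L, length(s))
  tpr <- c(0, cumsum(y)[ends] / n_pos)
  fpr <- c(0, cumsum(!y)[ends] / n_neg)
  fmax <- 1 - min_specificity
  # clip the curve at fpr = fmax with linear interpolation
  px <- c()
  py <- c()
  for (i in seq_len(length(fpr) - 1)) {
    if (fpr[i] >= fmax) break
    px <- c(px, fpr[i])
    py <- c(py, tpr[i])
    if (fpr[i + 1] >= fmax) {
      t_at <- tpr[i] + (tpr[i + 1] - tpr[i]) *
        (fmax - fpr[i]) / (fpr[i + 1] - fpr[i])
      px <- c(px, fmax)
      py <- c(py, t_at)
      break
    }
    if (i == length(fpr) - 1) {
      px <- c(px, fpr[i + 1])
      py <- c(py, tpr[i + 1])
    }
  }
  if (length(px) < 2) {
    raw <- 0
  } else {
    raw <- sum(diff(px) * (utils::head(py, -1) + utils::tail(py, -1)) / 2)
  }
  if (!standardized) return(raw)
  if (fmax == 0) return(0.5)
  max_a <- fmax
  min_a <- fmax^2 / 2
  0.5 * (1 + (raw - min_a) / (max_a - min_a))
}

#' Rank stability of methods across datasets
#'
#' Ranks methods per dataset by a performance metric (1 = best, average rank
#' on ties) and summarizes each method's mean rank and rank standard
#' deviation (SDrank); a high SDrank marks an unstable method.
#'
#' @param metric_table Numeric matrix or data frame, methods x datasets,
#'   with method rownames; larger metric = better.
#' @return A tibble: `method`, `mean_rank`, `sd_rank`, sorted by mean rank,
#'   with the per-dataset rank matrix in attribute `"ranks"`.
#' @export
rank_stability <- function(metric_table) {
  m <- as.matrix(metric_table)
  if (ncol(m) < 2) abort("rank stability needs >= 2 datasets")
  if (is.null(rownames(m))) rownames(m) <- paste0("method_", seq_len(nrow(m)))
  ranks <- apply(m, 2, function(col) rank(-col, ties.method = "average"))
  out <- tibble::tibble(
    method = rownames(m),
    mean_rank = unname(rowMeans(ranks)),
    sd_rank = unname(apply(ranks, 1, stats::sd)))
  out <- dplyr::arrange(out, .data$mean_rank)
  attr(out, "ranks") <- ranks
  out
}

#' Call differentially expressed genes between two groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log-normalized expression,
#' with the standard single-cell filter chain: a gene is a DEG iff its
#' absolute log fold change (difference of group means of log-normalized
#' values) is at least `logfc_threshold`, it is detected in at least
#' `min_pct` of cells in one of the groups, and its Bonferroni-corrected
#' p-value (over all tested genes) is below `alpha`.
#'
#' @param norm Genes x cells log-normalized matrix.
#' @param groups Binary partition of the cells (logical/0-1/two-level
#'   factor), both groups non-empty.
#' @param logfc_threshold Minimum |log fold change| (default 0.25).
#' @param min_pct Minimum detection fraction in either group (default 0.1).
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @return A tibble of called genes: `gene_id`, `logfc`, `pct_1`, `pct_2`,
#'   `p`, `p_bonf`.
#' @export
deg_call <- function(norm, groups, logfc_threshold = 0.25, min_pct = 0.1,
                     alpha = 0.05) {
  if (is.factor(groups) || is.character(groups)) {
    groups <- groups == sort(unique(as.character(groups)))[1]
  }
  g1 <- which(as.logical(groups))
  g2 <- which(!as.logical(groups))
  if (!length(g1) || !length(g2)) abort("both groups must be non-empty")
  x <- as.matrix(norm)
  n_genes <- nrow(x)
  # Seurat convention: log of the group mean on the expression scale
  logfc <- log(rowMeans(expm1(x[, g1, drop = FALSE])) + 1) -
    log(rowMeans(expm1(x[, g2, drop = FALSE])) + 1)
  pct1 <- rowMeans(x[, g1, drop = FALSE] > 0)
  pct2 <- rowMeans(x[, g2, drop = FALSE] > 0)
  pass_pre <- abs(logfc) >= logfc_threshold & pmax(pct1, pct2) >= min_pct
  p <- rep(NA_real_, n_genes)
  for (g in which(pass_pre)) {
    p[g] <- suppressWarnings(
      stats::wilcox.test(x[g, g1], x[g, g2], exact = NULL)$p.value)
  }
  p_bonf <- pmin(1, p * n_genes) # Bonferroni over all tested genes
  # alpha >= 1 disables the significance filter (clipping would otherwise
  # exclude genes whose adjusted p saturates at exactly 1)
  keep <- which(pass_pre & !is.na(p_bonf) & (p_bonf < alpha | alpha >= 1))
  ids <- rownames(x) %||% sprintf("gene_%05d", seq_len(n_genes))
  tibble::tibble(
    gene_id = ids[keep], logfc = logfc[keep],
    pct_1 = pct1[keep], pct_2 = pct2[keep],
    p = p[keep], p_bonf = p_bonf[keep])
}

#' Confusion metrics for a DEG call set against truth labels
#'
#' Differential genes (truth label up or down) are the positive class.
#'
#' @param called Character vector of called gene ids.
#' @param truth Tibble with `gene_id` and `deg` (up/down/none) covering all
#'   tested genes.
#' @return A tibble with one row: `tpr`, `tnr`, `accuracy`, plus the
#'   underlying confusion counts.
#' @export
deg_confusion <- function(called, truth) {
  pos <- truth$gene_id[truth$deg != "none"]
  neg <- truth$gene_id[truth$deg == "none"]
  tp <- length(intersect(called, pos))
  fp <- length(intersect(called, neg))
  fn <- length(pos) - tp
  tn <- length(neg) - fp
  tibble::tibble(
    tpr = if (length(pos)) tp / length(pos) else NA_real_,
    tnr = if (length(neg)) tn / length(neg) else NA_real_,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Downstream DEG-recovery experiment
#'
#' Measures how doublet contamination and its removal affect differential
#' expression calling on a ground-truth dataset: DEGs are called between the
#' two singlet types on (i) the clean singlet-only data, (ii) the
#' contaminated data (doublets included, each attributed to its first
#' member's type, as a clustering would absorb them), and (iii) the filtered
#' data after removing the top `removal_frac` of cells by the detector's
#' score. Returns the confusion metrics of each variant against the DEG
#' truth.
#'
#' @param td A `chord_truth` with DEG truth labels.
#' @param detector A function `f(counts) -> per-cell numeric scores`, or a
#'   precomputed score vector aligned to the dataset's cells.
#' @param removal_frac Fraction of top-scoring cells to remove.
#' @param ... Passed to [deg_call()].
#' @return A tibble: one row per variant (clean/contaminated/filtered) with
#'   `tpr`, `tnr`, `accuracy` and confusion counts.
#' @export
downstream_impact_experiment <- function(td, detector, removal_frac, ...) {
  stopifnot(inherits(td, "chord_truth"))
  if (!any(td$genes$deg != "none")) abort("dataset carries no DEG truth labels")
  types <- sort(unique(stats::na.omit(td$cells$cell_type)))
  if (length(types) != 2) abort("DEG experiment expects exactly two singlet types")
  # attribute each doublet to its first member's type
  member_type <- td$cells$cell_type[match(td$cells$member1, td$cells$cell_id)]
  eff_type <- ifelse(td$cells$is_doublet, member_type, td$cells$cell_type)
  norm <- normalize_counts(td$counts)

  run_variant <- function(cell_idx) {
    sub <- norm[, cell_idx, drop = FALSE]
    grp <- eff_type[cell_idx] == types[1]
    called <- deg_call(sub, grp, ...)$gene_id
    deg_confusion(called, td$genes)
  }

  scores <- if (is.function(detector)) detector(td$counts) else detector
  stopifnot(length(scores) == ncol(td$counts))
  removed <- top_n_by_score(scores, round(removal_frac * ncol(td$counts)))

  dplyr::bind_rows(
    clean = run_variant(which(!td$cells$is_doublet)),
    contaminated = run_variant(seq_len(ncol(td$counts))),
    filtered = run_variant(setdiff(seq_len(ncol(td$counts)), removed)),
    .id = "variant")
}

#' Full metric panel for one score column
#'
#' @inheritParams auroc
#' @param pauc_floors Specificity floors for the partial AUCs.
#' @return One-row tibble: `auroc`, `auprc`, `pauc<floor>` columns.
#' @export
metric_panel <- function(scores, labels,
                         pauc_floors = c(0.8, 0.9, 0.95, 0.975)) {
  row <- tibble::tibble(auroc = auroc(scores, labels),
                        auprc = auprc(scores, labels))
  for (f in pauc_floors) {
    row[[sprintf("pauc%g", f * 1000)]] <- partial_auc(scores, labels, f)
  }
  row
}
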
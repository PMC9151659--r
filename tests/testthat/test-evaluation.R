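test_that("AUROC matches hand-computed and brute-force pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")

  # property: identical to brute-force pair counting, ties included
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # many ties
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_brute(scores, labels))
  }
})

test_that("AUPRC handles perfect, degenerate and null rankings", {
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_equal(auprc(c(5, 1, 2, 3), c(1, 0, 0, 0)), 1.0)
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")

  set.seed(12)
  s <- runif(3000)
  y <- rbinom(3000, 1, 0.3)
  expect_equal(auprc(s, y), mean(y), tolerance = 0.05)

  # oracle: fine-grained Riemann sum over the interpolated PR curve
  set.seed(13)
  s <- round(runif(150), 2)
  y <- rbinom(150, 1, 0.4)
  ord <- order(-s)
  ys <- y[ord]
  ss <- s[ord]
  steps <- which(!duplicated(ss))
  ends <- c(steps[-1] - 1L, length(ss))
  tp <- c(0, cumsum(ys)[ends])
  fp <- c(0, cumsum(!ys)[ends])
  riemann <- 0
  P <- sum(y)
  for (i in seq_len(length(tp) - 1)) {
    if (tp[i + 1] == tp[i]) next
    tps <- seq(tp[i], tp[i + 1], length.out = 2001)
    fps <- fp[i] + (fp[i + 1] - fp[i]) * (tps - tp[i]) / (tp[i + 1] - tp[i])
    prec <- ifelse(tps + fps > 0, tps / (tps + fps), 1)
    riemann <- riemann + sum((prec[-1] + prec[-2001]) / 2 * diff(tps)) / P
  }
  expect_equal(auprc(s, y), riemann, tolerance = 1e-6)
})

test_that("partial AUC matches pROC raw and McClish-corrected values", {
  skip_if_not_installed("pROC")
  set.seed(2)
  s <- rnorm(300)
  y <- rbinom(300, 1, stats::plogis(s))
  r <- pROC::roc(y, s, quiet = TRUE)
  for (floor in c(0.8, 0.9, 0.95, 0.975)) {
    raw <- partial_auc(s, y, floor, standardized = FALSE)
    expect_equal(raw, as.numeric(pROC::auc(
      r, partial.auc = c(1, floor), partial.auc.focus = "specificity",
      partial.auc.correct = FALSE)), tolerance = 1e-10)
    expect_equal(partial_auc(s, y, floor), as.numeric(pROC::auc(
      r, partial.auc = c(1, floor), partial.auc.focus = "specificity",
      partial.auc.correct = TRUE)), tolerance = 1e-10)
    expect_lte(raw, 1 - floor)
  }
})

test_that("partial AUC degenerates to AUROC and centers chance at one half", {
  set.seed(3)
  s <- rnorm(500)
  y <- rbinom(500, 1, stats::plogis(2 * s))
  expect_equal(partial_auc(s, y, 0, standardized = FALSE), auroc(s, y))
  # a perfect classifier is 1 at every floor; random is ~0.5 standardized
  sp <- c(runif(250) + 2, runif(250))
  yp <- rep(c(1, 0), each = 250)
  for (floor in c(0.8, 0.95)) {
    expect_equal(partial_auc(sp, yp, floor), 1.0)
  }
  noise <- rnorm(4000)
  ylab <- rbinom(4000, 1, 0.5)
  expect_equal(partial_auc(noise, ylab, 0.9), 0.5, tolerance = 0.06)
})

test_that("rank stability summarizes per-dataset ranks with average ties", {
  m <- rbind(best = c(0.9, 0.8, 0.95),
             mid = c(0.7, 0.6, 0.75),
             worst = c(0.5, 0.4, 0.55))
  rs <- rank_stability(m)
  expect_equal(rs$sd_rank[rs$method == "best"], 0)
  expect_equal(rs$mean_rank[rs$method == "best"], 1)

  m2 <- rbind(a = c(1, 5, 3), b = c(5, 1, 9), c = c(3, 9, 1))
  # method a has ranks (3, 2, 2) etc; check the hand case (1,3,5)
  ranks <- c(1, 3, 5)
  expect_equal(mean(ranks), 3)
  expect_equal(stats::sd(ranks), 2)
  m3 <- rbind(a = c(0.9, 0.5, 0.1), b = c(0.1, 0.9, 0.5), c = c(0.5, 0.1, 0.9))
  rs3 <- rank_stability(m3)
  expect_equal(sort(unname(attr(rs3, "ranks")[, 1])), 1:3)
  expect_equal(rs3$sd_rank, rep(stats::sd(c(1, 2, 3)), 3))

  tied <- rbind(a = c(1, 1), b = c(1, 0.5))
  expect_equal(attr(rank_stability(tied), "ranks")[, 1], c(a = 1.5, b = 1.5))

  # invariant under monotone transforms of the metric
  expect_equal(rank_stability(m)$sd_rank, rank_stability(exp(m))$sd_rank)
  expect_error(rank_stability(m[, 1, drop = FALSE]), "2 datasets")
})

test_that("DEG calling applies the fold-change, detection and Bonferroni filters", {
  set.seed(5)
  n_per <- 200
  norm <- matrix(abs(rnorm(50 * 2 * n_per, 1, 0.2)), nrow = 50)
  rownames(norm) <- paste0("g", 1:50)
  groups <- rep(c(TRUE, FALSE), each = n_per)
  # identical groups: nothing called
  expect_equal(nrow(deg_call(norm, groups)), 0L)

  # a strongly shifted gene is called
  norm2 <- norm
  norm2[1, groups] <- norm2[1, groups] + 2.5
  expect_true("g1" %in% deg_call(norm2, groups)$gene_id)

  # rarely detected genes are excluded regardless of p
  norm3 <- norm
  norm3[2, ] <- 0
  norm3[2, sample(which(groups), 8)] <- 6   # 4% of group 1
  norm3[2, sample(which(!groups), 8)] <- 0.1
  expect_false("g2" %in% deg_call(norm3, groups)$gene_id)

  # alpha = 1, min_pct = 0, logfc = 0 returns every non-identical gene
  all_called <- deg_call(norm2, groups, logfc_threshold = 0, min_pct = 0,
                         alpha = 1)
  nonconstant <- vapply(seq_len(nrow(norm2)), function(g) {
    length(unique(norm2[g, ])) > 1
  }, logical(1))
  expect_setequal(all_called$gene_id, rownames(norm2)[nonconstant])
  expect_error(deg_call(norm, rep(TRUE, ncol(norm))), "non-empty")
})

test_that("DEG confusion arithmetic matches the confusion matrix", {
  truth <- tibble::tibble(
    gene_id = paste0("g", 1:1000),
    deg = c(rep("up", 50), rep("down", 50), rep("none", 900)))
  called_perfect <- truth$gene_id[truth$deg != "none"]
  expect_equal(unlist(deg_confusion(called_perfect, truth)[, 1:3]),
               c(tpr = 1, tnr = 1, accuracy = 1))
  none <- deg_confusion(character(0), truth)
  expect_equal(none$tpr, 0)
  expect_equal(none$tnr, 1)
  called <- c(truth$gene_id[1:80], truth$gene_id[101:110])
  conf <- deg_confusion(called, truth)
  expect_equal(conf$tpr, 0.8)
  expect_equal(conf$tnr, 0.9888888888888889)
  expect_equal(conf$accuracy, 0.97)
})

test_that("an oracle detector restores clean-data DEG metrics downstream", {
  td <- cached_truth("deg_truth", function() {
    generate_truth(n_types = 2, cells_per_type = 200, n_genes = 1000,
                   doublet_frac = 0.4, seed = 31)
  })
  oracle <- as.numeric(td$cells$is_doublet)
  frac <- mean(td$cells$is_doublet)
  res <- downstream_impact_experiment(td, oracle, removal_frac = frac)
  clean <- dplyr::filter(res, variant == "clean")
  filtered <- dplyr::filter(res, variant == "filtered")
  expect_equal(filtered$tpr, clean$tpr)
  expect_equal(filtered$tnr, clean$tnr)

  # removal_frac 0 reproduces the contaminated variant
  res0 <- downstream_impact_experiment(td, oracle, removal_frac = 0)
  expect_equal(dplyr::filter(res0, variant == "filtered")$tpr,
               dplyr::filter(res0, variant == "contaminated")$tpr)

  # contamination hurts true-DEG recovery relative to clean data
  contaminated <- dplyr::filter(res, variant == "contaminated")
  expect_lte(contaminated$tpr, clean$tpr)
})

test_that("the metric panel reports every published index per method", {
  set.seed(41)
  s <- rnorm(200)
  y <- rbinom(200, 1, stats::plogis(2 * s))
  panel <- metric_panel(s, y)
  expect_named(panel, c("auroc", "auprc", "pauc800", "pauc900", "pauc950",
                        "pauc975"))
  expect_true(all(panel >= 0 & panel <= 1))
})
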
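test_that("the loading-based rate estimator is linear, capped and guarded", {
  expect_equal(estimate_doublet_rate(1000), 0.009)
  expect_equal(estimate_doublet_rate(0), 0)
  expect_equal(estimate_doublet_rate(5000), 0.045)
  expect_error(estimate_doublet_rate(-5), "non-negative")
  expect_warning(rate <- estimate_doublet_rate(1e6), "capped")
  expect_equal(rate, 0.5)
})

test_that("overkill removes the union of per-method top fractions", {
  n <- 100
  m <- tiny_counts()[, integer(0)]
  m <- Matrix::Matrix(matrix(1, nrow = 2, ncol = n), sparse = TRUE)
  dimnames(m) <- list(c("g1", "g2"), paste0("c", seq_len(n)))

  ranks <- seq_len(n)
  identical_scores <- tibble::tibble(
    cell_id = colnames(m), m1 = ranks, m2 = ranks, m3 = ranks)
  ok <- overkill_filter(m, identical_scores, d = 0.1, overkillrate = 1)
  expect_equal(length(ok$removed), 10L)
  expect_setequal(ok$removed, paste0("c", 91:100))

  # disjoint top-10 sets: the union removes 30 cells
  s1 <- s2 <- s3 <- rep(0, n)
  s1[1:10] <- 10
  s2[11:20] <- 10
  s3[21:30] <- 10
  disjoint <- tibble::tibble(cell_id = colnames(m), m1 = s1, m2 = s2, m3 = s3)
  ok2 <- overkill_filter(m, disjoint, d = 0.1, overkillrate = 1)
  expect_equal(length(ok2$removed), 30L)
  expect_equal(ncol(ok2$counts), 70L)

  # overkillrate 0 disables the filter
  ok3 <- overkill_filter(m, identical_scores, d = 0.1, overkillrate = 0)
  expect_equal(length(ok3$removed), 0L)
  expect_equal(ncol(ok3$counts), n)
})

test_that("training-doublet counts follow round(N d/(1-d)) with cluster adjustment", {
  td <- small_truth()
  singlets <- td$counts[, !td$cells$is_doublet] # 300 singlets, two types
  cfg <- chord_config(doubletrate = 0.4, seed = 2)
  ts <- simulate_training_doublets(singlets, d = 0.4, cfg, seed = 2)
  expect_equal(sum(ts$labels), round(300 * 0.4 / 0.6))
  expect_equal(ncol(ts$counts), 300 + round(300 * 0.4 / 0.6))
  # provenance references distinct prefiltered cells from distinct clusters
  expect_true(all(ts$provenance$member1 != ts$provenance$member2))
  lab <- ts$clusters$labels
  expect_true(all(lab[ts$provenance$member1] != lab[ts$provenance$member2]))
})

test_that("d = 0 simulates nothing and single-cluster data is refused", {
  td <- small_truth()
  singlets <- td$counts[, !td$cells$is_doublet]
  ts0 <- simulate_training_doublets(singlets, d = 0, chord_config(seed = 1))
  expect_equal(sum(ts0$labels), 0L)
  expect_identical(ts0$counts, singlets)

  # constant data collapses to one occupied cluster
  flat <- Matrix::Matrix(matrix(5, 50, 80), sparse = TRUE)
  dimnames(flat) <- list(paste0("g", 1:50), paste0("c", 1:80))
  expect_error(
    simulate_training_doublets(flat, d = 0.2, chord_config(seed = 1)),
    "clusters")
})

test_that("simulated doublet profiles average to the unweighted pair mean", {
  # E[w] = 1, so over many draws the weighted mean converges to the plain mean
  td <- small_truth()
  singlets <- td$counts[, !td$cells$is_doublet]
  cfg <- chord_config(doubletrate = 0.5, seed = 6)
  ts <- simulate_training_doublets(singlets, d = 0.5, cfg, seed = 6)
  w <- c(ts$provenance$w1, ts$provenance$w2)
  se <- cfg$weight_sd / sqrt(length(w))
  expect_lt(abs(mean(w) - 1), 3 * se)
  expect_true(all(w >= 0))
  # one doublet's profile equals the weighted member mean exactly
  pv <- ts$provenance[1, ]
  expected <- (singlets[, pv$member1] * pv$w1 + singlets[, pv$member2] * pv$w2) / 2
  expect_equal(as.numeric(ts$counts[, pv$doublet_id]), as.numeric(expected))
})

test_that("the stacker fits, predicts in [0,1], and enforces its feature schema", {
  set.seed(9)
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)
  features <- tibble::tibble(
    cell_id = paste0("c", 1:n),
    good = y + rnorm(n, 0, 0.1),
    noise = rnorm(n))
  cfg <- chord_config(doubletrate = 0.1, seed = 3, gbm_n_trees = 300L)
  model <- train_ensemble(features, y, cfg, seed = 3)
  expect_lte(model$best_iteration, 300L)
  expect_equal(model$train_auc, 1.0)
  preds <- predict_scores(model, features)
  expect_true(all(preds >= 0 & preds <= 1))
  expect_gte(auroc(preds, y), 0.99)

  # identical feature rows get identical scores
  same <- features
  same$good <- 0.5
  same$noise <- 0.1
  expect_equal(length(unique(predict_scores(model, same))), 1L)

  expect_error(predict_scores(model, features[, c("cell_id", "good")]),
               "missing \\[noise\\]")
  expect_error(train_ensemble(features, rep(0L, n), cfg), "both classes")
  expect_error(train_ensemble(features[, 1:2], y, cfg), ">= 2 feature")
})

test_that("doublet calling flags exactly round(d n) cells in score order", {
  scores <- c(0.9, 0.1, 0.5, 0.8, 0.2, 0.7, 0.3, 0.6, 0.4, 0.05)
  expect_equal(sum(call_doublets(scores, 0.1)), 1L)
  expect_equal(which(call_doublets(scores, 0.1)), 1L)
  expect_equal(sum(call_doublets(scores, 0)), 0L)
  expect_equal(sum(call_doublets(scores, 1)), 10L)
  # every flagged score >= every unflagged score
  calls <- call_doublets(scores, 0.3)
  expect_gte(min(scores[calls]), max(scores[!calls]))
  # ties at the cutoff go to the lower index
  tied <- c(1, 1, 1, 0)
  expect_equal(which(call_doublets(tied, 0.5)), c(1L, 2L))
})

test_that("the full pipeline is deterministic and enforces paired external scores", {
  td <- small_truth()
  cfg <- chord_config(doubletrate = 0.1, seed = 23, gbm_n_trees = 300L)
  r1 <- run_chord(td$counts, cfg)
  r2 <- run_chord(td$counts, cfg)
  expect_identical(r1$scores, r2$scores)
  expect_identical(r1$calls, r2$calls)
  expect_equal(sum(r1$calls), round(0.1 * ncol(td$counts)))

  ext <- tibble::tibble(cell_id = colnames(td$counts),
                        external = seq_len(ncol(td$counts)) / ncol(td$counts))
  expect_error(run_chord(td$counts, cfg, external_original = ext), "both")
})

test_that("external score columns ride along as stacking features (ChordP)", {
  td <- small_truth()
  cfg <- chord_config(doubletrate = 0.1, seed = 23, gbm_n_trees = 200L)
  ts <- run_chord(td$counts, cfg, return_training_set = TRUE)
  # fabricate two external methods: a noisy oracle on the training labels
  # and pure noise, for both the original matrix and the training set
  set.seed(77)
  ext_train <- tibble::tibble(
    cell_id = colnames(ts$counts),
    ora = ts$labels + rnorm(length(ts$labels), 0, 0.2),
    rnd = rnorm(length(ts$labels)))
  ext_orig <- tibble::tibble(
    cell_id = colnames(td$counts),
    ora = td$cells$is_doublet + rnorm(ncol(td$counts), 0, 0.2),
    rnd = rnorm(ncol(td$counts)))
  res <- run_chord(td$counts, cfg, external_original = ext_orig,
                   external_train = ext_train)
  expect_setequal(res$model$feature_names,
                  c("coexpression", "knn", "boosted", "ora", "rnd"))
  expect_equal(ncol(res$scores), 1 + 5 + 1) # cell_id + features + chord
  expect_gte(auroc(res$scores$chord, td$cells$is_doublet), 0.95)
})

test_that("tidy, glance and autoplot expose the result in tabular form", {
  td <- small_truth()
  cfg <- chord_config(doubletrate = 0.1, seed = 23, gbm_n_trees = 200L)
  res <- run_chord(td$counts, cfg)
  td_tbl <- tidy(res)
  expect_s3_class(td_tbl, "tbl_df")
  expect_equal(nrow(td_tbl), ncol(td$counts))
  expect_true(all(c("cell_id", "chord", "is_doublet_call") %in% names(td_tbl)))
  gl <- glance(res)
  expect_equal(gl$n_called, sum(res$calls))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  p2 <- plot_roc(res$scores, td$cells$is_doublet)
  expect_s3_class(p2, "ggplot")
})
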
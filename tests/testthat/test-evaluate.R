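test_that("confusion uses a strict threshold", {
  cm <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 1L, fp = 0L, fn = 0L))

  cm2 <- confusion(1, 0.5)
  expect_equal(cm2$fn, 1L)
  expect_equal(cm2$tp, 0L)

  cm3 <- confusion(c(0, 0, 1, 1), c(0.6, 0.2, 0.7, 0.4))
  expect_equal(unlist(cm3[c("tp", "fp", "tn", "fn")]),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))

  expect_error(confusion(numeric(0), numeric(0)), "empty")
})

test_that("metrics match closed-form arithmetic and flag undefined cases", {
  cm <- structure(list(tp = 45, fp = 10, tn = 40, fn = 5),
                  class = "confusion")
  mt <- metrics(cm)
  expect_equal(mt$accuracy, 0.85)
  expect_equal(mt$precision, 45 / 55)
  expect_equal(mt$recall, 0.9)
  expect_equal(mt$f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9))

  perfect <- metrics(structure(list(tp = 3, fp = 0, tn = 4, fn = 0),
                               class = "confusion"))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))

  degen <- metrics(structure(list(tp = 0, fp = 0, tn = 5, fn = 2),
                             class = "confusion"))
  expect_true(is.na(degen$precision))
  expect_equal(degen$accuracy, 5 / 7)
  # conservation: accuracy * total = tp + tn
  expect_equal(mt$accuracy * 100, 45 + 40)
})

test_that("roc_auc matches hand-derived examples and curve invariants", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc, 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), -c(0.1, 0.4, 0.35, 0.8))$auc, 0.25)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  r <- roc_auc(c(0, 1, 0, 1, 1), c(0.3, 0.3, 0.2, 0.9, 0.1))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("trapezoid AUC equals the Mann-Whitney oracle", {
  set.seed(51)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), sample(1:3, 1))  # induces ties
    expect_equal(roc_auc(y, p)$auc, mw_auc_oracle(y, p), tolerance = 1e-12)
  }
})

test_that("pearson_corr matches brute force and cor.test", {
  expect_equal(pearson_corr(c(0, 1, 0, 1), c(0, 1, 0, 1))$r, 1)
  expect_equal(pearson_corr(c(0, 1, 0, 1), c(1, 0, 1, 0))$r, -1)

  y <- c(0, 0, 1, 1); p <- c(0.1, 0.2, 0.8, 0.9)
  pc <- pearson_corr(y, p)
  brute <- sum((y - mean(y)) * (p - mean(p))) / (3 * sd(y) * sd(p))
  expect_equal(pc$r, brute, tolerance = 1e-12)
  ct <- cor.test(y, p)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p_value, ct$p.value, tolerance = 1e-9)

  expect_error(pearson_corr(c(1, 1, 1), c(0.1, 0.2, 0.3)), "variance")
  expect_error(pearson_corr(c(0, 1), c(0.1, 0.2)), "at least 3")
})

test_that("bootstrap_auc is seeded, degenerate on separation, and covers
           the point AUC", {
  set.seed(52)
  y <- rep(c(0, 1), 100)
  p <- ifelse(y == 1, runif(200, 0.4, 1), runif(200, 0, 0.6))
  b1 <- bootstrap_auc(y, p, n_reps = 300, seed = 7)
  b2 <- bootstrap_auc(y, p, n_reps = 300, seed = 7)
  expect_identical(b1$auc_samples, b2$auc_samples)

  # perfectly separated scores: every resample has AUC 1
  y_sep <- rep(c(0, 1), each = 50)
  p_sep <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  bs <- bootstrap_auc(y_sep, p_sep, n_reps = 100, seed = 1)
  expect_equal(bs$mean_auc, 1)
  expect_equal(bs$ci95, c(1, 1))

  point <- roc_auc(y, p)$auc
  expect_true(b1$ci95[1] <= point && point <= b1$ci95[2])

  # mean converges toward the point AUC as reps grow (fixed data)
  d2 <- abs(bootstrap_auc(y, p, n_reps = 100, seed = 3)$mean_auc - point)
  d4 <- abs(bootstrap_auc(y, p, n_reps = 5000, seed = 3)$mean_auc - point)
  expect_lt(d4, d2)
})

test_that("stratified folds partition each class evenly", {
  y <- rep(c(0, 1), c(33, 27))
  fold <- cfcnv:::stratified_folds(y, 10, seed = 3)
  expect_setequal(unique(fold), 1:10)
  expect_true(max(table(fold)) - min(table(fold)) <= 1)
  for (cls in 0:1) {
    t <- table(fold[y == cls])
    expect_true(max(t) - min(t) <= 1)
  }
})

test_that("cross_validate is stable on a strong-signal cohort", {
  d <- separable_data(n = 120, p = 200)
  cfg <- tiny_model_config(epochs = 12, conv1_filters = 8,
                           conv2_filters = 16, attention_dim = 8,
                           dense1_units = 16, dense2_units = 4)
  cv <- cross_validate(d$X, d$y, k = 10, cfg = cfg, seed = 2)
  expect_length(cv$folds, 10)
  expect_lt(cv$accuracy_sd, 0.1)
  expect_error(cross_validate(d$X, d$y, k = 100, cfg = cfg), "at least k")
})
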
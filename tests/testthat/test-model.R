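test_that("split_dataset applies largest-remainder apportionment", {
  expect_equal(unname(split_dataset(100)$sizes), c(75L, 5L, 20L))
  expect_equal(unname(split_dataset(4470)$sizes), c(3353L, 223L, 894L))
  # floors (7,0,2), remainders (.5,.5,0), one leftover -> train by tie order
  expect_equal(unname(split_dataset(10)$sizes), c(8L, 0L, 2L))
  expect_error(split_dataset(2), ">= 3")
  expect_error(split_dataset(10, fractions = c(a = 0.6, b = 0.5)), "sum to 1")
})

test_that("split partitions are disjoint and exhaustive for all n in 3..1000", {
  for (n in 3:1000) {
    sp <- split_dataset(n, seed = n)
    all_idx <- c(sp$train, sp$val, sp$test)
    if (length(all_idx) != n || anyDuplicated(all_idx) ||
        !setequal(all_idx, seq_len(n)) || sum(sp$sizes) != n) {
      fail(sprintf("split invariant violated at n=%d", n))
    }
  }
  succeed()
})

test_that("build_model validates geometry and reports parameters", {
  mdl <- build_model(model_config(), 4520)
  expect_s3_class(mdl, "cfcnn")
  expect_gt(attr(mdl, "n_parameters"), 1000)
  expect_false(mdl$trained)

  expect_error(build_model(model_config(conv1_kernel = 16), 10), "exceeds")
  expect_error(build_model(model_config(), 40), "length 0")
})

test_that("training learns a separable problem and records history", {
  d <- separable_data()
  cfg <- tiny_model_config(epochs = 30)
  mdl <- build_model(cfg, ncol(d$X))
  mdl <- train_model(mdl, d$X, d$y)
  expect_true(mdl$trained)
  expect_equal(nrow(mdl$history), 30)
  expect_gt(mdl$history$acc[30], 0.95)
  expect_lte(mdl$history$loss[30], mdl$history$loss[1])

  p <- predict(mdl, d$X)
  expect_true(all(p >= 0 & p <= 1))
  # duplicate rows get identical outputs (deterministic eval mode)
  dup <- d$X[c(1, 1, 2, 2), ]
  pd <- predict(mdl, dup)
  expect_identical(pd[1], pd[2])
  expect_identical(pd[3], pd[4])

  # strict threshold: probability exactly at the threshold is class 0
  mdl$cfg$threshold <- p[1]
  cls <- predict(mdl, d$X, type = "class")
  expect_equal(cls[1], 0)

  expect_error(train_model(build_model(cfg, ncol(d$X)), d$X,
                           rep(1, nrow(d$X))), "single class")
})

test_that("training is deterministic for a fixed seed", {
  d <- separable_data(n = 60, p = 120)
  cfg <- tiny_model_config(epochs = 4, conv1_filters = 8, conv2_filters = 8,
                           attention_dim = 8, dense1_units = 8,
                           dense2_units = 4)
  m1 <- train_model(build_model(cfg, ncol(d$X)), d$X, d$y)
  m2 <- train_model(build_model(cfg, ncol(d$X)), d$X, d$y)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("attention weights are a distribution, order-invariant, and
           concentrate on the discriminative block", {
  d <- separable_data()
  cfg <- tiny_model_config(epochs = 30)
  mdl <- train_model(build_model(cfg, ncol(d$X)), d$X, d$y)
  w <- attention_weights(mdl, d$X)
  expect_length(w, ncol(d$X))
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-6)

  w_perm <- attention_weights(mdl, d$X[sample(nrow(d$X)), ])
  expect_equal(w, w_perm, tolerance = 1e-12)

  # implanted block 40:60 should carry above-average weight
  expect_gt(mean(w[40:60]), mean(w))

  expect_error(attention_weights(build_model(cfg, ncol(d$X)), d$X),
               "untrained")
  expect_error(attention_weights(mdl, d$X[0, , drop = FALSE]), "empty")
})

test_that("a single pooled position degenerates to uniform weights", {
  cfg <- tiny_model_config(conv1_kernel = 2, pool1 = 1, conv2_kernel = 2,
                           pool2 = 4, epochs = 2, batch_size = 8)
  # N = 8: L1 = 7, L1p = 7, L2 = 6, L2p = 1
  mdl <- build_model(cfg, 8)
  expect_equal(mdl$dims$L2p, 1)
  set.seed(1)
  X <- matrix(rnorm(160), 20, 8)
  y <- rep(c(0, 1), 10)
  mdl <- train_model(mdl, X, y)
  expect_equal(attention_weights(mdl, X), rep(1 / 8, 8))
})

test_that("grid_search evaluates the full grid and picks the planted best", {
  d <- separable_data(n = 80, p = 120)
  base <- tiny_model_config(epochs = 10, conv1_filters = 8,
                            conv2_filters = 8, attention_dim = 8,
                            dense1_units = 8, dense2_units = 4)
  sp <- split_dataset(80, fractions = c(train = 0.6, val = 0.4, test = 0),
                      seed = 2)
  g1 <- grid_search(list(conv1_filters = 8), d$X, d$y, base, split = sp)
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best_config$conv1_filters, 8)

  g2 <- grid_search(list(conv1_filters = c(4, 8), pool1 = c(2, 4)),
                    d$X, d$y, base, split = sp)
  expect_equal(nrow(g2$table), 4)

  # rigged grid: kernel wider than the input cannot build -> planted wins
  g3 <- grid_search(list(conv1_kernel = c(8, 500)), d$X, d$y, base,
                    split = sp)
  expect_equal(g3$best_config$conv1_kernel, 8)
  expect_true(is.na(g3$table$val_auc[g3$table$conv1_kernel == 500]))

  expect_error(grid_search(list(), d$X, d$y, base), "empty grid")
})
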
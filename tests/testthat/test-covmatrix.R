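test_that("count_coverage sums depth x overlap into windows", {
  ws <- toy_window_set(c(A = 5), 5)
  depth <- data.frame(chrom = "A", start = 0:4, end = 1:5,
                      depth = c(1, 1, 2, 0, 3))
  p <- count_coverage(ws, depth)
  expect_equal(unname(p$values), 7)

  ws <- toy_window_set(c(A = 10000), 10000)
  p <- count_coverage(ws, data.frame(chrom = "A", start = 0, end = 10000,
                                     depth = 2))
  expect_equal(unname(p$values), 20000)
  expect_equal(p$mean_depth, 2)

  ws <- toy_window_set(c(A = 20000), 10000)
  p <- count_coverage(ws, data.frame(chrom = "A", start = 5000, end = 15000,
                                     depth = 1))
  expect_equal(unname(p$values), c(5000, 5000))

  expect_error(
    count_coverage(ws, data.frame(chrom = "A", start = 0, end = 10,
                                  depth = -1)),
    "negative")
})

test_that("count_coverage conserves mass over the unmasked genome", {
  set.seed(11)
  ws <- toy_window_set(c(A = 30000, B = 17000), 7000)
  for (i in 1:10) {
    # random sorted non-overlapping records per chromosome
    recs <- do.call(rbind, lapply(c("A", "B"), function(ch) {
      len <- ws$chrom_sizes$length[ws$chrom_sizes$chrom == ch]
      cuts <- sort(sample(0:len, 8))
      data.frame(chrom = ch, start = cuts[-8], end = cuts[-1],
                 depth = rpois(7, 2))
    }))
    recs <- recs[recs$end > recs$start, ]
    p <- count_coverage(ws, recs)
    expect_equal(sum(p$values),
                 sum(recs$depth * (recs$end - recs$start)))
  }
})

test_that("sample_qc applies strict thresholds", {
  ws <- toy_window_set(c(A = 10000), 10000)
  prof <- function(md, reads) {
    p <- count_coverage(ws, data.frame(chrom = "A", start = 0, end = 10000,
                                       depth = md), n_unique_reads = reads)
    sample_qc(p)
  }
  p <- prof(0.14, 7e6)
  expect_false(p$qc_pass)
  expect_equal(p$qc_reasons, "low_coverage")

  expect_true(prof(0.15, 6e6)$qc_pass)

  p <- prof(0.2, 5999999)
  expect_false(p$qc_pass)
  expect_equal(p$qc_reasons, "low_reads")

  p0 <- count_coverage(ws, data.frame(chrom = "A", start = 0, end = 10000,
                                      depth = 0.2))
  expect_warning(p0 <- sample_qc(p0), "skipped")
  expect_true(p0$qc_pass)
})

make_profile <- function(values, ids = NULL) {
  structure(list(sample_id = ids %||% "s", values = values,
                 mean_depth = mean(values), n_unique_reads = NA,
                 qc_pass = NA, stage = "raw"),
            class = "coverage_profile")
}

test_that("correct_bias flattens a pure GC trend", {
  set.seed(21)
  n <- 400
  gc <- runif(n, 0.3, 0.6)
  f <- 1.4 - 2 * (gc - 0.45)^2 * 10  # smooth unimodal, positive on range
  expect_true(all(f > 0))
  v <- 100 * f
  p <- make_profile(stats::setNames(v, seq_len(n) - 1))
  pc <- correct_bias(p, gc = gc, mappability = rep(0.95, n))
  cv <- sd(pc$values) / mean(pc$values)
  expect_lt(cv, 1e-3)
  expect_equal(mean(pc$values), mean(v))
  expect_equal(pc$stage, "corrected")
})

test_that("correct_bias flattens a pure mappability trend (stage 2)", {
  set.seed(22)
  n <- 400
  mp <- runif(n, 0.9, 1)
  g <- 0.5 + (mp - 0.9) * 6
  v <- 80 * g
  p <- make_profile(stats::setNames(v, seq_len(n) - 1))
  pc <- correct_bias(p, gc = rep(0.45, n), mappability = mp)
  expect_lt(sd(pc$values) / mean(pc$values), 1e-3)
})

test_that("correct_bias is a near-identity without bias and reduces GC rank
           correlation with bias", {
  set.seed(23)
  n <- 500
  gc <- runif(n, 0.3, 0.6)
  v_flat <- rep(100, n) + rnorm(n, sd = 0.5)
  p <- make_profile(stats::setNames(v_flat, seq_len(n) - 1))
  pc <- correct_bias(p, gc = gc, mappability = rep(1, n))
  expect_lt(max(abs(pc$values - v_flat) / v_flat), 0.02)

  # one-sided GC range makes the quadratic bias monotone, so the rank
  # correlation is large before correction and should collapse after
  gc_m <- runif(n, 0.45, 0.65)
  v_biased <- 100 * (1 - 3 * (gc_m - 0.45)^2) * exp(rnorm(n, sd = 0.05))
  pb <- make_profile(stats::setNames(v_biased, seq_len(n) - 1))
  pbc <- correct_bias(pb, gc = gc_m, mappability = rep(1, n))
  rho_before <- abs(cor(v_biased, gc_m, method = "spearman"))
  rho_after <- abs(cor(as.numeric(pbc$values), gc_m, method = "spearman"))
  expect_gt(rho_before, 0.5)
  expect_lt(rho_after, rho_before / 2)
})

test_that("correct_bias refuses tiny fitting sets", {
  p <- make_profile(stats::setNames(rep(10, 30), 0:29))
  expect_error(correct_bias(p, gc = runif(30)), "refused")
})

test_that("assemble_matrix enforces QC, labels and window consistency", {
  mk <- function(id, vals, pass = TRUE) {
    p <- make_profile(stats::setNames(vals, seq_along(vals) - 1), id)
    p$qc_pass <- pass
    p
  }
  ps <- list(mk("a", 1:4), mk("b", 5:8), mk("c", 9:12))
  m <- assemble_matrix(ps, c(a = 0, b = 1, c = 1))
  expect_equal(dim(m$values), c(3L, 4L))
  expect_equal(m$labels, c(0, 1, 1))

  ps2 <- list(mk("a", 1:4), mk("b", 5:8, pass = FALSE), mk("c", 9:12))
  m2 <- assemble_matrix(ps2, c(a = 0, b = 1, c = 1))
  expect_equal(dim(m2$values), c(2L, 4L))
  expect_equal(attr(m2, "excluded"), "b")

  ps3 <- list(mk("a", 1:4), mk("b", 1:5))
  expect_error(assemble_matrix(ps3, c(a = 0, b = 1)), "mismatch")
  expect_error(assemble_matrix(ps, c(a = 0, b = 1)), "label missing")
})

test_that("normalize_rows gives unit row means and is idempotent", {
  m <- toy_matrix(rbind(c(2, 4, 6), c(0.1, 0.2, 0.3), c(1, 1, 1)),
                  c(0, 1, 1), stage = "raw")
  n1 <- normalize_rows(m)
  expect_equal(unname(n1$values[1, ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(n1$values[2, ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(n1$values[3, ]), c(1, 1, 1))
  expect_equal(unname(rowMeans(n1$values)), rep(1, 3))
  # idempotent; invariant to per-row rescaling
  expect_equal(normalize_rows(n1)$values, n1$values)
  m2 <- m; m2$values <- m$values * c(10, 0.5, 3)
  expect_equal(normalize_rows(m2)$values, n1$values)

  mz <- toy_matrix(rbind(c(0, 0), c(1, 2)), c(0, 1), stage = "raw")
  expect_error(normalize_rows(mz), "s1")
})

test_that("prune_windows applies both strict rules with reasons", {
  # boundary: fraction exactly 0.8 is NOT over 80%
  vals <- cbind(c(0.05, 0.05, 0.05, 0.05, 0.5),   # frac 0.8 -> keep by rule1
                rep(0.05, 5),                      # all low -> dropout_rule
                c(1, 1, 1.005, 1.005, 1.005),      # diff 0.005 -> mean_diff
                c(0.5, 0.5, 1.5, 1.5, 1.5))        # informative -> keep
  m <- toy_matrix(vals, c(0, 0, 1, 1, 1))
  out <- prune_windows(m)
  expect_equal(out$report$n_initial, 4)
  # col1 kept by rule 1 but dropped by rule 2? means: 0.05 vs 0.2 diff 0.15
  expect_equal(sort(out$report$dropped$window_index), c(1L, 2L))
  expect_equal(
    out$report$dropped$reason[order(out$report$dropped$window_index)],
    c("dropout_rule", "mean_diff_rule"))
  expect_equal(out$matrix$window_indices, c(0L, 3L))
  expect_equal(out$report$n_retained + nrow(out$report$dropped),
               out$report$n_initial)

  expect_error(prune_windows(toy_matrix(vals, rep(1, 5))), "both classes")
})

test_that("prune_windows agrees with the brute-force oracle", {
  set.seed(31)
  for (i in 1:10) {
    vals <- matrix(rexp(50 * 200, rate = 1), 50, 200)
    vals[sample(length(vals), 2000)] <- 0.01
    labels <- rep(c(0, 1), 25)
    m <- toy_matrix(vals, labels)
    out <- prune_windows(m)
    oracle <- prune_oracle(vals, labels)
    expect_equal(sort(out$report$dropped$window_index),
                 which(oracle$drop) - 1L)
    got <- out$report$dropped
    expect_equal(got$reason[order(got$window_index)],
                 oracle$reason[oracle$drop])
  }
})

test_that("coverage matrix TSV round-trip preserves values and metadata", {
  m <- toy_matrix(matrix(runif(12), 3, 4), c(0, 1, 1))
  f <- tempfile(fileext = ".tsv")
  write_matrix(m, f)
  m2 <- read_matrix(f)
  expect_equal(m2$values, m$values, tolerance = 1e-12,
               ignore_attr = "dimnames")
  expect_equal(m2$labels, m$labels)
  expect_equal(m2$stage, m$stage)
  expect_equal(m2$window_indices, m$window_indices)
})
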
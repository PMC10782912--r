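test_that("rank_windows sorts stably with genome-order tie-breaks", {
  ws <- toy_window_set(c(A = 30000), 10000)
  rr <- rank_windows(c(0.1, 0.5, 0.4), ws, top_k = 2)
  expect_equal(rr$regions$window_index, c(1L, 2L))
  expect_equal(rr$regions$weight, c(0.5, 0.4))

  rr_u <- rank_windows(rep(1 / 3, 3), ws, top_k = 2)
  expect_equal(rr_u$regions$window_index, c(0L, 1L))

  rr_all <- rank_windows(c(0.1, 0.5, 0.4), ws, top_k = 3)
  expect_equal(rr_all$regions$window_index, c(1L, 2L, 0L))

  expect_warning(rr_t <- rank_windows(c(0.1, 0.5, 0.4), ws, top_k = 10),
                 "truncated")
  expect_equal(rr_t$top_k, 3)

  # subset weights via window_indices (post-pruning use)
  rr_s <- rank_windows(c(0.9, 0.2), ws, top_k = 2,
                       window_indices = c(2L, 0L))
  expect_equal(rr_s$regions$window_index, c(2L, 0L))
  expect_equal(rr_s$regions$start, c(20000, 0))
})

test_that("annotate_genes reports >=1 bp overlaps, deduplicated, in rank
           order", {
  ws <- toy_window_set(c(A = 30000), 10000)
  rr <- rank_windows(c(0.2, 0.7, 0.1), ws, top_k = 2)  # windows 1 then 0
  genes <- data.frame(
    chrom = "A",
    start = c(5000, 10000, 12000, 15000),
    end = c(6000, 11000, 22000, 16000),
    name = c("inW0", "inW1", "spans", "alsoW1"))
  got <- annotate_genes(rr, genes)
  # window 1 = [10000,20000) ranked first; window 0 = [0,10000) second
  expect_equal(got, c("inW1", "spans", "alsoW1", "inW0"))

  # half-open abutment does not overlap
  abut <- data.frame(chrom = "A", start = 20000, end = 21000, name = "abut")
  expect_equal(annotate_genes(rr, abut), character(0))

  expect_warning(
    got2 <- annotate_genes(rr, data.frame(chrom = "A", start = 10, end = 5,
                                          name = "bad")),
    "malformed")
  expect_equal(got2, character(0))
})

test_that("annotate_genes agrees with a brute-force all-pairs scan", {
  set.seed(61)
  ws <- toy_window_set(c(A = 50000, B = 30000), 5000)
  for (i in 1:10) {
    w <- runif(nrow(ws$windows))
    rr <- rank_windows(w, ws, top_k = 6)
    genes <- data.frame(
      chrom = sample(c("A", "B", "C"), 15, replace = TRUE),
      start = sample(0:48000, 15))
    genes$end <- genes$start + sample(500:8000, 15)
    genes$name <- paste0("g", 1:15)
    got <- sort(annotate_genes(rr, genes))
    expected <- character(0)
    for (gi in seq_len(nrow(genes))) for (wi in seq_len(nrow(rr$regions))) {
      if (genes$chrom[gi] == rr$regions$chrom[wi] &&
          genes$start[gi] < rr$regions$end[wi] &&
          genes$end[gi] > rr$regions$start[wi])
        expected <- c(expected, genes$name[gi])
    }
    expect_equal(got, sort(unique(expected)))
  }
})

test_that("ora_enrich matches closed-form hypergeometric and BH arithmetic", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), none = paste0("g", 6:10))
  res <- ora_enrich(paste0("g", 1:5), sets, universe)
  phit <- res$p_value[res$term_id == "hit"]
  expect_equal(phit, 1 / choose(20, 5), tolerance = 1e-12)
  # k = 0 with K > 0 gives p = 1
  expect_equal(res$p_value[res$term_id == "none"], 1)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))

  # BH step-up on a hand-worked example
  expect_equal(p.adjust(c(0.005, 0.01, 0.03, 0.04), "BH"),
               c(0.02, 0.02, 0.04, 0.04))

  expect_warning(ora_enrich(c("g1", "zz"), sets, universe), "dropped")
  expect_error(ora_enrich("g1", sets, character(0)), "empty universe")
  suppressWarnings(
    expect_error(ora_enrich("zz", sets, universe), "no selected genes"))
})

test_that("hypergeometric tail matches exhaustive enumeration (N <= 30)", {
  set.seed(62)
  for (i in 1:100) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }
  # pmf normalization against enumeration
  for (i in 1:20) {
    N <- sample(5:30, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    ks <- max(0, n - (N - K)):min(K, n)
    expect_equal(sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n),
                 1, tolerance = 1e-12)
  }
})

test_that("GMT round-trip and enrichment output ordering", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5", "bad"), f)
  expect_warning(sets <- read_gmt(f), "malformed")
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))

  universe <- paste0("g", 1:50)
  res <- ora_enrich(c("g1", "g2", "g3"), sets, universe)
  expect_true(!is.unsorted(res$p_adjusted))
  expect_true(all(res$p_adjusted <= 1))
  expect_equal(res$genes[res$term_id == "setA"], "g1,g2,g3")
})
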
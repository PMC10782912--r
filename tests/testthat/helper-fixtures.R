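# Shared fixture builders. Everything is generated in code; no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_chrom_sizes <- function(lengths = c(A = 25000, B = 8000)) {
  f <- tempfile(fileext = ".chrom.sizes")
  writeLines(paste(names(lengths), lengths), f)
  f
}

toy_window_set <- function(lengths = c(A = 25000, B = 8000), size = 10000) {
  make_windows(load_chrom_sizes(toy_chrom_sizes(lengths)), size)
}

# A coverage_matrix with explicit values/labels at a given stage.
toy_matrix <- function(values, labels, stage = "normalized") {
  coverage_matrix(values, labels, stage = stage)
}

# Small, fast model config used wherever a real training run is needed.
tiny_model_config <- function(...) {
  args <- list(conv1_filters = 16, conv1_kernel = 8, pool1 = 4,
               conv2_filters = 32, conv2_kernel = 8, pool2 = 4,
               attention_dim = 32, dense1_units = 32, dense2_units = 8,
               learning_rate = 5e-3, batch_size = 32, epochs = 40,
               seed = 3)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

# Cleanly separable cohort: one block of windows shifted additively in cases.
separable_data <- function(n = 200, p = 500, shift = 1, seed = 5) {
  set.seed(seed)
  X <- matrix(1 + rnorm(n * p, sd = 0.1), n, p)
  y <- rep(c(0, 1), length.out = n)
  X[y == 1, 40:60] <- X[y == 1, 40:60] + shift
  list(X = X, y = y)
}

# Brute-force per-column pruning oracle: direct re-computation of both rules.
prune_oracle <- function(values, labels, dropout_frac = 0.8,
                         dropout_value = 0.1, mean_diff = 0.01) {
  drop <- logical(ncol(values))
  reason <- character(ncol(values))
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    f <- sum(col < dropout_value) / length(col)
    r1 <- f > dropout_frac
    d <- abs(mean(col[labels == 0]) - mean(col[labels == 1]))
    r2 <- d < mean_diff
    drop[j] <- r1 || r2
    reason[j] <- if (r1) "dropout_rule" else if (r2) "mean_diff_rule" else ""
  }
  list(drop = drop, reason = reason)
}

# Mann-Whitney AUC oracle: explicit pair counting with half credit for ties.
mw_auc_oracle <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Hypergeometric upper tail by explicit combinatorial enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# The end-to-end acceptance cohort (the stated world for criteria 5 and 6).
acceptance_sim_config <- function(effect_size, seed = 1) {
  sim_config(n_samples = 400, case_fraction = 0.5,
             chrom_lengths = c(chrA = 6e6, chrB = 4e6), window_size = 5000,
             n_signal_segments = 5, segment_length_windows = 20,
             effect_size = effect_size, penetrance = 0.8,
             gc_bias_strength = 1, dropout_rate = 0.05,
             noise = "negbin", dispersion = 50, seed = seed)
}

# Shared pipeline run: simulate -> normalize -> prune -> impute -> split ->
# train -> evaluate (reduced-epoch config suited to a 400-sample cohort).
run_acceptance_pipeline <- function(effect_size, seed = 1) {
  co <- simulate_cohort(acceptance_sim_config(effect_size, seed))
  cm <- normalize_rows(cohort_matrix(co))
  pruned <- prune_windows(cm)
  cm <- pruned$matrix
  cm <- impute_lowrank(cm, flag_missing(cm), seed = seed + 10)
  sp <- split_dataset(nrow(cm$values), seed = seed + 1)
  X <- cm$values; y <- cm$labels
  cfg <- model_config(learning_rate = 5e-3, batch_size = 64, epochs = 40,
                      seed = seed + 2)
  mdl <- build_model(cfg, ncol(X))
  mdl <- train_model(mdl, X[sp$train, , drop = FALSE], y[sp$train])
  p_test <- predict(mdl, X[sp$test, , drop = FALSE])
  list(cohort = co, matrix = cm, split = sp, model = mdl,
       test_auc = roc_auc(y[sp$test], p_test)$auc)
}
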
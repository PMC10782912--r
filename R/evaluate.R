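# Classification performance: confusion matrix, threshold metrics, ROC/AUC,
# prediction-label correlation, bootstrap AUC distribution, stratified
# k-fold cross-validation.

#' Confusion matrix at a decision threshold
#'
#' A sample is called positive iff its probability is strictly above the
#' threshold (so exactly 0.5 at the default is negative).
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @param threshold Decision threshold. Default 0.5.
#' @return A `confusion` object: list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y, p, threshold = 0.5) {
  if (length(y) == 0) stop2("empty input")
  if (length(y) != length(p)) stop2("y and p lengths differ")
  pos <- p > threshold
  structure(list(tp = sum(pos & y == 1), fp = sum(pos & y == 0),
                 tn = sum(!pos & y == 0), fn = sum(!pos & y == 1)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Threshold metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm A [confusion()] result.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) stop2("empty confusion matrix")
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- sdiv(cm$tp, cm$tp + cm$fp)
  recall <- sdiv(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = (cm$tp + cm$tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

# Rank-based AUC: Mann-Whitney statistic with half credit for ties.
fast_auc <- function(y, p) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' Sweeps every unique score as a threshold to produce (FPR, TPR) points
#' (anchored at (0,0) and (1,1)), and integrates the curve by the trapezoid
#' rule. With ties given half credit this equals the normalized
#' Mann-Whitney pair statistic.
#'
#' @param y 0/1 labels (both classes required).
#' @param p Scores/probabilities.
#' @return List with `roc` (data.frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(y, p) {
  if (length(y) != length(p)) stop2("y and p lengths differ")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop2("both classes must be present")
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  # collapse tied scores so each unique threshold contributes one point
  grp <- cumsum(!duplicated(ps))
  tp <- cumsum(ys == 1); fp <- cumsum(ys == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1),
    threshold = c(Inf, ps[last])
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Pearson correlation between predictions and labels
#'
#' Product-moment correlation with a two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param y Labels (or any numeric vector with variance).
#' @param p Predictions.
#' @return List with `r` and `p_value`.
#' @export
pearson_corr <- function(y, p) {
  n <- length(y)
  if (n < 3) stop2("need at least 3 observations")
  if (stats::sd(y) == 0 || stats::sd(p) == 0)
    stop2("zero variance in y or p")
  r <- sum((y - mean(y)) * (p - mean(p))) /
    ((n - 1) * stats::sd(y) * stats::sd(p))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pv <- if (is.infinite(tstat)) 0 else
    2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p_value = pv)
}

#' Bootstrap distribution of the AUC
#'
#' Resamples (label, prediction) pairs with replacement to the original n,
#' recomputing the AUC each time; single-class resamples are redrawn (their
#' count is reported). Returns the mean AUC and the percentile 95% interval.
#'
#' @param y 0/1 labels (both classes present).
#' @param p Predictions.
#' @param n_reps Bootstrap replicates. Default 10000.
#' @param seed RNG seed (two runs with one seed are identical).
#' @return A `bootstrap_result`: list with `n_reps`, `auc_samples`,
#'   `mean_auc`, `ci95`, `n_redrawn`, `seed`.
#' @export
bootstrap_auc <- function(y, p, n_reps = 10000, seed = 1) {
  n <- length(y)
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop2("both classes must be present")
  out <- with_seed(seed, {
    aucs <- numeric(n_reps)
    redrawn <- 0L
    for (i in seq_len(n_reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
        redrawn <- redrawn + 1L
      }
      aucs[i] <- fast_auc(y[idx], p[idx])
    }
    list(aucs = aucs, redrawn = redrawn)
  })
  ci <- unname(stats::quantile(out$aucs, c(0.025, 0.975)))
  structure(list(n_reps = n_reps, auc_samples = out$aucs,
                 mean_auc = mean(out$aucs), ci95 = ci,
                 n_redrawn = out$redrawn, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: mean AUC %.4f, 95%% CI [%.4f, %.4f] (%d reps)\n",
              x$mean_auc, x$ci95[1], x$ci95[2], x$n_reps))
  invisible(x)
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, threshold metrics, ROC/AUC and
#' prediction-label correlation for one prediction set.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @param threshold Decision threshold. Default 0.5.
#' @return An `eval_report` list.
#' @export
evaluate_predictions <- function(y, p, threshold = 0.5) {
  cm <- confusion(y, p, threshold)
  ra <- roc_auc(y, p)
  pc <- pearson_corr(y, p)
  structure(c(list(confusion = cm), metrics(cm),
              list(roc = ra$roc, auc = ra$auc,
                   pearson_r = pc$r, p_value = pc$p_value,
                   threshold = threshold, n = length(y))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report (n=%d): acc %.4f, precision %.4f, recall %.4f, F1 %.4f, AUC %.4f, r %.3f (p=%.3g)\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$auc, x$pearson_r,
    x$p_value))
  invisible(x)
}

# Seeded stratified k-fold assignment: classes are dealt round-robin with a
# carried-over rotation offset, so fold sizes differ by at most 1 both
# overall and within each class; membership within a class is a seeded
# permutation.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    off <- 0L
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- ((off + seq_along(idx) - 1L) %% k) + 1L
      off <- off + length(idx)
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Splits samples into k label-stratified folds, trains a model on each
#' training complement and evaluates on the held-out fold. Reports per-fold
#' evaluation reports and the standard deviation of fold accuracies (the
#' stability statistic).
#'
#' @param X samples x windows matrix or `coverage_matrix`.
#' @param y 0/1 labels (each class must have >= k members).
#' @param k Number of folds. Default 10.
#' @param cfg A [model_config()] used for every fold (fold f trains with
#'   seed `cfg$seed + f`).
#' @param seed Fold-assignment seed. Default 1.
#' @return List with `folds` (per-fold `eval_report`), `accuracy` vector,
#'   `accuracy_sd`, `auc` vector.
#' @export
cross_validate <- function(X, y, k = 10, cfg = model_config(), seed = 1) {
  if (inherits(X, "coverage_matrix")) {
    y <- y %||% X$labels
    X <- X$values
  }
  y <- as.numeric(y)
  if (min(table(y)) < k)
    stop2("each class needs at least k = ", k, " members")
  fold <- stratified_folds(y, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cfg_f <- cfg; cfg_f$seed <- cfg$seed + f
    mdl <- build_model(cfg_f, ncol(X))
    mdl <- train_model(mdl, X[tr, , drop = FALSE], y[tr])
    pv <- predict(mdl, X[!tr, , drop = FALSE])
    reports[[f]] <- evaluate_predictions(y[!tr], pv, cfg$threshold)
  }
  acc <- vapply(reports, function(r) r$accuracy, 0)
  list(folds = reports, accuracy = acc,
       accuracy_sd = stats::sd(acc),
       auc = vapply(reports, function(r) r$auc, 0))
}
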
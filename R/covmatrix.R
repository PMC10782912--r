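# Per-sample window coverage, sample QC, GC/mappability bias correction,
# cohort matrix assembly, row normalization and window pruning.
#
# Stage order is fixed: count -> correct -> QC filter -> assemble ->
# normalize -> prune -> impute. Correction operates on binned counts.

#' Sum base coverage into windows
#'
#' Converts per-interval depth records (bedGraph: `chrom start end depth`)
#' into one coverage value per unmasked window by summing depth x overlap bp.
#' Mean depth is total aligned bases divided by the total unmasked genome
#' length.
#'
#' @param ws A `window_set`.
#' @param depth data.frame with columns `chrom`, `start`, `end`, `depth`
#'   (non-overlapping within a chromosome), or a bedGraph path.
#' @param sample_id Sample identifier stored on the profile.
#' @param n_unique_reads Optional deduplicated read count used by
#'   [sample_qc()].
#' @return A `coverage_profile`: list with `sample_id`, `values` (named by
#'   unmasked window index), `mean_depth`, `n_unique_reads`, `qc_pass`,
#'   `stage = "raw"`.
#' @export
count_coverage <- function(ws, depth, sample_id = "sample",
                           n_unique_reads = NA_integer_) {
  stopifnot(inherits(ws, "window_set"))
  if (is.character(depth) && length(depth) == 1L)
    depth <- read_intervals(depth, c("chrom", "start", "end", "depth"),
                            numeric_cols = c(2L, 3L, 4L))
  if (nrow(depth) > 0 && any(depth$depth < 0)) stop2("negative depth record")
  n <- nrow(ws$windows)
  vals <- numeric(n)
  hits <- interval_to_windows(ws, depth)
  if (nrow(hits) > 0L) {
    rs <- rowsum(depth$depth[hits$row] * hits$bp, hits$window)
    vals[as.numeric(rownames(rs)) + 1] <- rs[, 1]
  }
  unmasked <- !ws$windows$masked
  glen <- sum(ws$windows$end[unmasked] - ws$windows$start[unmasked])
  structure(list(
    sample_id = sample_id,
    values = stats::setNames(vals[unmasked], ws$windows$index[unmasked]),
    mean_depth = sum(vals[unmasked]) / glen,
    n_unique_reads = n_unique_reads,
    qc_pass = NA,
    stage = "raw"
  ), class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile '%s': %d windows, mean depth %.3fx, stage %s\n",
              x$sample_id, length(x$values), x$mean_depth, x$stage))
  invisible(x)
}

#' Sample-level quality control
#'
#' A sample fails when its mean depth is strictly below `min_mean_depth`
#' (default 0.15x) or its unique-read count is strictly below `min_reads`
#' (default 6e6). Boundary values pass. A missing read count skips that
#' check with a warning.
#'
#' @param p A `coverage_profile`.
#' @param min_mean_depth Minimum mean depth (x). Default 0.15.
#' @param min_reads Minimum unique reads. Default 6e6.
#' @return The profile with `qc_pass` set and a `qc_reasons` character
#'   vector (empty when passing).
#' @export
sample_qc <- function(p, min_mean_depth = 0.15, min_reads = 6e6) {
  stopifnot(inherits(p, "coverage_profile"))
  reasons <- character(0)
  if (p$mean_depth < min_mean_depth) reasons <- c(reasons, "low_coverage")
  if (is.na(p$n_unique_reads)) {
    warning("n_unique_reads missing for ", p$sample_id,
            "; read-count check skipped")
  } else if (p$n_unique_reads < min_reads) {
    reasons <- c(reasons, "low_reads")
  }
  p$qc_pass <- length(reasons) == 0L
  p$qc_reasons <- reasons
  p
}

# Fit a loess trend y ~ x on the eligible subset and return a positive
# prediction function valid over the full x range (linear interpolation on
# the fitted curve, flat extrapolation).
fit_trend <- function(x, y, eligible, span) {
  xf <- x[eligible]; yf <- y[eligible]
  if (diff(range(xf)) < 1e-9) {
    # covariate is constant: the trend is its mean (identity correction)
    mu <- max(mean(yf), 1e-12)
    return(function(xq) rep(mu, length(xq)))
  }
  fit <- stats::loess(yf ~ xf, span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(xf), max(xf), length.out = 512)
  pred <- stats::predict(fit, data.frame(xf = grid))
  floor_val <- max(mean(yf) * 1e-3, 1e-12)
  pred <- pmax(pred, floor_val)
  function(xq) {
    out <- stats::approx(grid, pred, xout = xq, rule = 2)$y
    pmax(out, floor_val)
  }
}

#' Two-stage GC and mappability bias correction
#'
#' Removes systematic depth bias by dividing out smooth univariate trends,
#' in the style of readcount correctors for binned low-pass data: (1) a
#' loess trend of coverage against GC fraction is fitted on a trimmed set of
#' fitting-eligible windows and divided out; (2) a loess trend of the
#' GC-corrected values against mappability is divided out. The output is
#' rescaled so the profile mean is unchanged. Windows ineligible for fitting
#' are still corrected by the fitted trends.
#'
#' Fitting-eligible windows have GC and mappability defined, mappability >=
#' `min_mappability`, and raw value inside the
#' `[trim_quantiles[1], trim_quantiles[2]]` value quantiles.
#'
#' @param p A `coverage_profile` (stage `"raw"`).
#' @param ws A `window_set` with `gc` (and optionally `mappability`)
#'   attached, or `NULL` when `gc`/`mappability` vectors are given directly.
#' @param gc,mappability Optional per-unmasked-window numeric vectors
#'   overriding the tracks in `ws`. `mappability = NULL` skips stage 2.
#' @param span Loess span. Default 0.3.
#' @param min_mappability Mappability floor for fitting eligibility.
#'   Default 0.9.
#' @param trim_quantiles Value quantiles trimmed from the fitting set.
#'   Default `c(0.001, 0.999)`.
#' @return The profile with corrected `values`, `stage = "corrected"`.
#' @export
correct_bias <- function(p, ws = NULL, gc = NULL, mappability = NULL,
                         span = 0.3, min_mappability = 0.9,
                         trim_quantiles = c(0.001, 0.999)) {
  stopifnot(inherits(p, "coverage_profile"))
  if (p$stage != "raw") stop2("correct_bias expects a raw profile")
  n <- length(p$values)
  if (!is.null(ws)) {
    unmasked <- !ws$windows$masked
    if (is.null(gc) && !is.null(ws$gc)) gc <- ws$gc[unmasked]
    if (is.null(mappability) && !is.null(ws$mappability))
      mappability <- ws$mappability[unmasked]
  }
  if (is.null(gc)) stop2("no GC track available")
  if (length(gc) != n) stop2("gc length != number of profile windows")
  if (!is.null(mappability) && length(mappability) != n)
    stop2("mappability length != number of profile windows")
  v <- as.numeric(p$values)
  q <- stats::quantile(v, trim_quantiles, na.rm = TRUE, names = FALSE)
  eligible <- !is.na(gc) & v >= q[1] & v <= q[2] & v > 0
  if (!is.null(mappability))
    eligible <- eligible & !is.na(mappability) & mappability >= min_mappability
  if (sum(eligible) < 50)
    stop2("bias correction refused: only ", sum(eligible),
          " fitting-eligible windows (need >= 50)")
  mean_in <- mean(v)
  trend_gc <- fit_trend(gc, v, eligible, span)
  v1 <- v / trend_gc(gc)
  if (!is.null(mappability)) {
    trend_map <- fit_trend(mappability, v1, eligible, span)
    v2 <- v1 / trend_map(mappability)
  } else {
    v2 <- v1
  }
  v2 <- v2 * (mean_in / mean(v2))
  p$values <- stats::setNames(v2, names(p$values))
  p$stage <- "corrected"
  p
}

#' Assemble QC-passing profiles into a cohort coverage matrix
#'
#' @param profiles List of `coverage_profile`s sharing one window set and
#'   stage. Profiles with `qc_pass == FALSE` are excluded (logged in the
#'   `excluded` attribute); `NA` qc (never checked) is treated as passing.
#' @param labels Named 0/1 vector (names = sample ids), or an unnamed vector
#'   aligned with `profiles`. 0 = control, 1 = case.
#' @return A `coverage_matrix`: list with `values` (samples x windows
#'   matrix), `sample_ids`, `window_indices`, `labels`, `stage`.
#' @export
assemble_matrix <- function(profiles, labels) {
  stopifnot(length(profiles) > 0)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (is.null(names(labels))) {
    if (length(labels) != length(profiles))
      stop2("unnamed labels must match profiles in length")
    names(labels) <- ids
  }
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab) > 0)
    stop2("label missing for sample(s): ", paste(missing_lab, collapse = ", "))
  if (!all(labels %in% c(0, 1))) stop2("labels must be 0 or 1")
  keep <- vapply(profiles, function(p) !isFALSE(p$qc_pass), NA)
  excluded <- ids[!keep]
  profiles <- profiles[keep]
  if (length(profiles) == 0L) stop2("no QC-passing profiles")
  stages <- unique(vapply(profiles, function(p) p$stage, ""))
  if (length(stages) != 1L) stop2("profiles at mixed stages")
  widx <- names(profiles[[1]]$values)
  for (p in profiles)
    if (length(p$values) != length(widx) || !identical(names(p$values), widx))
      stop2("window-set mismatch between profiles")
  m <- do.call(rbind, lapply(profiles, function(p) as.numeric(p$values)))
  rownames(m) <- vapply(profiles, function(p) p$sample_id, "")
  colnames(m) <- widx
  out <- structure(list(
    values = m,
    sample_ids = rownames(m),
    window_indices = as.integer(widx),
    labels = unname(labels[rownames(m)]),
    stage = stages
  ), class = "coverage_matrix")
  attr(out, "excluded") <- excluded
  out
}

#' Construct a coverage matrix from a plain matrix
#'
#' Entry point for count matrices produced outside the profile workflow
#' (e.g. the synthetic-cohort simulator).
#'
#' @param values samples x windows numeric matrix.
#' @param labels 0/1 vector, one per row.
#' @param window_indices Integer window indices (columns). Default
#'   `0:(ncol-1)`.
#' @param sample_ids Row identifiers. Default `rownames(values)` or `s1..sn`.
#' @param stage Matrix stage. Default `"raw"`.
#' @export
coverage_matrix <- function(values, labels,
                            window_indices = NULL, sample_ids = NULL,
                            stage = "raw") {
  values <- as.matrix(values)
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  if (is.null(window_indices))
    window_indices <- 0:(ncol(values) - 1)
  stopifnot(length(labels) == nrow(values),
            all(labels %in% c(0, 1)),
            length(window_indices) == ncol(values))
  rownames(values) <- sample_ids
  colnames(values) <- window_indices
  structure(list(values = values, sample_ids = sample_ids,
                 window_indices = as.integer(window_indices),
                 labels = as.numeric(labels), stage = stage),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf(
    "coverage_matrix: %d samples x %d windows, stage %s (%d cases, %d controls)\n",
    nrow(x$values), ncol(x$values), x$stage,
    sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$values)

stage_rank <- c(raw = 1, corrected = 2, normalized = 3, imputed = 4)

#' Row-normalize a coverage matrix
#'
#' Divides every element by its row (sample) mean, so each sample's mean
#' normalized coverage is exactly 1 and samples of different sequencing
#' depth become comparable.
#'
#' @param m A `coverage_matrix` at stage `"raw"` or `"corrected"` (a
#'   `"normalized"` matrix is accepted and passes through unchanged:
#'   normalization is idempotent).
#' @return The matrix at stage `"normalized"`.
#' @export
normalize_rows <- function(m) {
  stopifnot(inherits(m, "coverage_matrix"))
  if (!m$stage %in% c("raw", "corrected", "normalized"))
    stop2("normalize_rows expects stage raw, corrected or normalized, got ",
          m$stage)
  rm_ <- rowMeans(m$values)
  if (any(rm_ <= 0))
    stop2("all-zero row(s): ",
          paste(m$sample_ids[rm_ <= 0], collapse = ", "))
  m$values <- m$values / rm_
  m$stage <- "normalized"
  m
}

#' Prune uninformative windows
#'
#' Drops a window (column) when either rule fires, both with strict
#' inequalities exactly as worded:
#' \itemize{
#'   \item dropout rule: over `dropout_frac` (default 80%) of samples have
#'     normalized coverage lower than `dropout_value` (default 0.1);
#'   \item mean-difference rule: the absolute difference between the window's
#'     mean coverage in controls (label 0) and cases (label 1) is less than
#'     `mean_diff` (default 0.01).
#' }
#' The dropout rule is checked first for reason attribution; precedence only
#' affects the recorded reason, never the retained set.
#'
#' @param m A normalized `coverage_matrix` containing both classes.
#' @param dropout_frac,dropout_value,mean_diff Rule thresholds.
#' @return List with `matrix` (pruned `coverage_matrix`) and `report`
#'   (a `pruning_report`: `dropped` data.frame with `window_index`,
#'   `reason`; `n_initial`; `n_retained`).
#' @export
prune_windows <- function(m, dropout_frac = 0.8, dropout_value = 0.1,
                          mean_diff = 0.01) {
  stopifnot(inherits(m, "coverage_matrix"))
  if (m$stage != "normalized") stop2("prune_windows expects stage normalized")
  if (length(unique(m$labels)) < 2)
    stop2("pruning needs both classes present (mean-difference rule)")
  x <- m$values
  frac_low <- colMeans(x < dropout_value)
  rule1 <- frac_low > dropout_frac
  mu0 <- colMeans(x[m$labels == 0, , drop = FALSE])
  mu1 <- colMeans(x[m$labels == 1, , drop = FALSE])
  rule2 <- abs(mu0 - mu1) < mean_diff
  drop <- rule1 | rule2
  reason <- ifelse(rule1, "dropout_rule", "mean_diff_rule")[drop]
  report <- structure(list(
    dropped = data.frame(window_index = m$window_indices[drop],
                         reason = reason, stringsAsFactors = FALSE),
    n_initial = ncol(x),
    n_retained = sum(!drop)
  ), class = "pruning_report")
  m$values <- x[, !drop, drop = FALSE]
  m$window_indices <- m$window_indices[!drop]
  list(matrix = m, report = report)
}

#' @export
print.pruning_report <- function(x, ...) {
  tab <- table(x$dropped$reason)
  cat(sprintf("pruning_report: %d -> %d windows (%s)\n",
              x$n_initial, x$n_retained,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a coverage matrix as TSV with a JSON sidecar
#'
#' The TSV holds one row per sample (first column `sample_id`, then one
#' column per window index); the sidecar `<path>.json` records stage,
#' labels, window indices and, when given, the pruning report.
#'
#' @param m A `coverage_matrix`.
#' @param path Output TSV path.
#' @param report Optional `pruning_report`.
#' @export
write_matrix <- function(m, path, report = NULL) {
  df <- data.frame(sample_id = m$sample_ids, m$values, check.names = FALSE)
  write_tsv(df, path)
  side <- list(stage = m$stage, labels = m$labels,
               sample_ids = m$sample_ids, window_indices = m$window_indices)
  if (!is.null(report))
    side$pruning <- list(n_initial = report$n_initial,
                         n_retained = report$n_retained,
                         dropped = report$dropped)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a coverage matrix written by [write_matrix()]
#' @param path TSV path (expects the `.json` sidecar next to it).
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  coverage_matrix(vals, labels = side$labels,
                  window_indices = side$window_indices,
                  sample_ids = df[[1]], stage = side$stage)
}
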
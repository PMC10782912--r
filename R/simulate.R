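# Synthetic low-coverage cfDNA cohorts: a toy genome of regular windows
# whose expected counts carry GC bias, mappability attenuation, random
# dropout and group-specific copy-number segments. The generator is the
# test bed for every other module: its ground truth (which windows carry
# signal) supports recovery scoring of the attention ranking.

#' Simulation configuration
#'
#' The generated world: `n_samples` plasma samples at depths drawn
#' uniformly from `mean_depth_range` (defaults around the ~0.2x regime of
#' low-pass cfDNA screening), over a toy genome tiled into `window_size`
#' windows. Expected counts per window are
#' `depth * window_len * bias(gc) * mappability * cn/2`, where `cn = 2`
#' except inside the implanted signal segments of case samples expressing
#' the effect (probability `penetrance`), where `cn = 2 * effect_size`.
#' GC bias is a unimodal quadratic centered at GC 0.45 with amplitude
#' `gc_bias_strength`. Counts follow the configured noise law
#' (`"poisson"`, `"negbin"` with `dispersion`, or `"none"` for the exact
#' expectation), then entries are zeroed with probability `dropout_rate`.
#'
#' @param n_samples Cohort size. Default 400.
#' @param case_fraction Fraction of case (label 1) samples; the case count
#'   is the deterministic `round(n_samples * case_fraction)`. Default 0.5.
#' @param chrom_lengths Named toy chromosome lengths (bp).
#'   Default `c(chrA = 6e6, chrB = 4e6)`.
#' @param window_size Window width (bp). Default 5000.
#' @param mean_depth_range Depth range (x). Default `c(0.15, 0.25)`.
#' @param gc_bias_strength Amplitude of the quadratic GC bias (0 = none).
#'   Default 1.
#' @param mappability_range Range of per-window mappability (drawn as
#'   `hi - (hi - lo) * Beta(1, 5)`, so mass sits near `hi`). `c(1, 1)`
#'   gives a perfectly mappable (flat) genome. Default `c(0.5, 1)`.
#' @param n_signal_segments Number of implanted CNV segments. Default 5.
#' @param segment_length_windows Windows per segment. Default 20.
#' @param effect_size Multiplicative copy-number effect (1.5 = gain,
#'   0.5 = loss, 1 = no signal). Default 1.5.
#' @param penetrance Probability a case sample expresses each segment.
#'   Default 0.8.
#' @param dropout_rate Probability an entry is zeroed. Default 0.05.
#' @param noise `"poisson"`, `"negbin"` or `"none"`. Default `"poisson"`.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed). Default 50.
#' @param seed Master seed. Default 1.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 400, case_fraction = 0.5,
                       chrom_lengths = c(chrA = 6e6, chrB = 4e6),
                       window_size = 5000,
                       mean_depth_range = c(0.15, 0.25),
                       gc_bias_strength = 1,
                       mappability_range = c(0.5, 1),
                       n_signal_segments = 5, segment_length_windows = 20,
                       effect_size = 1.5, penetrance = 0.8,
                       dropout_rate = 0.05,
                       noise = c("poisson", "negbin", "none"),
                       dispersion = 50, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(is_count(n_samples), is_fraction(case_fraction),
            is_fraction(penetrance), is_fraction(dropout_rate),
            effect_size > 0, length(mean_depth_range) == 2)
  cfg <- list(n_samples = n_samples, case_fraction = case_fraction,
              chrom_lengths = chrom_lengths, window_size = window_size,
              mean_depth_range = mean_depth_range,
              gc_bias_strength = gc_bias_strength,
              mappability_range = mappability_range,
              n_signal_segments = n_signal_segments,
              segment_length_windows = segment_length_windows,
              effect_size = effect_size, penetrance = penetrance,
              dropout_rate = dropout_rate, noise = noise,
              dispersion = dispersion, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

gc_bias_curve <- function(gc, strength) {
  pmax(1 - strength * (gc - 0.45)^2, 0.1)
}

#' Simulate a synthetic cfDNA cohort
#'
#' See [sim_config()] for the generative model. Fully reproducible from the
#' config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_cohort`: list with `ws` (annotated `window_set`),
#'   `counts` (samples x windows), `labels`, `depths`, `truth` (data.frame
#'   `window_index`, `segment`, `direction`), `cfg`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cs <- chrom_sizes(names(cfg$chrom_lengths), unname(cfg$chrom_lengths))
  ws <- make_windows(cs, cfg$window_size)
  N <- nrow(ws$windows)
  seg_total <- cfg$n_signal_segments * cfg$segment_length_windows
  if (seg_total > N)
    stop2("signal segments (", seg_total, " windows) exceed the genome (",
          N, " windows)")
  n_case <- round(cfg$n_samples * cfg$case_fraction)
  if (cfg$effect_size != 1 && cfg$n_signal_segments > 0 && n_case == 0)
    stop2("case_fraction yields zero case samples")
  out <- with_seed(cfg$seed, {
    gc <- stats::rbeta(N, 5, 5)
    mr <- cfg$mappability_range
    mappability <- mr[2] - (mr[2] - mr[1]) * stats::rbeta(N, 1, 5)
    # non-overlapping segment placement: sample starts on a coarse grid
    truth <- data.frame(window_index = integer(0), segment = integer(0),
                        direction = character(0))
    cn_mask <- rep(FALSE, N)
    if (cfg$n_signal_segments > 0 && cfg$effect_size != 1) {
      slots <- seq(1, N - cfg$segment_length_windows + 1,
                   by = cfg$segment_length_windows * 2)
      if (length(slots) < cfg$n_signal_segments)
        stop2("cannot place ", cfg$n_signal_segments,
              " non-overlapping segments")
      starts <- sort(sample(slots, cfg$n_signal_segments))
      dir <- if (cfg$effect_size > 1) "gain" else "loss"
      truth <- do.call(rbind, lapply(seq_along(starts), function(i) {
        idx <- starts[i]:(starts[i] + cfg$segment_length_windows - 1)
        data.frame(window_index = idx - 1L, segment = i, direction = dir)
      }))
      cn_mask[truth$window_index + 1] <- TRUE
    }
    labels <- numeric(cfg$n_samples)
    labels[sample.int(cfg$n_samples, n_case)] <- 1
    depths <- stats::runif(cfg$n_samples, cfg$mean_depth_range[1],
                           cfg$mean_depth_range[2])
    wlen <- ws$windows$end - ws$windows$start
    base <- gc_bias_curve(gc, cfg$gc_bias_strength) * mappability * wlen
    mu <- depths %o% base  # samples x windows
    if (any(cn_mask)) {
      for (s in which(labels == 1)) {
        expressed <- stats::runif(cfg$n_signal_segments) < cfg$penetrance
        if (any(expressed)) {
          segs <- truth$segment %in% which(expressed)
          cols <- truth$window_index[segs] + 1
          mu[s, cols] <- mu[s, cols] * cfg$effect_size
        }
      }
    }
    counts <- switch(cfg$noise,
      none = mu,
      poisson = matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu)),
      negbin = matrix(stats::rnbinom(length(mu), size = cfg$dispersion,
                                     mu = mu), nrow(mu), ncol(mu)))
    if (cfg$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(counts)) < cfg$dropout_rate,
                     nrow(counts), ncol(counts))
      counts[drop] <- 0
    }
    list(gc = gc, mappability = mappability, truth = truth,
         labels = labels, depths = depths, counts = counts)
  })
  ws <- annotate_windows(ws, gc = out$gc, mappability = out$mappability)
  rownames(out$counts) <- sprintf("sim%03d", seq_len(cfg$n_samples))
  colnames(out$counts) <- ws$windows$index
  structure(list(ws = ws, counts = out$counts, labels = out$labels,
                 depths = out$depths, truth = out$truth, cfg = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d samples (%d cases) x %d windows; %d signal windows (effect %.2g)\n",
    nrow(x$counts), sum(x$labels == 1), ncol(x$counts), nrow(x$truth),
    x$cfg$effect_size))
  invisible(x)
}

#' Coverage matrix view of a synthetic cohort
#' @param cohort A `synthetic_cohort`.
#' @return A `coverage_matrix` at stage `"raw"`.
#' @export
cohort_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  coverage_matrix(cohort$counts, cohort$labels,
                  window_indices = cohort$ws$windows$index,
                  sample_ids = rownames(cohort$counts), stage = "raw")
}

#' Score recovery of implanted signal windows by a ranking
#'
#' `precision@k` is the fraction of the k top-ranked windows that are true
#' signal windows; fold enrichment divides it by the truth density
#' `|truth| / n_universe`. `n_universe` defaults to the full window set the
#' truth was drawn from (not the possibly pruned ranked subset, where the
#' truth density is inflated by design).
#'
#' @param rr A `ranked_regions`.
#' @param truth Integer vector of true signal window indices (0-based), or
#'   the `truth` data.frame of a `synthetic_cohort`.
#' @param k Ranking depth. Default `2 * length(truth)`.
#' @param n_universe Window universe size for the truth density.
#' @return List with `precision_at_k`, `fold_enrichment`, `k`, `n_hits`.
#' @export
truth_recovery <- function(rr, truth, k = NULL, n_universe = NULL) {
  stopifnot(inherits(rr, "ranked_regions"))
  if (is.data.frame(truth)) truth <- truth$window_index
  truth <- unique(as.integer(truth))
  if (length(truth) == 0) stop2("empty truth set")
  if (is.null(k)) k <- 2L * length(truth)
  if (k > nrow(rr$regions))
    stop2("k (", k, ") exceeds ranked windows (", nrow(rr$regions), ")")
  if (is.null(n_universe)) n_universe <- nrow(rr$regions)
  topk <- rr$regions$window_index[seq_len(k)]
  n_hits <- length(intersect(topk, truth))
  prec <- n_hits / k
  list(precision_at_k = prec,
       fold_enrichment = prec / (length(truth) / n_universe),
       k = k, n_hits = n_hits)
}

#' Write a cohort as per-sample bedGraph depth files
#'
#' Materializes each sample's window counts as a bedGraph of constant
#' per-base depth per window (count / window length), suitable for
#' exercising [count_coverage()] on files, plus `labels.tsv` and
#' `truth.bed`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- cohort$ws$windows
  wlen <- w$end - w$start
  for (i in seq_len(nrow(cohort$counts))) {
    df <- data.frame(chrom = w$chrom, start = w$start, end = w$end,
                     depth = cohort$counts[i, ] / wlen)
    df <- df[df$depth > 0, , drop = FALSE]
    utils::write.table(df, file.path(dir, paste0(rownames(cohort$counts)[i],
                                                 ".bedgraph")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_tsv(data.frame(sample_id = rownames(cohort$counts),
                       label = cohort$labels),
            file.path(dir, "labels.tsv"))
  if (nrow(cohort$truth) > 0) {
    tw <- w[cohort$truth$window_index + 1, ]
    utils::write.table(
      data.frame(tw$chrom, tw$start, tw$end, cohort$truth$direction),
      file.path(dir, "truth.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
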
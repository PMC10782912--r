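# Dropout imputation by regularized low-rank matrix factorization.
#
# Observed entries are never altered: missing entries (coverage dropout) are
# replaced by the reconstruction U V' fitted to the observed entries only
# (completion, not smoothing).

#' Flag dropout entries of a normalized matrix
#'
#' An entry is treated as missing when its normalized coverage is strictly
#' below `epsilon`: at ~0.2x depth a window with essentially no observed
#' bases reflects sequencing dropout, not a true copy-number of zero.
#'
#' @param m A `coverage_matrix` at stage `"normalized"`.
#' @param epsilon Missingness threshold. Default 0.01. Exact zeros are
#'   always flagged, so `epsilon = 0` flags exactly the zero entries.
#' @return A logical samples x windows matrix (TRUE = missing) with
#'   attribute `n_missing`.
#' @export
flag_missing <- function(m, epsilon = 0.01) {
  stopifnot(inherits(m, "coverage_matrix"))
  if (m$stage != "normalized") stop2("flag_missing expects stage normalized")
  mask <- m$values < epsilon | m$values == 0
  all_row <- rowSums(!mask) == 0
  if (any(all_row))
    stop2("row(s) entirely missing: ",
          paste(m$sample_ids[all_row], collapse = ", "))
  all_col <- colSums(!mask) == 0
  if (any(all_col))
    stop2("column(s) entirely missing: window ",
          paste(m$window_indices[all_col], collapse = ", "))
  attr(mask, "n_missing") <- sum(mask)
  mask
}

#' Impute missing entries by regularized low-rank factorization
#'
#' Fits row factors U (samples x rank) and column factors V (windows x
#' rank) minimizing `sum over observed (x - u.v)^2 + lambda (||U||^2 +
#' ||V||^2)` by Adam-accelerated gradient descent from a seeded random
#' initialization, then replaces missing entries with the reconstruction
#' `U V'`. Observed entries are preserved verbatim.
#'
#' @param m A `coverage_matrix` (stage `"normalized"`).
#' @param mask Logical matrix from [flag_missing()] (TRUE = missing).
#' @param rank Factorization rank (< min(dim)). Default 10.
#' @param lambda L2 penalty on the factors. Default 0.1.
#' @param lr Adam step size. Default 0.05.
#' @param epochs Gradient steps. Default 500.
#' @param seed Seed for factor initialization.
#' @return The matrix at stage `"imputed"`, with attributes `loss`
#'   (per-epoch penalized loss) and `factors` (list U, V).
#' @export
impute_lowrank <- function(m, mask, rank = 10, lambda = 0.1,
                           lr = 0.05, epochs = 500, seed = 1) {
  stopifnot(inherits(m, "coverage_matrix"))
  x <- m$values
  stopifnot(identical(dim(mask), dim(x)))
  if (!is_count(rank) || rank >= min(dim(x)))
    stop2("rank must be a positive integer < min(dim)")
  w <- 1 - mask * 1  # 1 = observed
  if (all(mask == FALSE)) {
    m$stage <- "imputed"
    attr(m, "loss") <- numeric(0)
    return(m)
  }
  nr <- nrow(x); nc <- ncol(x)
  xz <- x * w  # zero out missing so they never enter the residual
  init_sd <- sqrt(sqrt(mean(xz[w == 1]^2) / rank))
  fac <- with_seed(seed, list(
    U = matrix(stats::rnorm(nr * rank, sd = init_sd), nr, rank),
    V = matrix(stats::rnorm(nc * rank, sd = init_sd), nc, rank)
  ))
  U <- fac$U; V <- fac$V
  mU <- vU <- matrix(0, nr, rank)
  mV <- vV <- matrix(0, nc, rank)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss <- numeric(epochs)
  for (t in seq_len(epochs)) {
    R <- (U %*% t(V) - xz) * w
    loss[t] <- sum(R^2) + lambda * (sum(U^2) + sum(V^2))
    gU <- 2 * (R %*% V) + 2 * lambda * U
    gV <- 2 * (t(R) %*% U) + 2 * lambda * V
    mU <- b1 * mU + (1 - b1) * gU; vU <- b2 * vU + (1 - b2) * gU^2
    mV <- b1 * mV + (1 - b1) * gV; vV <- b2 * vV + (1 - b2) * gV^2
    corr <- sqrt(1 - b2^t) / (1 - b1^t)
    U <- U - lr * corr * mU / (sqrt(vU) + eps)
    V <- V - lr * corr * mV / (sqrt(vV) + eps)
  }
  tail_n <- max(2L, ceiling(epochs * 0.2))
  tail_loss <- loss[(epochs - tail_n + 1):epochs]
  if (tail_loss[tail_n] > tail_loss[1])
    warning(sprintf(
      "imputation may not have converged: loss %.4g -> %.4g over final %d epochs",
      tail_loss[1], tail_loss[tail_n], tail_n))
  recon <- U %*% t(V)
  out <- x
  out[mask] <- recon[mask]
  m$values <- out
  m$stage <- "imputed"
  attr(m, "loss") <- loss
  attr(m, "factors") <- list(U = U, V = V, rank = rank, lambda = lambda,
                             seed = seed)
  m
}
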
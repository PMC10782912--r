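# 1D CNN with position-wise self-attention for binary classification of
# coverage profiles, implemented directly on BLAS matrix operations:
#
#   input (N x 1) -> conv1D (ReLU) -> maxpool -> conv1D (ReLU) -> maxpool
#     -> additive self-attention over pooled positions (softmax scores,
#        attended summary) -> dense (ReLU, dropout) -> dense (ReLU, dropout)
#     -> 1-unit sigmoid
#
# Convolutions are "valid" (no padding), pooling is non-overlapping with
# remainder positions dropped. Training: Adam on binary cross-entropy,
# fixed epoch count (no early stopping), dropout active only in training.
# One master seed derives the initialization, shuffle and dropout streams.

#' Model configuration
#'
#' Defaults mirror the published training protocol where stated (dropout
#' 0.4, Adam with learning rate 1e-5, batch size 512, 100 epochs, decision
#' threshold 0.5); layer widths and kernels are this package's defaults and
#' are all exposed to [grid_search()].
#'
#' @param conv1_filters,conv1_kernel First convolution: filters and kernel
#'   width. Defaults 32, 8.
#' @param pool1,pool2 Max-pooling widths (non-overlapping). Defaults 4, 4.
#' @param conv2_filters,conv2_kernel Second convolution. Defaults 64, 8.
#' @param attention_dim Hidden width of the additive attention scorer.
#'   Default 64.
#' @param attention_temperature Softmax temperature of the attention scores;
#'   values below 1 sharpen the attention distribution, forcing the attended
#'   summary to rely on few positions (which makes the learned weights
#'   localize on discriminative regions instead of diffuse averaging).
#'   Default 0.1.
#' @param dense1_units,dense2_units Fully connected widths. Defaults 64, 16.
#' @param dropout_rate Dropout after each dense layer. Default 0.4.
#' @param learning_rate Adam step size. Default 1e-5.
#' @param batch_size Minibatch size. Default 512.
#' @param epochs Training epochs (fixed; no early stopping). Default 100.
#' @param threshold Decision threshold; class 1 iff probability strictly
#'   above it. Default 0.5.
#' @param seed Master seed deriving init/shuffle/dropout streams. Default 1.
#' @return A `model_config` list.
#' @export
model_config <- function(conv1_filters = 32, conv1_kernel = 8, pool1 = 4,
                         conv2_filters = 64, conv2_kernel = 8, pool2 = 4,
                         attention_dim = 64, attention_temperature = 0.1,
                         dense1_units = 64,
                         dense2_units = 16, dropout_rate = 0.4,
                         learning_rate = 1e-5, batch_size = 512,
                         epochs = 100, threshold = 0.5, seed = 1) {
  cfg <- list(conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
              pool1 = pool1, conv2_filters = conv2_filters,
              conv2_kernel = conv2_kernel, pool2 = pool2,
              attention_dim = attention_dim,
              attention_temperature = attention_temperature,
              dense1_units = dense1_units,
              dense2_units = dense2_units, dropout_rate = dropout_rate,
              learning_rate = learning_rate, batch_size = batch_size,
              epochs = epochs, threshold = threshold, seed = seed)
  if (!is.numeric(attention_temperature) || attention_temperature <= 0)
    stop2("attention_temperature must be > 0")
  for (f in c("conv1_filters", "conv1_kernel", "pool1", "conv2_filters",
              "conv2_kernel", "pool2", "attention_dim", "dense1_units",
              "dense2_units", "batch_size", "epochs"))
    if (!is_count(cfg[[f]])) stop2(f, " must be a positive integer")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop2("dropout_rate must be in [0, 1)")
  structure(cfg, class = "model_config")
}

# Sequence lengths through the layer stack.
model_dims <- function(cfg, n_windows) {
  L1 <- n_windows - cfg$conv1_kernel + 1
  L1p <- L1 %/% cfg$pool1
  L2 <- L1p - cfg$conv2_kernel + 1
  L2p <- L2 %/% cfg$pool2
  list(N = n_windows, L1 = L1, L1p = L1p, L2 = L2, L2p = L2p)
}

#' Build an untrained CNN-attention model
#'
#' Validates that the layer stack leaves at least one pooled position for
#' the given window count, and initializes all weights (He-scaled normal,
#' seeded).
#'
#' @param cfg A [model_config()].
#' @param n_windows Number of input windows N.
#' @return A `cfcnn` model object; `n_parameters` attribute reports the
#'   parameter count.
#' @export
build_model <- function(cfg, n_windows) {
  stopifnot(inherits(cfg, "model_config"))
  d <- model_dims(cfg, n_windows)
  if (d$L1 < 1)
    stop2("conv1_kernel (", cfg$conv1_kernel, ") exceeds input length ",
          n_windows)
  if (d$L1p < 1 || d$L2 < 1 || d$L2p < 1)
    stop2("configuration collapses the sequence to length 0 ",
          "(pooled lengths: ", d$L1p, ", ", d$L2p, ")")
  k1 <- cfg$conv1_kernel; f1 <- cfg$conv1_filters
  k2 <- cfg$conv2_kernel; f2 <- cfg$conv2_filters
  da <- cfg$attention_dim; d1 <- cfg$dense1_units; d2 <- cfg$dense2_units
  he <- function(nr, nc, fan_in)
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  params <- with_seed(derive_seed(cfg$seed, "init"), list(
    W1 = he(k1, f1, k1), b1 = numeric(f1),
    W2 = he(k2 * f1, f2, k2 * f1), b2 = numeric(f2),
    Wa = he(f2, da, f2), ba = numeric(da),
    va = stats::rnorm(da, sd = sqrt(1 / da)),
    Wd1 = he(f2, d1, f2), bd1 = numeric(d1),
    Wd2 = he(d1, d2, d1), bd2 = numeric(d2),
    wo = matrix(stats::rnorm(d2, sd = sqrt(1 / d2)), d2, 1), bo = 0
  ))
  n_par <- sum(vapply(params, length, 0L))
  structure(list(cfg = cfg, dims = d, params = params,
                 feature_means = NULL, trained = FALSE, history = NULL),
            class = "cfcnn", n_parameters = n_par)
}

#' @export
print.cfcnn <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "cfcnn: %d windows -> conv(%d,k%d)/pool%d -> conv(%d,k%d)/pool%d -> %d attended positions -> dense(%d,%d) -> sigmoid\n",
    d$N, x$cfg$conv1_filters, x$cfg$conv1_kernel, x$cfg$pool1,
    x$cfg$conv2_filters, x$cfg$conv2_kernel, x$cfg$pool2, d$L2p,
    x$cfg$dense1_units, x$cfg$dense2_units))
  cat(sprintf("  %d parameters; %s\n", attr(x, "n_parameters"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Precomputed gather indices for a batch of B samples (row order inside all
# layer matrices is sample-major: sample b occupies a contiguous row block).
conv_indices <- function(cfg, d, B) {
  p1 <- cfg$pool1; p2 <- cfg$pool2
  k1 <- cfg$conv1_kernel; k2 <- cfg$conv2_kernel
  # conv1 im2col: column j gathers input position (pos + j - 1) from t(X)
  i1 <- rep((0:(B - 1)) * d$N, each = d$L1) + seq_len(d$L1)
  # pool1: group g offset k gathers conv1 row ((g-1)*p1 + k)
  pool1_base <- rep((0:(B - 1)) * d$L1, each = d$L1p) +
    rep(seq(0, by = p1, length.out = d$L1p), B)
  # conv2 im2col: offset j gathers pooled row (u + j - 1)
  i2 <- rep((0:(B - 1)) * d$L1p, each = d$L2) + seq_len(d$L2)
  pool2_base <- rep((0:(B - 1)) * d$L2, each = d$L2p) +
    rep(seq(0, by = p2, length.out = d$L2p), B)
  group <- rep(seq_len(B), each = d$L2p)
  list(i1 = i1, pool1_base = pool1_base, i2 = i2, pool2_base = pool2_base,
       group = group, B = B)
}

maxpool_fwd <- function(A, base, p) {
  cur <- A[base + 1L, , drop = FALSE]
  amax <- matrix(1L, nrow(cur), ncol(cur))
  if (p > 1) for (k in 2:p) {
    cand <- A[base + k, , drop = FALSE]
    sel <- cand > cur
    cur[sel] <- cand[sel]
    amax[sel] <- k
  }
  list(out = cur, amax = amax)
}

maxpool_bwd <- function(dOut, amax, base, n_rows_in) {
  nc <- ncol(dOut)
  src_row <- base + amax  # winning source row, per (pooled row, channel)
  li <- src_row + (rep(seq_len(nc), each = nrow(dOut)) - 1L) * n_rows_in
  dA <- numeric(n_rows_in * nc)
  dA[li] <- dOut  # injective: each pooled cell has one winner
  dim(dA) <- c(n_rows_in, nc)
  dA
}

im2col <- function(A, idx, k) {
  # A: rows x channels; returns length(idx) x (k * channels)
  nc <- ncol(A)
  out <- matrix(0, length(idx), k * nc)
  for (j in seq_len(k))
    out[, ((j - 1) * nc + 1):(j * nc)] <- A[idx + (j - 1L), , drop = FALSE]
  out
}

col2im_add <- function(dM, idx, k, n_rows_in, nc) {
  dA <- matrix(0, n_rows_in, nc)
  for (j in seq_len(k)) {
    blk <- dM[, ((j - 1) * nc + 1):(j * nc), drop = FALSE]
    tgt <- idx + (j - 1L)
    dA[tgt, ] <- dA[tgt, , drop = FALSE] + blk
  }
  dA
}

relu <- function(x) x * (x > 0)

sigmoid_ <- function(z) 1 / (1 + exp(-z))

# Full forward pass for a batch. X: B x N (already feature-centered).
# Returns intermediates when `keep = TRUE` (for backprop / attention).
cfcnn_forward <- function(model, X, ci = NULL, keep = FALSE,
                          drop_masks = NULL) {
  p <- model$params; cfg <- model$cfg; d <- model$dims
  B <- nrow(X)
  if (is.null(ci)) ci <- conv_indices(cfg, d, B)
  Xt <- t(X)  # N x B; column-major vector indexing by ci$i1
  M1 <- matrix(0, B * d$L1, cfg$conv1_kernel)
  for (j in seq_len(cfg$conv1_kernel)) M1[, j] <- Xt[ci$i1 + (j - 1L)]
  Z1 <- sweep(M1 %*% p$W1, 2, p$b1, "+")
  A1 <- relu(Z1)
  pl1 <- maxpool_fwd(A1, ci$pool1_base, cfg$pool1)
  M2 <- im2col(pl1$out, ci$i2, cfg$conv2_kernel)
  Z2 <- sweep(M2 %*% p$W2, 2, p$b2, "+")
  A2 <- relu(Z2)
  pl2 <- maxpool_fwd(A2, ci$pool2_base, cfg$pool2)
  H <- pl2$out  # (B * L2p) x F2
  Spre <- sweep(H %*% p$Wa, 2, p$ba, "+")
  S <- tanh(Spre)
  e <- as.numeric(S %*% p$va) / cfg$attention_temperature
  E <- matrix(e, nrow = d$L2p)  # positions x samples
  E <- exp(sweep(E, 2, apply(E, 2, max)))
  alpha_m <- sweep(E, 2, colSums(E), "/")
  alpha <- as.numeric(alpha_m)
  C <- rowsum(H * alpha, ci$group)  # B x F2 attended summary
  Zd1 <- sweep(C %*% p$Wd1, 2, p$bd1, "+")
  D1 <- relu(Zd1)
  if (!is.null(drop_masks)) D1 <- D1 * drop_masks$m1
  Zd2 <- sweep(D1 %*% p$Wd2, 2, p$bd2, "+")
  D2 <- relu(Zd2)
  if (!is.null(drop_masks)) D2 <- D2 * drop_masks$m2
  logit <- as.numeric(D2 %*% p$wo + p$bo)
  prob <- sigmoid_(logit)
  if (!keep) return(list(prob = prob, alpha = alpha_m))
  list(prob = prob, logit = logit, alpha = alpha_m, alpha_vec = alpha,
       M1 = M1, Z1 = Z1, A1 = A1, pl1 = pl1, M2 = M2, Z2 = Z2, A2 = A2,
       pl2 = pl2, H = H, S = S, C = C, Zd1 = Zd1, D1 = D1, Zd2 = Zd2,
       D2 = D2, ci = ci, B = B)
}

# Gradients of mean binary cross-entropy wrt all parameters.
cfcnn_backward <- function(model, fw, y, drop_masks) {
  p <- model$params; cfg <- model$cfg; d <- model$dims
  B <- fw$B; ci <- fw$ci
  g <- list()
  dlogit <- (fw$prob - y) / B
  g$bo <- sum(dlogit)
  g$wo <- crossprod(fw$D2, dlogit)
  dD2 <- tcrossprod(dlogit, as.numeric(p$wo))
  if (!is.null(drop_masks)) dD2 <- dD2 * drop_masks$m2
  dZd2 <- dD2 * (fw$Zd2 > 0)
  g$bd2 <- colSums(dZd2)
  g$Wd2 <- crossprod(fw$D1, dZd2)
  dD1 <- dZd2 %*% t(p$Wd2)
  if (!is.null(drop_masks)) dD1 <- dD1 * drop_masks$m1
  dZd1 <- dD1 * (fw$Zd1 > 0)
  g$bd1 <- colSums(dZd1)
  g$Wd1 <- crossprod(fw$C, dZd1)
  dC <- dZd1 %*% t(p$Wd1)
  # attention backward
  dCexp <- dC[ci$group, , drop = FALSE]
  dH <- fw$alpha_vec * dCexp
  dalpha <- rowSums(fw$H * dCexp)
  Dm <- matrix(dalpha, nrow = d$L2p)
  ssum <- colSums(fw$alpha * Dm)
  dE <- fw$alpha * sweep(Dm, 2, ssum)
  de <- as.numeric(dE) / cfg$attention_temperature
  g$va <- as.numeric(crossprod(fw$S, de))
  dSpre <- tcrossprod(de, p$va) * (1 - fw$S^2)
  g$ba <- colSums(dSpre)
  g$Wa <- crossprod(fw$H, dSpre)
  dH <- dH + dSpre %*% t(p$Wa)
  # pool2 / conv2 backward
  dA2 <- maxpool_bwd(dH, fw$pl2$amax, ci$pool2_base, B * d$L2)
  dZ2 <- dA2 * (fw$Z2 > 0)
  g$b2 <- colSums(dZ2)
  g$W2 <- crossprod(fw$M2, dZ2)
  dM2 <- dZ2 %*% t(p$W2)
  dA1p <- col2im_add(dM2, ci$i2, cfg$conv2_kernel,
                     B * d$L1p, cfg$conv1_filters)
  # pool1 / conv1 backward (input gradient not needed)
  dA1 <- maxpool_bwd(dA1p, fw$pl1$amax, ci$pool1_base, B * d$L1)
  dZ1 <- dA1 * (fw$Z1 > 0)
  g$b1 <- colSums(dZ1)
  g$W1 <- crossprod(fw$M1, dZ1)
  g
}

bce_loss <- function(y, prob) {
  eps <- 1e-12
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

#' Train the CNN-attention classifier
#'
#' Fixed-epoch Adam training on binary cross-entropy; dropout is active only
#' during training, and per-epoch loss/accuracy on the training (and, when
#' given, validation) data is recorded. Inputs are centered per feature
#' (window) by the training-set means; the centering vector is stored on the
#' model and re-applied at prediction time. Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param model An untrained model from [build_model()] (or a trained one to
#'   continue training).
#' @param X_train samples x windows numeric matrix (stage normalized or
#'   imputed), or a `coverage_matrix`.
#' @param y_train 0/1 labels (taken from the `coverage_matrix` when omitted).
#' @param X_val,y_val Optional validation data, monitored only (no early
#'   stopping).
#' @return The trained `cfcnn` with `history` (per-epoch data.frame) and
#'   `attention_window_weights` left `NULL` until [attention_weights()] is
#'   called.
#' @export
train_model <- function(model, X_train, y_train = NULL,
                        X_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "cfcnn"))
  if (inherits(X_train, "coverage_matrix")) {
    y_train <- y_train %||% X_train$labels
    X_train <- X_train$values
  }
  if (inherits(X_val, "coverage_matrix")) {
    y_val <- y_val %||% X_val$labels
    X_val <- X_val$values
  }
  X_train <- as.matrix(X_train)
  if (ncol(X_train) != model$dims$N)
    stop2("X_train has ", ncol(X_train), " columns; model expects ",
          model$dims$N)
  y_train <- as.numeric(y_train)
  if (length(unique(y_train)) < 2)
    stop2("training labels contain a single class")
  cfg <- model$cfg
  n <- nrow(X_train)
  model$feature_means <- colMeans(X_train)
  Xc <- sweep(X_train, 2, model$feature_means)
  Xvc <- if (!is.null(X_val))
    sweep(as.matrix(X_val), 2, model$feature_means)
  # Adam state
  ad_m <- lapply(model$params, function(w) w * 0)
  ad_v <- ad_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  ci_cache <- list()
  get_ci <- function(B) {
    key <- as.character(B)
    if (is.null(ci_cache[[key]]))
      ci_cache[[key]] <<- conv_indices(cfg, model$dims, B)
    ci_cache[[key]]
  }
  shuffle_seed <- derive_seed(cfg$seed, "shuffle")
  dropout_seed <- derive_seed(cfg$seed, "dropout")
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(shuffle_seed + ep, sample.int(n))
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0; ep_correct <- 0
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1, n)]
      B <- length(idx)
      Xb <- Xc[idx, , drop = FALSE]
      yb <- y_train[idx]
      dm <- NULL
      if (cfg$dropout_rate > 0) {
        keepp <- 1 - cfg$dropout_rate
        dm <- with_seed(dropout_seed + ep * 10007 + bi, list(
          m1 = matrix(stats::rbinom(B * cfg$dense1_units, 1, keepp),
                      B, cfg$dense1_units) / keepp,
          m2 = matrix(stats::rbinom(B * cfg$dense2_units, 1, keepp),
                      B, cfg$dense2_units) / keepp))
      }
      fw <- cfcnn_forward(model, Xb, ci = get_ci(B), keep = TRUE,
                          drop_masks = dm)
      g <- cfcnn_backward(model, fw, yb, dm)
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(g)) {
        ad_m[[nm]] <- b1 * ad_m[[nm]] + (1 - b1) * g[[nm]]
        ad_v[[nm]] <- b2 * ad_v[[nm]] + (1 - b2) * g[[nm]]^2
        model$params[[nm]] <- model$params[[nm]] -
          cfg$learning_rate * corr * ad_m[[nm]] / (sqrt(ad_v[[nm]]) + eps)
      }
      ep_loss <- ep_loss + bce_loss(yb, fw$prob) * B
      ep_correct <- ep_correct + sum((fw$prob > 0.5) == (yb == 1))
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n, acc = ep_correct / n,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(Xvc) && nrow(Xvc) > 0) {
      pv <- cfcnn_predict_centered(model, Xvc)
      row$val_loss <- bce_loss(as.numeric(y_val), pv)
      row$val_acc <- mean((pv > 0.5) == (as.numeric(y_val) == 1))
    }
    hist[[ep]] <- row
  }
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model
}

# Evaluation-mode probabilities on already-centered input, chunked to bound
# the im2col working set.
cfcnn_predict_centered <- function(model, Xc, chunk = 256L) {
  n <- nrow(Xc)
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    out[idx] <- cfcnn_forward(model, Xc[idx, , drop = FALSE])$prob
  }
  out
}

#' Predict class-1 probabilities (and optional hard labels)
#'
#' @param object A trained `cfcnn`.
#' @param X samples x windows matrix or `coverage_matrix` with the model's
#'   window count.
#' @param type `"prob"` (default) for sigmoid probabilities, `"class"` for
#'   hard 0/1 labels at the configured threshold (class 1 iff probability is
#'   strictly above it: exactly 0.5 at the default threshold gives class 0).
#' @param ... Unused.
#' @export
predict.cfcnn <- function(object, X, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!object$trained) stop2("model is untrained")
  if (inherits(X, "coverage_matrix")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != object$dims$N)
    stop2("X has ", ncol(X), " columns; model expects ", object$dims$N)
  p <- cfcnn_predict_centered(object,
                              sweep(X, 2, object$feature_means))
  if (type == "class") as.numeric(p > object$cfg$threshold) else p
}

# Receptive field (input window range, 1-based inclusive) of each final
# pooled position.
receptive_fields <- function(cfg, d) {
  t <- seq_len(d$L2p)
  u_lo <- (t - 1) * cfg$pool2 + 1
  u_hi <- t * cfg$pool2
  v_lo <- u_lo
  v_hi <- u_hi + cfg$conv2_kernel - 1
  w_lo <- (v_lo - 1) * cfg$pool1 + 1
  w_hi <- v_hi * cfg$pool1
  in_lo <- pmax(1, w_lo)
  in_hi <- pmin(d$N, w_hi + cfg$conv1_kernel - 1)
  cbind(lo = in_lo, hi = in_hi)
}

#' Per-window attention weights
#'
#' Averages the softmax attention scores over a reference set (typically the
#' training data), then maps each pooled position's weight back to input
#' windows by spreading it uniformly over the windows in its receptive
#' field; the result is renormalized to sum to 1. This is the 1 x N weight
#' array ranking each window's contribution to the classification.
#'
#' @param tm A trained `cfcnn`.
#' @param X_ref Reference samples (matrix or `coverage_matrix`), non-empty.
#' @return Numeric vector of length N; non-negative, sums to 1. Invariant to
#'   the ordering of `X_ref` rows.
#' @export
attention_weights <- function(tm, X_ref) {
  stopifnot(inherits(tm, "cfcnn"))
  if (!tm$trained) stop2("model is untrained")
  if (inherits(X_ref, "coverage_matrix")) X_ref <- X_ref$values
  X_ref <- as.matrix(X_ref)
  if (nrow(X_ref) == 0) stop2("reference set is empty")
  if (ncol(X_ref) != tm$dims$N)
    stop2("X_ref has ", ncol(X_ref), " columns; model expects ", tm$dims$N)
  Xc <- sweep(X_ref, 2, tm$feature_means)
  d <- tm$dims
  if (d$L2p == 1) return(rep(1 / d$N, d$N))
  acc <- numeric(d$L2p)
  n <- nrow(Xc)
  for (s in seq(1, n, by = 256L)) {
    idx <- s:min(s + 255L, n)
    fw <- cfcnn_forward(tm, Xc[idx, , drop = FALSE])
    acc <- acc + rowSums(fw$alpha)
  }
  pos_w <- acc / n
  rf <- receptive_fields(tm$cfg, d)
  w <- numeric(d$N)
  for (t in seq_len(d$L2p)) {
    rng <- rf[t, 1]:rf[t, 2]
    w[rng] <- w[rng] + pos_w[t] / length(rng)
  }
  w / sum(w)
}

#' Largest-remainder train/validation/test split
#'
#' Partition sizes are the largest-remainder apportionment of
#' `fractions * n` (ties broken in the order train > validation > test);
#' membership is a seeded uniform permutation.
#'
#' @param n Number of samples (>= 3).
#' @param fractions Named fractions summing to 1.
#'   Default `c(train = 0.75, val = 0.05, test = 0.20)`.
#' @param seed Permutation seed.
#' @return A `split_spec`: list with `sizes` and index vectors `train`,
#'   `val`, `test` (disjoint, exhaustive, 1-based).
#' @export
split_dataset <- function(n, fractions = c(train = 0.75, val = 0.05,
                                           test = 0.20), seed = 1) {
  if (!is_count(n) || n < 3) stop2("n must be an integer >= 3")
  if (abs(sum(fractions) - 1) > 1e-9) stop2("fractions must sum to 1")
  target <- fractions * n
  sizes <- floor(target)
  rem <- target - sizes
  left <- n - sum(sizes)
  if (left > 0) {
    # largest remainder; ties broken by position order (train > val > test)
    ord <- order(-rem, seq_along(rem))
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  sizes <- stats::setNames(as.integer(sizes), names(fractions))
  perm <- with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  idx <- list()
  startp <- 1L
  for (i in seq_along(sizes)) {
    idx[[names(sizes)[i]]] <-
      if (sizes[i] > 0) sort(perm[startp:ends[i]]) else integer(0)
    startp <- ends[i] + 1L
  }
  structure(list(n = n, fractions = fractions, seed = seed,
                 sizes = sizes, train = idx$train, val = idx$val,
                 test = idx$test),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: n=%d -> %s\n", x$n,
              paste(sprintf("%s %d", names(x$sizes), x$sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per configuration in the cartesian grid and scores it by
#' AUC on the validation partition; ties are broken by smaller parameter
#' count. The full score table is returned alongside the winner.
#'
#' @param space Named list of value vectors for [model_config()] fields
#'   (e.g. `list(conv1_filters = c(8, 16), conv1_kernel = c(4, 8))`).
#' @param X,y Data matrix and 0/1 labels.
#' @param base_config A [model_config()] supplying all non-searched fields.
#' @param split Optional [split_dataset()] result; by default an internal
#'   75/5/20 split seeded from `base_config$seed`.
#' @return List with `best_config`, `best_score`, and `table` (one row per
#'   grid point: hyperparameters, validation AUC, parameter count).
#' @export
grid_search <- function(space, X, y, base_config = model_config(),
                        split = NULL) {
  if (length(space) == 0 || any(lengths(space) == 0)) stop2("empty grid")
  if (inherits(X, "coverage_matrix")) {
    y <- y %||% X$labels
    X <- X$values
  }
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  if (is.null(split)) split <- split_dataset(nrow(X), seed = base_config$seed)
  rows <- vector("list", nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    for (nm in names(grid)) cfg[[nm]] <- grid[i, nm]
    cfg <- do.call(model_config, unclass(cfg))
    fit <- tryCatch({
      mdl <- build_model(cfg, ncol(X))
      mdl <- train_model(mdl, X[split$train, , drop = FALSE], y[split$train])
      pv <- predict(mdl, X[split$val, , drop = FALSE])
      list(auc = fast_auc(y[split$val], pv),
           n_par = attr(mdl, "n_parameters"), model = mdl)
    }, error = function(e) list(auc = NA_real_, n_par = NA_integer_,
                                model = NULL, err = conditionMessage(e)))
    rows[[i]] <- cbind(grid[i, , drop = FALSE],
                       data.frame(val_auc = fit$auc, n_parameters = fit$n_par))
    models[[i]] <- fit$model
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- which(!is.na(tab$val_auc))
  if (length(ok) == 0) stop2("every grid configuration failed to train")
  best <- ok[order(-tab$val_auc[ok], tab$n_parameters[ok])][1]
  list(best_config = models[[best]]$cfg, best_model = models[[best]],
       best_score = tab$val_auc[best], table = tab)
}
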
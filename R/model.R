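# The densely connected inception CNN for clip-level seizure probability.
# Each inception block applies three parallel 1-D temporal convolutions
# (stride 2) and concatenates their outputs channel-wise together with a
# stride-2 average-pooled copy of its input, so every block sees the
# concatenation of all previous block outputs (dense connectivity). An
# adaptive average pool to a fixed number of time bins feeds two fully
# connected layers ending in a single logistic output, which makes the
# parameter count independent of clip length (12-s and 60-s models share
# one architecture). Forward and backward passes are implemented with
# im2col-style BLAS matrix products; no deep learning framework is
# available in this environment.

#' Dense-inception architecture configuration
#'
#' Two presets are provided. `"paper"` is the full-scale architecture: 8
#' inception blocks, kernel widths 3/8/24 samples, 33 filters per branch,
#' adaptive pooling to 4 bins and a 2865-unit hidden layer, which yields
#' exactly 12,677,803 parameters. `"desk"` is a small, fast preset
#' (3 blocks, 4 filters per branch, an 8x average-pool front end, ~8k
#' parameters) for CPU-scale experiments on 12-s clips.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param n_blocks Number of inception blocks.
#' @param kernel_sizes Exactly 3 temporal kernel widths (samples).
#' @param growth Filters per branch (each block adds `3 * growth` channels).
#' @param pool_out Adaptive average-pool output length (time bins).
#' @param fc_sizes Widths of the two fully connected layers; the second must
#'   be 1 (the logistic output).
#' @param dropout_p Dropout probability (default 0.2), applied to the last
#'   layer; see `dropout_position`.
#' @param dropout_position `"fc2_input"` (default: on the input to the final
#'   FC layer) or `"fc1_input"`.
#' @param clip_len_s,fs,n_channels Input geometry.
#' @param front_pool Average-pool factor applied to the raw clip before the
#'   first block (1 = none); must divide the clip's sample count.
#' @param width_multiplier Scales `growth` and the hidden FC width (rounded);
#'   for quick width sweeps around a preset.
#' @param leaky_slope Negative slope of the leaky-ReLU activations.
#' @return Object of class `dense_inception_config`.
#' @export
dense_inception_config <- function(preset = c("desk", "paper"),
                                   n_blocks = NULL, kernel_sizes = NULL,
                                   growth = NULL, pool_out = NULL,
                                   fc_sizes = NULL, dropout_p = 0.2,
                                   dropout_position = c("fc2_input", "fc1_input"),
                                   clip_len_s = 12, fs = 200, n_channels = 19,
                                   front_pool = NULL, width_multiplier = 1,
                                   leaky_slope = 0.1) {
  preset <- match.arg(preset)
  dropout_position <- match.arg(dropout_position)
  def <- if (preset == "paper") {
    list(n_blocks = 8L, kernel_sizes = c(3L, 8L, 24L), growth = 33L,
         pool_out = 4L, fc_sizes = c(2865L, 1L), front_pool = 1L)
  } else {
    list(n_blocks = 3L, kernel_sizes = c(3L, 5L, 9L), growth = 4L,
         pool_out = 4L, fc_sizes = c(16L, 1L), front_pool = 8L)
  }
  cfg <- list(preset = preset,
              n_blocks = if (is.null(n_blocks)) def$n_blocks else as.integer(n_blocks),
              kernel_sizes = if (is.null(kernel_sizes)) def$kernel_sizes else as.integer(kernel_sizes),
              growth = if (is.null(growth)) def$growth else as.integer(growth),
              pool_out = if (is.null(pool_out)) def$pool_out else as.integer(pool_out),
              fc_sizes = if (is.null(fc_sizes)) def$fc_sizes else as.integer(fc_sizes),
              dropout_p = dropout_p, dropout_position = dropout_position,
              clip_len_s = clip_len_s, fs = fs, n_channels = as.integer(n_channels),
              front_pool = if (is.null(front_pool)) def$front_pool else as.integer(front_pool),
              width_multiplier = width_multiplier, leaky_slope = leaky_slope)
  if (width_multiplier != 1) {
    cfg$growth <- max(1L, as.integer(round(cfg$growth * width_multiplier)))
    cfg$fc_sizes[1] <- max(1L, as.integer(round(cfg$fc_sizes[1] * width_multiplier)))
  }
  if (length(cfg$kernel_sizes) != 3L)
    abort_invalid("an inception block requires exactly 3 kernel sizes",
                  class = "weakeeg_invalid_config")
  if (length(cfg$fc_sizes) != 2L || cfg$fc_sizes[2] != 1L)
    abort_invalid("exactly 2 fully connected layers ending in width 1 are required",
                  class = "weakeeg_invalid_config")
  if (dropout_p < 0 || dropout_p >= 1)
    abort_invalid("dropout_p must be in [0, 1)", class = "weakeeg_invalid_config")
  n_in <- round(cfg$clip_len_s * cfg$fs)
  if (n_in %% cfg$front_pool != 0)
    abort_invalid("front_pool must divide the clip sample count",
                  class = "weakeeg_invalid_config")
  structure(cfg, class = "dense_inception_config")
}

# Per-layer geometry: input/output lengths and channel counts.
config_shapes <- function(cfg) {
  t_len <- round(cfg$clip_len_s * cfg$fs) %/% cfg$front_pool
  c_in <- cfg$n_channels
  blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    t_out <- ceiling(t_len / 2)
    blocks[[b]] <- list(t_in = t_len, t_out = t_out, c_in = c_in,
                        c_out = c_in + 3L * cfg$growth)
    t_len <- t_out
    c_in <- c_in + 3L * cfg$growth
  }
  if (t_len < cfg$pool_out)
    abort_invalid("clip too short for the configured pooling depth",
                  class = "weakeeg_invalid_config")
  list(blocks = blocks, t_final = t_len, c_final = c_in,
       flat = c_in * cfg$pool_out)
}

#' Closed-form parameter count of a configuration
#'
#' Convolution weights and biases plus the two FC layers, computed from the
#' shape arithmetic alone (no model is built). Used as the independent oracle
#' for the built model's parameter store.
#'
#' @param config A [dense_inception_config()].
#' @return Integer parameter count.
#' @export
count_params <- function(config) {
  sh <- config_shapes(config)
  n <- 0
  for (blk in sh$blocks)
    n <- n + sum(config$kernel_sizes) * blk$c_in * config$growth + 3L * config$growth
  h <- config$fc_sizes[1]
  n + sh$flat * h + h + h * 1L + 1L
}

#' Build a dense-inception model
#'
#' Initializes every convolutional and fully connected parameter with a
#' seeded fan-in (He) scheme. The returned handle carries the config, a named
#' parameter store (the layer registry), and per-parameter trainable flags.
#'
#' @param config A [dense_inception_config()].
#' @param seed Initialization seed.
#' @return Object of class `dense_inception`.
#' @export
build_model <- function(config, seed = 1) {
  stopifnot(inherits(config, "dense_inception_config"))
  sh <- config_shapes(config)
  params <- list()
  with_seed(seed, {
    for (b in seq_len(config$n_blocks)) {
      c_in <- sh$blocks[[b]]$c_in
      for (j in 1:3) {
        k <- config$kernel_sizes[j]
        fan_in <- k * c_in
        params[[sprintf("block%d.conv%d.W", b, j)]] <-
          matrix(stats::rnorm(fan_in * config$growth, sd = sqrt(2 / fan_in)),
                 fan_in, config$growth)
        params[[sprintf("block%d.conv%d.b", b, j)]] <- rep(0, config$growth)
      }
    }
    h <- config$fc_sizes[1]
    params[["fc1.W"]] <- matrix(stats::rnorm(sh$flat * h, sd = sqrt(2 / sh$flat)),
                                 sh$flat, h)
    params[["fc1.b"]] <- rep(0, h)
    params[["fc2.W"]] <- matrix(stats::rnorm(h, sd = sqrt(1 / h)), h, 1)
    params[["fc2.b"]] <- 0
  })
  trainable <- rep(TRUE, length(params))
  names(trainable) <- names(params)
  structure(list(config = config, shapes = sh, params = params,
                 trainable = trainable, init_seed = seed),
            class = "dense_inception")
}

#' @method print dense_inception
#' @export
print.dense_inception <- function(x, ...) {
  cat(sprintf("<dense_inception '%s': %d blocks, kernels %s, growth %d, %s parameters (%d trainable tensors)>\n",
              x$config$preset, x$config$n_blocks,
              paste(x$config$kernel_sizes, collapse = "/"), x$config$growth,
              format(n_params(x), big.mark = ","), sum(x$trainable)))
  invisible(x)
}

#' Total parameter count of a built model
#' @param model A `dense_inception` model.
#' @return Integer count over the parameter store.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Count of trainable parameters
#' @param model A `dense_inception` model.
#' @return Integer count over parameters with trainable flag set.
#' @export
n_trainable_params <- function(model) {
  sum(vapply(names(model$params)[model$trainable], function(nm)
    length(model$params[[nm]]), numeric(1)))
}

#' Freeze everything except the two fully connected layers
#'
#' Marks all convolutional parameters non-trainable; only `fc1` and `fc2`
#' receive optimizer updates afterwards. Used by transfer fine-tuning.
#'
#' @param model A `dense_inception` model.
#' @return The model with updated trainable flags.
#' @export
freeze_all_but_last_two_fc <- function(model) {
  model$trainable[] <- grepl("^fc[12]\\.", names(model$params))
  model
}

#' Mark all parameters trainable
#' @param model A `dense_inception` model.
#' @return The model with every trainable flag set.
#' @export
unfreeze_all <- function(model) {
  model$trainable[] <- TRUE
  model
}

# ---- forward / backward ----------------------------------------------------

leaky_relu <- function(x, a) x * (a + (1 - a) * (x > 0))

# Index matrices for stride-2 convolution/pooling are pure functions of
# (t_in, k, B); they are memoized per session because every training batch
# reuses the same geometry.
.idx_cache <- new.env(parent = emptyenv())

# Forward gather G ((t_out*B) x k; 0 = zero pad) and, per tap, the reverse
# (transposed-conv) gather R[[j]] (length t_in*B; 0 = no contribution), for a
# stride-2 'same' convolution over B stacked clips of length t_in.
conv_index <- function(t_in, k, B, stride = 2L) {
  key <- sprintf("c%d_%d_%d_%d", t_in, k, B, stride)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  t_out <- ceiling(t_in / stride)
  pad <- (k - 1L) %/% 2L
  starts <- stride * (seq_len(t_out) - 1L) + 1L - pad
  P <- outer(starts, 0:(k - 1L), "+")
  P[P < 1L | P > t_in] <- 0L
  G <- P
  if (B > 1L) {
    offs <- rep((seq_len(B) - 1L) * t_in, each = t_out)
    G <- P[rep(seq_len(t_out), B), , drop = FALSE]
    G <- G + offs * (G > 0L)
  }
  fwd <- lapply(seq_len(k), function(j) {
    dst <- which(G[, j] > 0L)
    list(dst = dst, src = G[dst, j], full = length(dst) == nrow(G))
  })
  s <- seq_len(t_in)
  bwd <- lapply(seq_len(k), function(j) {
    num <- s - 1L + pad - (j - 1L)
    t <- num %/% stride + 1L
    ok <- (num %% stride == 0L) & t >= 1L & t <= t_out
    r <- integer(t_in); r[ok] <- t[ok]
    if (B > 1L) {
      offs <- rep((seq_len(B) - 1L) * t_out, each = t_in)
      r <- rep(r, B)
      r <- r + offs * (r > 0L)
    }
    r # source output column per input column; 0 = no contribution
  })
  out <- list(fwd = fwd, bwd = bwd, t_out = t_out, n_out = t_out * B)
  assign(key, out, envir = .idx_cache)
  out
}

# im2col in channels-first layout: X is (C x t_in*B) and M is
# (k*C x t_out*B); per tap, valid output columns gather input columns
# directly (column subsetting is contiguous in R), the rest stay zero.
gather_cols <- function(X, ci) {
  k <- length(ci$fwd); C <- nrow(X)
  M <- matrix(0, k * C, ci$n_out)
  for (j in seq_len(k)) {
    f <- ci$fwd[[j]]
    rows <- (j - 1L) * C + seq_len(C)
    if (f$full) M[rows, ] <- X[, f$src, drop = FALSE]
    else M[rows, f$dst] <- X[, f$src, drop = FALSE]
  }
  M
}

# Input gradient of the stride-2 convolution: per tap the output->input map
# is affine, so the transposed convolution is a zero-padded column gather
# (no sub-assignment, which would copy the accumulator).
conv_backward_input <- function(dXin, dM, ci, C) {
  for (j in seq_along(ci$bwd)) {
    rows <- (j - 1L) * C + seq_len(C)
    blkz <- cbind(matrix(0, C, 1L), dM[rows, , drop = FALSE])
    dXin <- dXin + blkz[, ci$bwd[[j]] + 1L, drop = FALSE]
  }
  dXin
}

# Stride-2 average pooling (the dense passthrough), channels-first.
pool_index <- function(t_in, B) {
  key <- sprintf("p%d_%d", t_in, B)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  t_out <- ceiling(t_in / 2)
  i1 <- 2L * seq_len(t_out) - 1L
  i2 <- 2L * seq_len(t_out)
  odd_tail <- i2[t_out] > t_in
  if (odd_tail) i2[t_out] <- i2[t_out] - 1L # duplicate; corrected below
  cnt <- rep(2L, t_out); if (odd_tail) cnt[t_out] <- 1L
  rp <- (seq_len(t_in) + 1L) %/% 2L # input col -> output col
  if (B > 1L) {
    offs_in <- rep((seq_len(B) - 1L) * t_in, each = t_out)
    offs_out <- rep((seq_len(B) - 1L) * t_out, each = t_in)
    i1 <- rep(i1, B) + offs_in
    i2 <- rep(i2, B) + offs_in
    cnt <- rep(cnt, B)
    rp <- rep(rp, B) + offs_out
  }
  tails <- which(cnt == 1L)
  out <- list(i1 = i1, i2 = i2, cnt = cnt, tails = tails, rp = rp,
              t_out = t_out)
  assign(key, out, envir = .idx_cache)
  out
}

pool2 <- function(X, t_in, B) {
  pk <- pool_index(t_in, B)
  s <- (X[, pk$i1, drop = FALSE] + X[, pk$i2, drop = FALSE]) / 2
  if (length(pk$tails))
    s[, pk$tails] <- X[, pk$i1[pk$tails], drop = FALSE]
  list(out = s, pk = pk)
}

pool2_backward <- function(dOut, pk) {
  d <- dOut / rep(pk$cnt, each = nrow(dOut))
  d[, pk$rp, drop = FALSE]
}

# Adaptive average pooling as one matrix product: S is (t_final*B x P*B)
# with S[t, bin] = 1/count(bin) inside the bin's clip, so out = X %*% S and
# the backward pass is dX = dOut %*% t(S).
adaptive_pool_matrix <- function(t_final, P, B) {
  key <- sprintf("a%d_%d_%d", t_final, P, B)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  bins <- ceiling(seq_len(t_final) * P / t_final)
  cnt <- tabulate(bins, nbins = P)
  S1 <- matrix(0, t_final, P)
  S1[cbind(seq_len(t_final), bins)] <- 1 / cnt[bins]
  S <- matrix(0, t_final * B, P * B)
  for (b in seq_len(B))
    S[(b - 1L) * t_final + seq_len(t_final), (b - 1L) * P + seq_len(P)] <- S1
  assign(key, S, envir = .idx_cache)
  S
}

# Forward pass over a batch of B stacked clips (channels-first: xb is
# (C x n_samples*B)). Returns probabilities plus (optionally) the caches
# needed for the backward pass.
nn_forward <- function(model, xb, B, train = FALSE, keep_cache = FALSE,
                       dropout_mask = NULL) {
  cfg <- model$config; sh <- model$shapes; P <- model$params
  a <- cfg$leaky_slope
  cache <- list()
  X <- xb
  if (cfg$front_pool > 1L) {
    fp <- cfg$front_pool
    t0 <- sh$blocks[[1]]$t_in
    A <- X
    dim(A) <- c(nrow(X), fp, t0 * B)
    X <- A[, 1, ]
    for (u in 2:fp) X <- X + A[, u, ]
    X <- X / fp
  }
  for (b in seq_len(cfg$n_blocks)) {
    blk <- sh$blocks[[b]]
    branches <- vector("list", 3)
    bc <- list()
    for (j in 1:3) {
      k <- cfg$kernel_sizes[j]
      ci <- conv_index(blk$t_in, k, B)
      M <- gather_cols(X, ci)
      Z <- crossprod(P[[sprintf("block%d.conv%d.W", b, j)]], M)
      Z <- Z + P[[sprintf("block%d.conv%d.b", b, j)]]
      H <- leaky_relu(Z, a)
      branches[[j]] <- H
      if (keep_cache) bc[[j]] <- list(ci = ci, M = M, Z = Z)
    }
    pl <- pool2(X, blk$t_in, B)
    Xn <- rbind(pl$out, branches[[1]], branches[[2]], branches[[3]])
    if (keep_cache) cache[[sprintf("block%d", b)]] <-
      list(branches = bc, pool = pl$pk, t_in = blk$t_in, c_in = blk$c_in)
    X <- Xn
  }
  # adaptive average pool to pool_out bins, then flatten per clip
  Pp <- cfg$pool_out
  S <- adaptive_pool_matrix(sh$t_final, Pp, B)
  Xp <- X %*% S # (c_final x Pp*B)
  A <- array(Xp, dim = c(sh$c_final, Pp, B))
  Fmat <- matrix(aperm(A, c(3, 2, 1)), B, Pp * sh$c_final)
  drop_in_fc1 <- cfg$dropout_position == "fc1_input"
  F1in <- Fmat
  m1 <- NULL
  if (train && cfg$dropout_p > 0 && drop_in_fc1) {
    m1 <- if (is.null(dropout_mask)) matrix(stats::rbinom(length(F1in), 1, 1 - cfg$dropout_p),
                                            nrow(F1in)) / (1 - cfg$dropout_p) else dropout_mask
    F1in <- F1in * m1
  }
  Z1 <- F1in %*% P[["fc1.W"]]
  Z1 <- Z1 + rep(P[["fc1.b"]], each = nrow(Z1))
  H1 <- leaky_relu(Z1, a)
  H1d <- H1
  m2 <- NULL
  if (train && cfg$dropout_p > 0 && !drop_in_fc1) {
    m2 <- if (is.null(dropout_mask)) matrix(stats::rbinom(length(H1), 1, 1 - cfg$dropout_p),
                                            nrow(H1)) / (1 - cfg$dropout_p) else dropout_mask
    H1d <- H1 * m2
  }
  z <- drop(H1d %*% P[["fc2.W"]]) + P[["fc2.b"]]
  prob <- 1 / (1 + exp(-z))
  if (!keep_cache) return(list(prob = prob, logit = z))
  cache$S <- S
  cache$F1in <- F1in; cache$Z1 <- Z1; cache$H1d <- H1d
  cache$m1 <- m1; cache$m2 <- m2; cache$B <- B
  list(prob = prob, logit = z, cache = cache)
}

# Backward pass: returns named gradient list matching the parameter store.
nn_backward <- function(model, fw, y) {
  cfg <- model$config; sh <- model$shapes; P <- model$params
  a <- cfg$leaky_slope; cc <- fw$cache; B <- cc$B
  grads <- list()
  dz <- matrix((fw$prob - y) / B, ncol = 1) # BCE-with-logits
  grads[["fc2.W"]] <- crossprod(cc$H1d, dz)
  grads[["fc2.b"]] <- sum(dz)
  dH1d <- tcrossprod(dz, P[["fc2.W"]])
  if (!is.null(cc$m2)) dH1d <- dH1d * cc$m2
  dZ1 <- dH1d * (a + (1 - a) * (cc$Z1 > 0))
  grads[["fc1.W"]] <- crossprod(cc$F1in, dZ1)
  grads[["fc1.b"]] <- colSums(dZ1)
  dF1in <- tcrossprod(dZ1, P[["fc1.W"]])
  if (!is.null(cc$m1)) dF1in <- dF1in * cc$m1
  # unflatten to (c_final x Pp*B), undo the adaptive pooling matmul
  Pp <- cfg$pool_out
  A <- array(dF1in, dim = c(B, Pp, sh$c_final))
  dXp <- matrix(aperm(A, c(3, 2, 1)), sh$c_final, Pp * B)
  dX <- tcrossprod(dXp, cc$S)
  for (b in rev(seq_len(cfg$n_blocks))) {
    bc <- cc[[sprintf("block%d", b)]]
    g <- cfg$growth
    C_in <- bc$c_in
    dXin <- pool2_backward(dX[seq_len(C_in), , drop = FALSE], bc$pool)
    for (j in 1:3) {
      rows <- C_in + (j - 1L) * g + seq_len(g)
      cj <- bc$branches[[j]]
      dZ <- dX[rows, , drop = FALSE] * (a + (1 - a) * (cj$Z > 0))
      grads[[sprintf("block%d.conv%d.W", b, j)]] <- tcrossprod(cj$M, dZ)
      grads[[sprintf("block%d.conv%d.b", b, j)]] <- rowSums(dZ)
      dM <- P[[sprintf("block%d.conv%d.W", b, j)]] %*% dZ
      dXin <- conv_backward_input(dXin, dM, cj$ci, C_in)
    }
    dX <- dXin
  }
  grads
}

# Channels-first batch assembly: (19 x n_samples*B).
stack_clips <- function(clips) {
  do.call(cbind, lapply(clips, function(cl)
    t(if (inherits(cl, "eeg_clip")) cl$x else cl)))
}

#' Predicted seizure probabilities for clips
#'
#' Deterministic evaluation-mode forward pass (dropout off); batch order is
#' irrelevant to the per-clip outputs.
#'
#' @param model A `dense_inception` model.
#' @param clips A `clip_dataset`, list of clips, or single clip/matrix.
#' @param batch_size Evaluation batch size.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, clips, batch_size = 64L) {
  stopifnot(inherits(model, "dense_inception"))
  if (inherits(clips, "eeg_clip") || is.matrix(clips)) clips <- list(clips)
  clips <- as_clip_list(clips)
  n_exp <- round(model$config$clip_len_s * model$config$fs)
  probs <- numeric(length(clips))
  i <- 1L
  while (i <= length(clips)) {
    j <- min(i + batch_size - 1L, length(clips))
    batch <- clips[i:j]
    xb <- stack_clips(batch)
    if (ncol(xb) != n_exp * length(batch) || nrow(xb) != model$config$n_channels)
      abort_invalid("clip shape does not match the model input shape",
                    class = "weakeeg_invalid_input")
    probs[i:j] <- nn_forward(model, xb, length(batch))$prob
    i <- j + 1L
  }
  probs
}
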
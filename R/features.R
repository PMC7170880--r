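# Hand-engineered feature battery for the classical baselines: per-channel
# time-domain statistics, DFT band energies, Daubechies-4 wavelet energies,
# pairwise lagged cross-correlation, and electrode-graph measures.

#' Default clinical frequency bands
#'
#' The fundamental rhythmic bands: delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-70 Hz.
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 70))
}

clip_matrix <- function(clip) {
  if (inherits(clip, "eeg_clip")) clip$x
  else if (is.matrix(clip)) clip
  else abort_invalid("expected an eeg_clip or a samples-by-channels matrix")
}

#' Time-domain features per channel
#'
#' Mean, variance, skewness, kurtosis, total signal area (`sum(|x|) * dt`),
#' peak-to-peak amplitude, zero-crossing count (strict sign changes after
#' mean removal), and decorrelation time (lag in seconds of the first zero
#' crossing of the autocorrelation, linearly interpolated). Skewness and
#' kurtosis are the standardized 3rd/4th central moments; kurtosis is
#' non-excess (a Gaussian scores 3). Constant channels score 0 for both by
#' convention.
#'
#' @param clip An `eeg_clip` or samples-by-channels matrix.
#' @param fs Sampling rate (taken from the clip when available).
#' @return Named numeric vector, names `<channel>.<feature>`.
#' @export
time_domain_features <- function(clip, fs = 200) {
  x <- clip_matrix(clip)
  if (inherits(clip, "eeg_clip")) fs <- clip$fs
  ch <- colnames(x); if (is.null(ch)) ch <- paste0("ch", seq_len(ncol(x)))
  out <- numeric(0)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    mu <- mean(v); cv <- v - mu
    m2 <- mean(cv^2)
    skew <- if (m2 > 0) mean(cv^3) / m2^1.5 else 0
    kurt <- if (m2 > 0) mean(cv^4) / m2^2 else 0
    zc <- {
      s <- sign(cv)
      s[abs(cv) < 1e-8 * max(abs(cv), 1e-300)] <- 0 # numerical zeros
      s <- s[s != 0]
      if (length(s) > 1) sum(s[-1] != s[-length(s)]) else 0
    }
    f <- c(mean = mu, variance = m2, skewness = skew, kurtosis = kurt,
           area = sum(abs(v)) / fs, peak_to_peak = diff(range(v)),
           zero_crossings = zc, decorrelation_time = decorrelation_time(cv, fs))
    names(f) <- paste(ch[j], names(f), sep = ".")
    out <- c(out, f)
  }
  out
}

# Lag (s) of the first zero crossing of the autocorrelation function,
# linearly interpolated between lags; the record length / fs when the ACF
# never crosses zero.
decorrelation_time <- function(cv, fs, max_lag_s = 2) {
  n <- length(cv)
  if (all(cv == 0)) return(0)
  lag_max <- min(n - 1L, round(max_lag_s * fs))
  # biased ACF via FFT
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(cv, rep(0, nfft - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(lag_max + 1L)] / nfft
  ac <- ac / ac[1]
  below <- which(ac <= 0)
  if (length(below) == 0) return(n / fs)
  k <- below[1] # 1-based; lag k-1 samples
  if (k <= 1) return(0)
  # interpolate between lag k-2 and k-1
  a0 <- ac[k - 1]; a1 <- ac[k]
  frac <- if (a0 == a1) 0 else a0 / (a0 - a1)
  ((k - 2) + frac) / fs
}

#' Frequency-domain features per channel
#'
#' Total spectral energy (`sum(x^2)`, Parseval-consistent with the DFT),
#' fractional energy in each clinical band, and Daubechies-4 discrete wavelet
#' transform detail-coefficient energies over `dwt_levels` dyadic levels
#' (normalized to fractions of total wavelet energy).
#'
#' @param clip An `eeg_clip` or matrix.
#' @param bands Band edges, see [eeg_bands()].
#' @param fs Sampling rate.
#' @param dwt_levels Number of DWT decomposition levels (default 5).
#' @return Named numeric vector.
#' @export
frequency_domain_features <- function(clip, bands = eeg_bands(), fs = 200,
                                      dwt_levels = 5) {
  x <- clip_matrix(clip)
  if (inherits(clip, "eeg_clip")) fs <- clip$fs
  ch <- colnames(x); if (is.null(ch)) ch <- paste0("ch", seq_len(ncol(x)))
  n <- nrow(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X2 <- Mod(stats::mvfft(x))^2
  out <- numeric(0)
  for (j in seq_len(ncol(x))) {
    tot <- sum(X2[, j]) / n # Parseval: equals sum(x^2)
    bf <- vapply(bands, function(b) {
      if (tot > 0) sum(X2[f >= b[1] & f < b[2], j]) / n / tot else 0
    }, numeric(1))
    names(bf) <- paste0(names(bands), "_frac")
    de <- dwt_detail_energies(x[, j], dwt_levels)
    det <- sum(de)
    de <- if (det > 0) de / det else de
    names(de) <- paste0("dwt_d", seq_along(de), "_frac")
    fj <- c(total_energy = tot, bf, de)
    names(fj) <- paste(ch[j], names(fj), sep = ".")
    out <- c(out, fj)
  }
  out
}

# Daubechies-4 (8-tap) scaling filter.
DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)

# One periodized DWT analysis step; odd-length inputs are extended by
# repeating the final sample.
dwt_step <- function(v, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1) # detail filter
  if (length(v) %% 2 == 1) v <- c(v, v[length(v)])
  n <- length(v); L <- length(h)
  idx <- outer(seq(1, n, by = 2), seq_len(L) - 1L, "+")
  idx <- ((idx - 1L) %% n) + 1L
  vm <- matrix(v[idx], ncol = L)
  list(approx = drop(vm %*% h), detail = drop(vm %*% g))
}

dwt_detail_energies <- function(v, levels) {
  e <- numeric(levels)
  for (l in seq_len(levels)) {
    s <- dwt_step(v, DB4_H)
    e[l] <- sum(s$detail^2)
    v <- s$approx
    if (length(v) < length(DB4_H)) break
  }
  e
}

#' Pairwise lagged cross-correlation features
#'
#' For each unordered channel pair, the maximum over lags within
#' `+/- max_lag_s` of the absolute normalized cross-correlation (global
#' normalization by the channel energies, values in [0, 1]). Pairs involving
#' a zero-variance channel score 0.
#'
#' @param clip An `eeg_clip` or matrix.
#' @param max_lag_s Lag search half-window in seconds (default 0.5).
#' @param fs Sampling rate.
#' @return Named numeric vector of `choose(n_channels, 2)` values
#'   (171 for the 19-channel montage), names `<chA>_x_<chB>`.
#' @export
connectivity_features <- function(clip, max_lag_s = 0.5, fs = 200) {
  x <- clip_matrix(clip)
  if (inherits(clip, "eeg_clip")) fs <- clip$fs
  if (ncol(x) < 2) abort_invalid("need at least 2 channels")
  ch <- colnames(x); if (is.null(ch)) ch <- paste0("ch", seq_len(ncol(x)))
  n <- nrow(x); C <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  ss <- colSums(xc^2)
  L <- min(n - 1L, round(max_lag_s * fs))
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::mvfft(rbind(xc, matrix(0, nfft - n, C)))
  out <- numeric(C * (C - 1) / 2); nm <- character(length(out))
  k <- 0L
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    k <- k + 1L
    nm[k] <- paste0(ch[i], "_x_", ch[j])
    if (ss[i] == 0 || ss[j] == 0) { out[k] <- 0; next }
    cc <- Re(stats::fft(X[, i] * Conj(X[, j]), inverse = TRUE)) / nfft
    # circular xcorr: lags 0..L at head, -1..-L at tail
    vals <- c(cc[seq_len(L + 1L)], cc[nfft - seq_len(L) + 1L])
    out[k] <- min(1, max(abs(vals)) / sqrt(ss[i] * ss[j]))
  }
  names(out) <- nm
  out
}

#' Electrode graph features
#'
#' Thresholds the pairwise max-abs-cross-correlation into an undirected graph
#' over the electrodes (edge when value >= threshold) and reports per-node
#' degree and local clustering coefficient plus the graph's global efficiency
#' (mean inverse shortest-path length; 0 for an edgeless graph).
#'
#' @param clip An `eeg_clip`, matrix, or a named connectivity vector from
#'   [connectivity_features()].
#' @param threshold Edge threshold (default 0.7).
#' @return Named numeric vector: `<ch>.degree`, `<ch>.clustering`,
#'   `global_efficiency`.
#' @export
graph_features <- function(clip, threshold = 0.7) {
  conn <- if (is.numeric(clip) && !is.matrix(clip) && !is.null(names(clip))) clip
          else connectivity_features(clip)
  ends <- strsplit(names(conn), "_x_", fixed = TRUE)
  ch <- unique(unlist(ends))
  adj <- matrix(0, length(ch), length(ch), dimnames = list(ch, ch))
  for (k in seq_along(conn)) if (conn[k] >= threshold) {
    adj[ends[[k]][1], ends[[k]][2]] <- 1
    adj[ends[[k]][2], ends[[k]][1]] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  deg <- igraph::degree(g)
  clus <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(clus) <- ch
  eff <- if (igraph::ecount(g) == 0) 0 else igraph::global_efficiency(g)
  out <- c(stats::setNames(deg, paste0(ch, ".degree")),
           stats::setNames(clus, paste0(ch, ".clustering")),
           global_efficiency = eff)
  out
}

#' Full feature vector for one clip
#'
#' Concatenates the time-domain, frequency-domain, connectivity, and graph
#' blocks; the layout is fixed for a given configuration.
#'
#' @param clip An `eeg_clip`.
#' @param bands,graph_threshold,dwt_levels Block parameters.
#' @return Named numeric vector.
#' @export
clip_features <- function(clip, bands = eeg_bands(), graph_threshold = 0.7,
                          dwt_levels = 5) {
  conn <- connectivity_features(clip)
  c(time_domain_features(clip),
    frequency_domain_features(clip, bands = bands, dwt_levels = dwt_levels),
    conn,
    graph_features(conn, threshold = graph_threshold))
}

#' Feature matrix for a clip collection
#'
#' @param clips A `clip_dataset` or list of clips.
#' @param ... Passed to [clip_features()].
#' @return Numeric matrix, one row per clip, named columns.
#' @export
feature_matrix <- function(clips, ...) {
  cl <- as_clip_list(clips)
  rows <- lapply(cl, clip_features, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  m
}
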
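# Polyphase resampling to the canonical 200 Hz rate with a Kaiser-windowed
# sinc low-pass. No signal-processing package ships with this environment, so
# the upfirdn path is implemented here (FFT convolution per channel).

kaiser_window <- function(t, beta) {
  # t in [-1, 1]
  besselI(beta * sqrt(pmax(0, 1 - t^2)), 0) / besselI(beta, 0)
}

# Kaiser-windowed sinc interpolation filter at the upsampled rate.
# zc: zero crossings per side; beta/roll follow the high-quality ("best")
# Kaiser design used for audio-grade resampling (beta ~14.77, rolloff 0.9475).
design_kaiser_lowpass <- function(up, down, zc = 32, beta = 14.769656,
                                  roll = 0.9475) {
  max_rate <- max(up, down)
  fc <- roll / max_rate # cutoff in units of the upsampled Nyquist
  nh <- zc * max_rate
  t <- (-nh):nh
  x <- fc * t
  h <- fc * ifelse(t == 0, 1, sin(pi * x) / (pi * x))
  h <- h * kaiser_window(t / nh, beta)
  list(h = up * h, delay = nh)
}

fft_filter_cols <- function(x, h) {
  n <- nrow(x); m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2)
  H <- stats::fft(c(h, rep(0, nfft - m)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  y[seq_len(n + m - 1L), , drop = FALSE]
}

#' Resample a signal to 200 Hz
#'
#' Polyphase rational resampling (upsample, Kaiser-windowed sinc low-pass,
#' downsample). When `src_fs` is already 200 the input is returned untouched,
#' bit for bit. Output length is `round(n_in * 200 / src_fs)`.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param src_fs Source sampling rate in Hz (positive, integer-valued).
#' @param target_fs Target rate (default 200).
#' @return Resampled vector/matrix at `target_fs`.
#' @export
resample_to_200hz <- function(x, src_fs, target_fs = 200) {
  if (!is.numeric(src_fs) || length(src_fs) != 1L || src_fs <= 0)
    abort_invalid("src_fs must be a positive scalar")
  if (src_fs == target_fs) return(x)
  if (abs(src_fs - round(src_fs)) > 1e-9 || abs(target_fs - round(target_fs)) > 1e-9)
    abort_invalid("sampling rates must be integer-valued Hz")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  g <- as.integer(gcd2(round(target_fs), round(src_fs)))
  up <- round(target_fs) %/% g
  down <- round(src_fs) %/% g
  n_in <- nrow(xm)
  n_out <- round(n_in * target_fs / src_fs)
  flt <- design_kaiser_lowpass(up, down)
  # upsample by zero insertion
  xu <- matrix(0, n_in * up, ncol(xm))
  xu[seq(1, n_in * up, by = up), ] <- xm
  y <- fft_filter_cols(xu, flt$h)
  idx <- flt$delay + 1L + (seq_len(n_out) - 1L) * down
  pad <- max(0L, max(idx) - nrow(y))
  if (pad > 0) y <- rbind(y, matrix(0, pad, ncol(y)))
  out <- y[idx, , drop = FALSE]
  if (!vec) colnames(out) <- colnames(xm)
  if (vec) drop(out) else out
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
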
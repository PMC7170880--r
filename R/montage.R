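# The 19-electrode 10-20 scalp montage used throughout the package.

#' Standard 10-20 channel names
#'
#' The 19 electrodes of the International 10-20 system, in the fixed column
#' order used by every signal matrix in this package.
#'
#' @return Character vector of length 19.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

# Approximate 2-D scalp coordinates (head radius 1, nose up) for the 19
# electrodes; used for smooth spatial falloff of focal discharges.
electrode_xy <- function() {
  m <- rbind(
    Fp1 = c(-0.31,  0.95), Fp2 = c( 0.31,  0.95),
    F3  = c(-0.39,  0.55), F4  = c( 0.39,  0.55),
    C3  = c(-0.50,  0.00), C4  = c( 0.50,  0.00),
    P3  = c(-0.39, -0.55), P4  = c( 0.39, -0.55),
    O1  = c(-0.31, -0.95), O2  = c( 0.31, -0.95),
    F7  = c(-0.81,  0.59), F8  = c( 0.81,  0.59),
    T3  = c(-1.00,  0.00), T4  = c( 1.00,  0.00),
    T5  = c(-0.81, -0.59), T6  = c( 0.81, -0.59),
    Fz  = c( 0.00,  0.58), Cz  = c( 0.00,  0.00),
    Pz  = c( 0.00, -0.58))
  colnames(m) <- c("x", "y")
  m[eeg_channels(), , drop = FALSE]
}

# Spatial weights in [0,1]: 1 on `focus` channels, Gaussian falloff with
# scalp distance elsewhere (sigma in head-radius units).
spatial_weights <- function(focus, sigma = 0.45) {
  xy <- electrode_xy()
  ch <- eeg_channels()
  if (!all(focus %in% ch)) abort_invalid("focus channels outside the 10-20 montage")
  w <- numeric(length(ch))
  names(w) <- ch
  fxy <- xy[focus, , drop = FALSE]
  for (i in seq_along(ch)) {
    d2 <- min(colSums((t(fxy) - xy[i, ])^2))
    w[i] <- exp(-d2 / (2 * sigma^2))
  }
  w[focus] <- 1
  w
}
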
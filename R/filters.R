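# Butterworth band-pass design and zero-phase filtering.
#
# No DSP package ships with the target environment, so the design is done
# here from first principles: analog Butterworth prototype -> low-pass to
# band-pass transform -> bilinear transform. Coefficients agree with
# reference implementations to machine precision (frozen check in the
# test suite).

# Polynomial coefficients (descending powers) from roots, complex-safe.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, ri * p)
  p
}

# Digital Butterworth band-pass (b, a) for an analog prototype of `order`.
# The resulting IIR filter has order 2 * `order`.
butter_bandpass_coef <- function(order, low, high, fs) {
  stopifnot(order >= 1, low > 0, high > low, high < fs / 2)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bilinear pre-warp of the band edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  ps <- p_proto * bw / 2
  p_bp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  k_bp <- bw^order
  fs2 <- 2 * fs
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, length(p_bp) - length(z_bp)))
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  list(b = Re(k_d * poly_from_roots(z_d)), a = Re(poly_from_roots(p_d)))
}

# Direct-form IIR filtering y[n] = sum(b x) - sum(a[-1] y), zero initial state.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb:length(xp)]
  if (length(a) > 1L) {
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  }
  u
}

# Zero-phase filtering: odd-reflection padding, forward then backward pass.
filtfilt_ba <- function(b, a, x) {
  pad <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= pad) {
    stop_vims("record too short for zero-phase filtering (need > ", pad, " samples)")
  }
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- iir_filter(b, a, c(pre, x, post))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter for ECG
#'
#' Applies a 3rd-order Butterworth band-pass (default 5--15 Hz) forward and
#' backward so the output has zero phase shift; phase distortion would bias
#' the detected R-peak times. The default band removes baseline wander, DC
#' drift, powerline interference and most T-wave energy while retaining the
#' QRS complex.
#'
#' @param ecg An [ecg_record()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Order of the analog Butterworth prototype (default 3; the
#'   digital band-pass has twice this order).
#' @return A filtered `ecg_record` with identical length, `fs` and
#'   `start_time`.
#' @export
bandpass_filter <- function(ecg, low = 5, high = 15, order = 3) {
  stopifnot(inherits(ecg, "ecg_record"))
  if (!(low > 0 && high > low && high < ecg$fs / 2)) {
    stop_vims("infeasible band [", low, ", ", high, "] Hz for fs = ", ecg$fs, " Hz")
  }
  ba <- butter_bandpass_coef(order, low, high, ecg$fs)
  ecg_record(filtfilt_ba(ba$b, ba$a, ecg$samples), ecg$fs, ecg$start_time)
}
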
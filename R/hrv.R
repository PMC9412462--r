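# Time- and frequency-domain HRV features.

#' Standard deviation of NN intervals (SDNN)
#'
#' Sample (n - 1 denominator) standard deviation of the NN intervals, ms.
#'
#' @param nn An `nn_series` (or numeric vector of intervals in ms).
#' @return SDNN in ms.
#' @export
sdnn <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 2L) stop_vims("SDNN needs at least 2 NN intervals")
  stats::sd(x)
}

#' pNN50
#'
#' Percentage of adjacent NN interval pairs differing by more than 50 ms
#' (strict inequality).
#'
#' @inheritParams sdnn
#' @param threshold Difference threshold in ms (default 50).
#' @return Percentage in \[0, 100\].
#' @export
pnn50 <- function(nn, threshold = 50) {
  x <- nn_intervals(nn)
  if (length(x) < 2L) stop_vims("pNN50 needs at least 2 NN intervals")
  100 * mean(abs(diff(x)) > threshold)
}

#' Mean heart rate
#'
#' @inheritParams sdnn
#' @return Heart rate in beats per minute, `60000 / mean(NN)`.
#' @export
mean_heart_rate <- function(nn) {
  x <- nn_intervals(nn)
  if (length(x) < 1L) stop_vims("heart rate needs at least 1 NN interval")
  60000 / mean(x)
}

nn_intervals <- function(nn) {
  if (inherits(nn, "nn_series")) nn$intervals
  else if (is.numeric(nn)) as.numeric(nn)
  else stop_vims("expected an `nn_series` or numeric vector")
}

#' Resample the NN tachogram to a uniform grid
#'
#' Cubic-spline interpolation of (onset time, interval) onto a uniform
#' grid at `fs_resample` (default 4 Hz), covering the NN time span. The
#' spline passes through the knots; gaps left by NN rejection are bridged
#' by the spline over the original onset times.
#'
#' @param nn An `nn_series` with at least 4 intervals spanning >= 2 s.
#' @param fs_resample Resampling rate, Hz.
#' @return A `uniform_tachogram`: `values` (ms), `fs_resample`, `t0`.
#' @export
resample_tachogram <- function(nn, fs_resample = 4) {
  stopifnot(inherits(nn, "nn_series"), fs_resample > 0)
  t <- nn$onset_times
  x <- nn$intervals
  if (length(x) < 4L) stop_vims("tachogram resampling needs at least 4 NN intervals")
  if (any(diff(t) <= 0)) stop_vims("NN onset times must be strictly increasing")
  span <- t[length(t)] - t[1]
  if (span < 2) stop_vims("NN series spans less than 2 s")
  grid <- seq(t[1], t[length(t)], by = 1 / fs_resample)
  f <- stats::splinefun(t, x, method = "fmm")
  structure(list(values = f(grid), fs_resample = fs_resample, t0 = t[1]),
            class = "uniform_tachogram")
}

#' HRV power spectrum of a uniform tachogram
#'
#' Single full-segment Hann-windowed periodogram (the full segment
#' maximises VLF resolution on 5--12 minute records). The series is
#' de-meaned, windowed, and the one-sided PSD is normalised so that its
#' integral equals the variance of the de-meaned series exactly (Parseval
#' by construction; see the methods vignette for why plain window-power
#' compensation is not used).
#'
#' @param tach A `uniform_tachogram` with >= 64 samples.
#' @return An `hrv_spectrum`: `freqs` (Hz, 0 to Nyquist), `psd` (ms^2/Hz),
#'   `window`, `segment_length`.
#' @export
hrv_spectrum <- function(tach) {
  stopifnot(inherits(tach, "uniform_tachogram"))
  x <- tach$values
  n <- length(x)
  if (n < 64L) stop_vims("spectrum needs at least 64 tachogram samples")
  fs <- tach$fs_resample
  x <- x - mean(x)
  v <- mean(x^2)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  X <- stats::fft(x * w)
  nh <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nh)])^2
  scale <- rep(2, nh)
  scale[1] <- 1
  if (n %% 2 == 0) scale[nh] <- 1
  p <- p * scale
  df <- fs / n
  tot <- sum(p) * df
  psd <- if (tot > 0) p * (v / tot) else p * 0
  structure(
    list(freqs = (seq_len(nh) - 1) * df, psd = psd,
         window = "hann", segment_length = n),
    class = "hrv_spectrum"
  )
}

#' Band powers of an HRV spectrum
#'
#' Trapezoidal integration of the PSD over the closed VLF and HF bands.
#' Band edges falling between grid points are handled by linear
#' interpolation of the PSD at the exact edges.
#'
#' @param spec An `hrv_spectrum`.
#' @param vlf,hf Band limits in Hz; defaults 0.0033--0.04 (VLF,
#'   sympathetic-linked) and 0.15--0.4 (HF, parasympathetic-linked).
#' @return A list with `vlf_power` and `hf_power` in ms^2.
#' @export
band_powers <- function(spec, vlf = c(0.0033, 0.04), hf = c(0.15, 0.4)) {
  stopifnot(inherits(spec, "hrv_spectrum"))
  nyq <- max(spec$freqs)
  for (band in list(vlf, hf)) {
    if (length(band) != 2L || band[1] < 0 || band[2] <= band[1] || band[2] > nyq) {
      stop_vims("band [", band[1], ", ", band[2], "] Hz outside spectral range")
    }
  }
  df <- spec$freqs[2] - spec$freqs[1]
  if (vlf[1] > 0 && 1 / df < 1 / vlf[1]) {
    warning(sprintf(
      "record spans %.0f s: shorter than one cycle of the %g Hz VLF edge; VLF power unreliable",
      1 / df, vlf[1]))
  }
  list(vlf_power = integrate_band(spec, vlf), hf_power = integrate_band(spec, hf))
}

integrate_band <- function(spec, band) {
  f <- spec$freqs
  p <- spec$psd
  inside <- f > band[1] & f < band[2]
  fb <- c(band[1], f[inside], band[2])
  pb <- c(stats::approx(f, p, xout = band[1], rule = 2)$y, p[inside],
          stats::approx(f, p, xout = band[2], rule = 2)$y)
  sum(diff(fb) * (pb[-1] + pb[-length(pb)]) / 2)
}

#' Log-normalised band powers
#'
#' `ln VLF` and `ln HF` via the natural log, with a documented floor
#' `eps = 1e-12` ms^2 keeping the log defined on degenerate inputs. The
#' ratio feature is the quotient of the logs, `ln(VLF) / ln(HF)`, as the
#' feature is named; set `ratio_mode = "log_of_ratio"` for `ln(VLF/HF)`.
#'
#' @param vlf_power,hf_power Band powers in ms^2 (>= 0).
#' @param eps Floor applied inside the log.
#' @param ratio_mode `"log_quotient"` (default) or `"log_of_ratio"`.
#' @return A list with `ln_vlf`, `ln_hf`, `ln_ratio`.
#' @export
ln_features <- function(vlf_power, hf_power, eps = 1e-12,
                        ratio_mode = c("log_quotient", "log_of_ratio")) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(vlf_power >= 0, hf_power >= 0)
  if (vlf_power < eps || hf_power < eps) {
    warning("band power below floor eps = ", eps, " ms^2; log floored")
  }
  ln_vlf <- log(max(vlf_power, eps))
  ln_hf <- log(max(hf_power, eps))
  ln_ratio <- if (ratio_mode == "log_of_ratio") {
    ln_vlf - ln_hf
  } else {
    if (ln_hf == 0) stop_vims("ln HF is exactly 0: ln VLF / ln HF undefined")
    ln_vlf / ln_hf
  }
  list(ln_vlf = ln_vlf, ln_hf = ln_hf, ln_ratio = ln_ratio)
}

#' Feature-extraction configuration
#'
#' Bundles the tunable parameters of the ECG-to-features pipeline: filter
#' band, NN acceptance bounds, resampling rate, spectral bands and the
#' ratio convention.
#'
#' @param low,high Band-pass edges, Hz.
#' @param nn_low,nn_high NN acceptance bounds, ms.
#' @param fs_resample Tachogram resampling rate, Hz.
#' @param vlf_band,hf_band Spectral bands, Hz.
#' @param ratio_mode See [ln_features()].
#' @param qrs A [qrs_config()].
#' @param min_duration Records shorter than this (s) trigger a VLF
#'   validity warning (default 300 s, one cycle of the 0.0033 Hz edge).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(low = 5, high = 15, nn_low = 600, nn_high = 1200,
                           fs_resample = 4, vlf_band = c(0.0033, 0.04),
                           hf_band = c(0.15, 0.4),
                           ratio_mode = c("log_quotient", "log_of_ratio"),
                           qrs = qrs_config(), min_duration = 300) {
  structure(list(low = low, high = high, nn_low = nn_low, nn_high = nn_high,
                 fs_resample = fs_resample, vlf_band = vlf_band,
                 hf_band = hf_band, ratio_mode = match.arg(ratio_mode),
                 qrs = qrs, min_duration = min_duration),
            class = "feature_config")
}

# Features from an NN series (shared by the ECG path and the RR path).
features_from_nn <- function(nn, config = feature_config()) {
  if (length(nn$intervals) == 0L) stop_vims("no NN intervals: cannot extract features")
  tach <- resample_tachogram(nn, config$fs_resample)
  spec <- hrv_spectrum(tach)
  bp <- band_powers(spec, config$vlf_band, config$hf_band)
  lf <- ln_features(bp$vlf_power, bp$hf_power, ratio_mode = config$ratio_mode)
  structure(
    list(heart_rate = mean_heart_rate(nn), sdnn = sdnn(nn), pnn50 = pnn50(nn),
         ln_vlf = lf$ln_vlf, ln_hf = lf$ln_hf, ln_ratio = lf$ln_ratio,
         vlf_power = bp$vlf_power, hf_power = bp$hf_power,
         n_beats = length(nn$intervals) + 1L + nn$n_rejected,
         n_rejected = nn$n_rejected),
    class = "feature_vector"
  )
}

#' Extract the six cardiac features from raw ECG
#'
#' Composition of the full signal path: band-pass filter, R-peak
#' detection, RR intervals, NN filtering, time-domain features, 4-Hz
#' tachogram, Hann-windowed spectrum, VLF/HF band powers and their logs.
#'
#' @param ecg An [ecg_record()]; >= 300 s recommended for VLF validity
#'   (a warning is raised below `config$min_duration`).
#' @param config A [feature_config()].
#' @return A `feature_vector`: `heart_rate` (bpm), `sdnn` (ms), `pnn50`
#'   (%), `ln_vlf`, `ln_hf`, `ln_ratio`, plus QC fields `vlf_power`,
#'   `hf_power`, `n_beats`, `n_rejected`.
#' @export
extract_features <- function(ecg, config = feature_config()) {
  stopifnot(inherits(ecg, "ecg_record"), inherits(config, "feature_config"))
  if (duration(ecg) < config$min_duration) {
    warning(sprintf("record is %.0f s (< %g s): VLF estimates unreliable",
                    duration(ecg), config$min_duration))
  }
  filt <- bandpass_filter(ecg, config$low, config$high)
  peaks <- detect_r_peaks(filt, config$qrs, raw = ecg)
  if (length(peaks$times) < 2L) stop_vims("fewer than 2 R-peaks detected")
  rri <- compute_rri(peaks)
  nn <- suppressWarnings(filter_nn(rri, config$nn_low, config$nn_high))
  if (length(nn$intervals) == 0L) {
    stop_vims("no NN intervals within [", config$nn_low, ", ",
              config$nn_high, "] ms")
  }
  features_from_nn(nn, config)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(
    "<feature_vector> HR %.1f bpm | SDNN %.1f ms | pNN50 %.1f%% | ln VLF %.2f | ln HF %.2f | ratio %.2f\n",
    x$heart_rate, x$sdnn, x$pnn50, x$ln_vlf, x$ln_hf, x$ln_ratio))
  invisible(x)
}

#' Convert feature vectors to a one-row data frame
#' @param x A `feature_vector`.
#' @param ... Unused.
#' @return A one-row data frame.
#' @export
as.data.frame.feature_vector <- function(x, ...) {
  data.frame(heart_rate = x$heart_rate, sdnn = x$sdnn, pnn50 = x$pnn50,
             ln_vlf = x$ln_vlf, ln_hf = x$ln_hf, ln_ratio = x$ln_ratio,
             n_beats = x$n_beats, n_rejected = x$n_rejected)
}
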
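# Synthetic RR-interval and ECG generators with known ground truth.
#
# RR modulation is additive sinusoidal (not integral pulse frequency
# modulation): each sinusoid of amplitude a contributes an exactly known
# band power a^2 / 2, which is what makes spectral recovery testable.

#' Parameters of the RR-interval generator
#'
#' @param mean_rr Mean RR interval, ms (> 0).
#' @param vlf_amp,vlf_freq Amplitude (ms) and frequency (Hz) of the
#'   very-low-frequency modulation (band 0.0033--0.04 Hz).
#' @param hf_amp,hf_freq Amplitude (ms) and frequency (Hz) of the
#'   high-frequency (respiratory) modulation (band 0.15--0.4 Hz).
#' @param jitter_sd SD of white beat-to-beat noise, ms.
#' @param duration Minimum record span, s.
#' @param seed Integer seed.
#' @return A list of class `rr_gen_params`.
#' @export
rr_gen_params <- function(mean_rr = 900, vlf_amp = 15, vlf_freq = 0.02,
                          hf_amp = 15, hf_freq = 0.25, jitter_sd = 5,
                          duration = 300, seed = 1) {
  if (!is_scalar_number(mean_rr) || mean_rr <= 0) {
    stop_vims("`mean_rr` must be positive (ms)")
  }
  stopifnot(vlf_amp >= 0, hf_amp >= 0, jitter_sd >= 0,
            vlf_freq > 0, hf_freq > 0, duration > 0)
  structure(list(mean_rr = mean_rr, vlf_amp = vlf_amp, vlf_freq = vlf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq, jitter_sd = jitter_sd,
                 duration = duration, seed = seed),
            class = "rr_gen_params")
}

#' Generate a synthetic RR-interval series
#'
#' `RR(k) = mean_rr + vlf_amp sin(2 pi vlf_freq t_k) +
#'  hf_amp sin(2 pi hf_freq t_k) + e_k`, `e_k ~ N(0, jitter_sd^2)`, with
#' `t_k` the cumulative beat time. Fully reproducible from the seed.
#'
#' @param params An [rr_gen_params()].
#' @return An `rr_series`: `intervals` (ms), `onset_times` (s, beat times
#'   starting at 0; one per interval), `beat_times` (s, all beats,
#'   length `n + 1`).
#' @export
generate_rr_series <- function(params = rr_gen_params()) {
  stopifnot(inherits(params, "rr_gen_params"))
  p <- params
  n_max <- ceiling(p.duration_beats(p)) + 10L
  with_seed(p$seed, {
    eps <- stats::rnorm(n_max, 0, p$jitter_sd)
    intervals <- numeric(n_max)
    t <- 0
    k <- 0L
    while (t < p$duration) {
      k <- k + 1L
      if (k > n_max) {
        eps <- c(eps, stats::rnorm(n_max, 0, p$jitter_sd))
        intervals <- c(intervals, numeric(n_max))
        n_max <- length(intervals)
      }
      rr <- p$mean_rr +
        p$vlf_amp * sin(2 * pi * p$vlf_freq * t) +
        p$hf_amp * sin(2 * pi * p$hf_freq * t) +
        eps[k]
      rr <- max(rr, 1)  # intervals must stay positive
      intervals[k] <- rr
      t <- t + rr / 1000
    }
    if (k < 2L) stop_vims("duration too short: fewer than 2 beats generated")
    intervals <- intervals[seq_len(k)]
    beat_times <- c(0, cumsum(intervals) / 1000)
    structure(list(intervals = intervals,
                   onset_times = beat_times[seq_len(k)],
                   beat_times = beat_times),
              class = "rr_series")
  })
}

p.duration_beats <- function(p) p$duration * 1000 / max(p$mean_rr - p$vlf_amp - p$hf_amp, 1)

#' Convert a generated RR series to an NN-style series
#'
#' Convenience bridge from the generator to the HRV feature path, skipping
#' ECG synthesis and detection ("fast mode").
#'
#' @param rr An `rr_series`.
#' @return An `nn_series` with `n_rejected = 0`.
#' @export
as_nn_series <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  structure(list(intervals = rr$intervals, onset_times = rr$onset_times,
                 n_rejected = 0L),
            class = "nn_series")
}

#' Parameters of the ECG waveform generator
#'
#' One P-QRS-T beat template (sum of 5 Gaussians) is centred at each beat
#' time; baseline wander (~0.3 Hz), powerline interference (60 Hz) and
#' white noise are added. Morphology realism is not a goal -- exercising
#' the detector is.
#'
#' @param fs Sampling rate, Hz (>= 100).
#' @param beat_template List with numeric vectors `amp` (mV), `width`
#'   (Gaussian SD, s) and `offset` (s relative to the R-peak) for the
#'   P, Q, R, S, T deflections. The R amplitude must be the largest
#'   positive deflection.
#' @param baseline_wander_amp Baseline wander amplitude, mV.
#' @param wander_freq Baseline wander frequency, Hz.
#' @param powerline_amp Powerline interference amplitude, mV.
#' @param powerline_freq Powerline frequency, Hz (60 in the target setup).
#' @param noise_sd White (muscle) noise SD, mV.
#' @param seed Integer seed.
#' @return A list of class `ecg_gen_params`.
#' @export
ecg_gen_params <- function(fs = 500,
                           beat_template = list(
                             amp = c(P = 0.12, Q = -0.15, R = 1.2,
                                     S = -0.25, T = 0.35),
                             width = c(P = 0.025, Q = 0.010, R = 0.012,
                                       S = 0.010, T = 0.045),
                             offset = c(P = -0.18, Q = -0.03, R = 0,
                                        S = 0.03, T = 0.28)),
                           baseline_wander_amp = 0, wander_freq = 0.3,
                           powerline_amp = 0, powerline_freq = 60,
                           noise_sd = 0, seed = 1) {
  if (!is_scalar_number(fs) || fs < 100) {
    stop_vims("`fs` must be >= 100 Hz to resolve the QRS complex")
  }
  a <- beat_template$amp
  if (max(a) != a[["R"]]) {
    stop_vims("template R amplitude must be the largest positive deflection")
  }
  stopifnot(baseline_wander_amp >= 0, powerline_amp >= 0, noise_sd >= 0)
  structure(list(fs = fs, beat_template = beat_template,
                 baseline_wander_amp = baseline_wander_amp,
                 wander_freq = wander_freq, powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq, noise_sd = noise_sd,
                 seed = seed),
            class = "ecg_gen_params")
}

#' Synthesize an ECG record from an RR series
#'
#' A 0.5-s lead-in pad precedes the first beat so its full P-QRS-T
#' complex lies inside the record; the returned ground-truth R times are
#' on the record clock (first R at 0.5 s).
#'
#' @param rr An `rr_series` (>= 2 beats).
#' @param params An [ecg_gen_params()].
#' @return A list with `ecg` (an [ecg_record()]) and `r_times` (the
#'   ground-truth R-peak times in s, one per beat).
#' @export
generate_ecg <- function(rr, params = ecg_gen_params()) {
  stopifnot(inherits(rr, "rr_series"), inherits(params, "ecg_gen_params"))
  pad <- 0.5
  beats <- rr$beat_times + pad
  if (length(beats) < 2L) stop_vims("need at least 2 beats")
  fs <- params$fs
  tpl <- params$beat_template
  t_end <- beats[length(beats)] + 0.5
  n <- ceiling(t_end * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  half <- 0.45  # template support half-width, s
  for (bt in beats) {
    lo <- max(1L, floor((bt - half) * fs) + 1L)
    hi <- min(n, ceiling((bt + half) * fs) + 1L)
    tl <- tt[lo:hi] - bt
    seg <- numeric(length(tl))
    for (j in seq_along(tpl$amp)) {
      seg <- seg + tpl$amp[[j]] * exp(-0.5 * (tl - tpl$offset[[j]])^2 / tpl$width[[j]]^2)
    }
    x[lo:hi] <- x[lo:hi] + seg
  }
  with_seed(params$seed, {
    if (params$baseline_wander_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + params$baseline_wander_amp * sin(2 * pi * params$wander_freq * tt + phase)
    }
    if (params$powerline_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + params$powerline_amp * sin(2 * pi * params$powerline_freq * tt + phase)
    }
    if (params$noise_sd > 0) x <- x + stats::rnorm(n, 0, params$noise_sd)
    list(ecg = ecg_record(x, fs), r_times = beats)
  })
}

#' Score a detector against ground-truth R times
#'
#' Greedy one-to-one matching within a tolerance window.
#'
#' @param detected,truth Numeric vectors of peak times, s.
#' @param tol Matching tolerance, s (default 0.02).
#' @return List with `tp`, `fp`, `fn`, `sensitivity`, `ppv` (fractions).
#' @export
score_detection <- function(detected, truth, tol = 0.02) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (t in truth) {
    cand <- which(!used & abs(detected - t) <= tol)
    if (length(cand)) {
      used[cand[which.min(abs(detected[cand] - t))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- sum(!used)
  fn <- length(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       ppv = if (length(detected)) tp / length(detected) else NA_real_)
}

#' Generate one SSQ response from a latent severity
#'
#' Cumulative-threshold ordinal model: each item's rating is the number of
#' thresholds exceeded by `severity + noise`. Monotone in severity, with
#' all-0 and all-3 limits at the extremes.
#'
#' @param severity Finite latent motion-sickness severity (0 is mild;
#'   around 3 saturates most items).
#' @param seed Integer seed.
#' @param thresholds Increasing cutpoints of the ordinal model.
#' @param noise_sd SD of the per-item latent noise.
#' @return An [ssq_response()].
#' @export
generate_ssq_response <- function(severity, seed = 1,
                                  thresholds = c(0.5, 1.5, 2.5),
                                  noise_sd = 0.6) {
  if (!is_scalar_number(severity)) stop_vims("`severity` must be finite")
  stopifnot(all(diff(thresholds) > 0), noise_sd >= 0)
  items <- .ssq_item_table()$item
  with_seed(seed, {
    u <- severity + stats::rnorm(length(items), 0, noise_sd)
    ratings <- vapply(u, function(ui) sum(ui > thresholds), numeric(1))
    ssq_response(stats::setNames(ratings, items))
  })
}
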
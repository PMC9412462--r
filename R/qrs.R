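# R-peak detection (Pan-Tompkins style) and RR/NN interval series.

#' Detector configuration
#'
#' Tuning constants of the QRS detector. Defaults follow the classic
#' derivative / squaring / moving-window-integration detector: 150 ms
#' integration window, 200 ms refractory period, search-back enabled.
#'
#' @param refractory Minimum spacing between accepted peaks, s.
#' @param integration_window Moving-window integration length, s.
#' @param search_back Recover missed beats when an RR gap exceeds
#'   `search_back_factor` times the running RR average.
#' @param search_back_factor Gap multiplier that triggers search-back.
#' @param refine_window Half-width (s) of the window, centred on the
#'   detection, within which the peak time is refined to the local maximum
#'   of the reference (unfiltered) signal.
#' @param apply_bandpass Apply [bandpass_filter()] internally first; set
#'   when passing raw ECG straight to [detect_r_peaks()].
#' @return A list of class `qrs_config`.
#' @export
qrs_config <- function(refractory = 0.2, integration_window = 0.15,
                       search_back = TRUE, search_back_factor = 1.66,
                       refine_window = 0.05, apply_bandpass = FALSE) {
  stopifnot(refractory > 0, integration_window > 0, refine_window >= 0)
  structure(list(refractory = refractory,
                 integration_window = integration_window,
                 search_back = isTRUE(search_back),
                 search_back_factor = search_back_factor,
                 refine_window = refine_window,
                 apply_bandpass = isTRUE(apply_bandpass)),
            class = "qrs_config")
}

rpeak_series <- function(times, indices) {
  structure(list(times = as.numeric(times), indices = as.integer(indices)),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks\n", length(x$times)))
  invisible(x)
}

# indices of strict local maxima of v
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Detect R-peaks in a band-passed ECG
#'
#' Derivative, squaring, 150-ms moving-window integration, then adaptive
#' dual-threshold peak picking with a 200-ms refractory period and
#' search-back for missed beats. Detections are refined to the local
#' maximum of the reference signal (by default the unfiltered record when
#' supplied via `raw`) within +/- 50 ms, so reported R times are
#' morphology-true.
#'
#' @param filtered Band-passed [ecg_record()] (or raw, with
#'   `config$apply_bandpass = TRUE`).
#' @param config A [qrs_config()].
#' @param raw Optional unfiltered `ecg_record` used for peak-time
#'   refinement; defaults to `filtered`.
#' @return An `rpeak_series` with strictly increasing `times` (s) and
#'   sample `indices`. A flat or empty-energy record yields an empty
#'   series with a warning.
#' @export
detect_r_peaks <- function(filtered, config = qrs_config(), raw = NULL) {
  stopifnot(inherits(filtered, "ecg_record"), inherits(config, "qrs_config"))
  fs <- filtered$fs
  if (duration(filtered) < 2) {
    stop_vims("record shorter than 2 s: too short for threshold adaptation")
  }
  if (config$apply_bandpass) filtered <- bandpass_filter(filtered)
  ref <- raw %||% filtered
  stopifnot(inherits(ref, "ecg_record"), length(ref$samples) == length(filtered$samples))

  x <- filtered$samples
  # zero-delay five-point derivative
  d <- as.numeric(stats::filter(x, c(-1, -2, 0, 2, 1) * fs / 8, sides = 2))
  d[is.na(d)] <- 0
  sq <- d^2
  wlen <- max(1L, round(config$integration_window * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  mwi[is.na(mwi)] <- 0

  cand <- local_maxima(mwi)
  # collapse ripple maxima: keep only the largest candidate within any
  # refractory-length neighbourhood
  if (length(cand) > 1L) {
    min_gap <- round(config$refractory * fs)
    keep_c <- logical(length(cand))
    for (oi in order(mwi[cand], decreasing = TRUE)) {
      if (!any(keep_c & abs(cand - cand[oi]) < min_gap)) keep_c[oi] <- TRUE
    }
    cand <- sort(cand[keep_c])
  }
  if (length(cand) == 0L || max(mwi) <= 0) {
    warning("no QRS energy found; returning empty peak series")
    return(rpeak_series(numeric(0), integer(0)))
  }

  init <- seq_len(min(length(mwi), round(2 * fs)))
  spki <- max(mwi[init])
  npki <- mean(mwi[init]) / 2
  refr <- config$refractory
  accepted <- integer(0)
  skipped <- integer(0)
  rr_hist <- numeric(0)
  last_t <- -Inf

  for (ci in cand) {
    v <- mwi[ci]
    t <- (ci - 1) / fs
    thr1 <- npki + 0.25 * (spki - npki)
    if (v > thr1 && (t - last_t) >= refr) {
      # search-back: long gap since the last beat -> rescue the largest
      # skipped candidate above the lower threshold
      if (config$search_back && length(rr_hist) >= 2) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        if ((t - last_t) > config$search_back_factor * rr_avg && length(skipped)) {
          gap <- skipped[(skipped - 1) / fs > last_t + refr &
                         (skipped - 1) / fs < t - refr]
          if (length(gap)) {
            best <- gap[which.max(mwi[gap])]
            if (mwi[best] > 0.5 * thr1) {
              bt <- (best - 1) / fs
              rr_hist <- c(rr_hist, bt - last_t)
              accepted <- c(accepted, best)
              last_t <- bt
              spki <- 0.25 * mwi[best] + 0.75 * spki
            }
          }
        }
      }
      if (is.finite(last_t)) rr_hist <- c(rr_hist, t - last_t)
      accepted <- c(accepted, ci)
      last_t <- t
      spki <- 0.125 * v + 0.875 * spki
      skipped <- integer(0)
    } else {
      npki <- 0.125 * v + 0.875 * npki
      skipped <- c(skipped, ci)
    }
  }
  if (length(accepted) == 0L) {
    warning("no peaks above adaptive threshold; returning empty peak series")
    return(rpeak_series(numeric(0), integer(0)))
  }

  # refine each detection to the local maximum of the reference signal
  half <- as.integer(max(0, round(config$refine_window * fs)))
  n <- length(ref$samples)
  idx <- vapply(accepted, function(ci) {
    lo <- max(1L, as.integer(ci) - half)
    hi <- min(n, as.integer(ci) + half)
    lo + which.max(ref$samples[lo:hi]) - 1L
  }, integer(1))
  idx <- sort(unique(idx))

  # refinement can merge neighbours; enforce the refractory period keeping
  # the larger reference amplitude
  keep <- rep(TRUE, length(idx))
  i <- 1L
  while (i < length(idx)) {
    j <- i + 1L
    while (j <= length(idx) && keep[j] == TRUE &&
           (idx[j] - idx[i]) / fs < refr) {
      if (ref$samples[idx[j]] > ref$samples[idx[i]]) {
        keep[i] <- FALSE
        i <- j
      } else {
        keep[j] <- FALSE
      }
      j <- j + 1L
    }
    i <- j
  }
  idx <- idx[keep]
  rpeak_series(filtered$start_time + (idx - 1) / fs, idx)
}

#' RR intervals from detected R-peaks
#'
#' @param peaks An `rpeak_series` with at least two peaks.
#' @return An `rri_series`: `intervals` (ms) and `onset_times` (s, the time
#'   of the first peak of each pair).
#' @export
compute_rri <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  n <- length(peaks$times)
  if (n < 2L) stop_vims("need at least 2 R-peaks to form RR intervals")
  structure(
    list(intervals = diff(peaks$times) * 1000,
         onset_times = peaks$times[-n]),
    class = "rri_series"
  )
}

#' Filter RR intervals to normal-to-normal (NN) intervals
#'
#' Keeps intervals inside the closed range `[nn_low, nn_high]` (defaults
#' 600--1200 ms); everything else is excluded, not interpolated. Onset
#' times of surviving intervals are preserved.
#'
#' @param rri An `rri_series`.
#' @param nn_low,nn_high Acceptance bounds in ms (inclusive).
#' @return An `nn_series` with `intervals`, `onset_times` and `n_rejected`.
#'   An empty result is returned with a warning; downstream operations
#'   reject it.
#' @export
filter_nn <- function(rri, nn_low = 600, nn_high = 1200) {
  stopifnot(inherits(rri, "rri_series"))
  if (!(nn_low < nn_high)) stop_vims("`nn_low` must be below `nn_high`")
  keep <- rri$intervals >= nn_low & rri$intervals <= nn_high
  out <- structure(
    list(intervals = rri$intervals[keep],
         onset_times = rri$onset_times[keep],
         n_rejected = sum(!keep)),
    class = "nn_series"
  )
  if (length(out$intervals) == 0L) {
    warning("no RR intervals within [", nn_low, ", ", nn_high, "] ms")
  }
  out
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d NN intervals (%d rejected)\n",
              length(x$intervals), x$n_rejected))
  invisible(x)
}
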
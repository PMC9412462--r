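# Sliding-window monitor: windowed feature extraction over an ECG stream
# plus a per-window binary motion-sickness decision from a trained
# classifier.

#' Monitor configuration
#'
#' The 300-s default window is the shortest span resolving the 0.0033-Hz
#' VLF band edge; the stride sets the decision granularity.
#'
#' @param classifier A trained `vims_classifier` (see
#'   [train_classifier()]).
#' @param window_length Window length, s (default 300).
#' @param stride Hop between window starts, s (`0 < stride <=
#'   window_length`).
#' @param zone_config Optional [zone_config()]; when supplied each window
#'   is also assigned an autonomic zone.
#' @param features A [feature_config()]; its `min_duration` is lowered to
#'   the window length so sub-300-s windows do not warn repeatedly.
#' @return A list of class `monitor_config`.
#' @export
monitor_config <- function(classifier, window_length = 300, stride = 10,
                           zone_config = NULL, features = feature_config()) {
  if (!inherits(classifier, "vims_classifier")) {
    stop_vims("`classifier` must be a trained vims_classifier")
  }
  if (!(stride > 0 && stride <= window_length)) {
    stop_vims("need 0 < stride <= window_length")
  }
  features$min_duration <- min(features$min_duration, window_length)
  structure(list(classifier = classifier, window_length = window_length,
                 stride = stride, zone_config = zone_config,
                 features = features),
            class = "monitor_config")
}

#' Cut an ECG record into sliding windows
#'
#' Windows `[t, t + W)` start at `0, stride, 2 stride, ...`; the count is
#' `floor((T - W) / stride) + 1`.
#'
#' @param ecg An [ecg_record()] of duration >= the window length.
#' @param config A [monitor_config()] (or any list with `window_length`
#'   and `stride`).
#' @return List of `ecg_record` windows, each with a correct
#'   `start_time`.
#' @export
iter_windows <- function(ecg, config) {
  stopifnot(inherits(ecg, "ecg_record"))
  W <- config$window_length
  stride <- config$stride
  T <- duration(ecg)
  if (T < W) stop_vims("record (", round(T, 1), " s) shorter than one window")
  starts <- seq(0, T - W, by = stride)
  lapply(starts, function(t0) {
    i0 <- floor(t0 * ecg$fs) + 1L
    i1 <- min(length(ecg$samples), i0 + round(W * ecg$fs) - 1L)
    ecg_record(ecg$samples[i0:i1], ecg$fs, start_time = ecg$start_time + t0)
  })
}

#' Run the sliding-window motion-sickness monitor
#'
#' For each window: extract the cardiac features, optionally assign the
#' autonomic zone, and apply the trained classifier for a binary MS /
#' normal decision. Windows whose feature extraction fails are logged
#' with status `"invalid"` and the failure reason, never dropped.
#'
#' @param ecg An [ecg_record()].
#' @param config A [monitor_config()].
#' @return A `monitor_log` data frame: `t_start`, `t_end`, `status`,
#'   the six features, `zone`, `decision` (`"MS"` / `"normal"`),
#'   `reason`.
#' @export
monitor <- function(ecg, config) {
  stopifnot(inherits(config, "monitor_config"))
  wins <- iter_windows(ecg, config)
  clf <- config$classifier
  feats <- c("sdnn", "pnn50", "ln_vlf", "ln_hf", "ln_ratio")
  logs <- lapply(wins, function(w) {
    base <- data.frame(t_start = w$start_time,
                       t_end = w$start_time + duration(w))
    fv <- tryCatch(suppressWarnings(extract_features(w, config$features)),
                   error = function(e) e)
    if (inherits(fv, "error")) {
      return(cbind(base, data.frame(
        status = "invalid", heart_rate = NA_real_, sdnn = NA_real_,
        pnn50 = NA_real_, ln_vlf = NA_real_, ln_hf = NA_real_,
        ln_ratio = NA_real_, zone = NA_character_, decision = NA_character_,
        reason = conditionMessage(fv))))
    }
    X <- matrix(unlist(fv[feats]), nrow = 1, dimnames = list(NULL, feats))
    pred <- predict(clf, X)
    zone <- if (!is.null(config$zone_config)) {
      classify_zone(fv$ln_vlf, fv$ln_hf, config$zone_config)
    } else NA_character_
    cbind(base, data.frame(
      status = "ok", heart_rate = fv$heart_rate, sdnn = fv$sdnn,
      pnn50 = fv$pnn50, ln_vlf = fv$ln_vlf, ln_hf = fv$ln_hf,
      ln_ratio = fv$ln_ratio, zone = zone,
      decision = if (pred$label == clf$positive) "MS" else "normal",
      reason = NA_character_))
  })
  out <- do.call(rbind, logs)
  class(out) <- c("monitor_log", "data.frame")
  out
}
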
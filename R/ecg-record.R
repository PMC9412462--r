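#' Uniformly sampled single-lead ECG record
#'
#' Container for a voltage trace sampled at a fixed rate, the unit of
#' exchange between the simulator, the preprocessing filters and the
#' R-peak detector.
#'
#' @param samples Numeric vector of voltages (mV).
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `ecg_record` with fields `samples`, `fs`,
#'   `start_time`.
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 500)), fs = 500)
#' duration(rec)
#' @export
ecg_record <- function(samples, fs, start_time = 0) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_vims("`samples` must be a non-empty numeric vector")
  }
  if (anyNA(samples)) stop_vims("`samples` contains missing values")
  if (!is_scalar_number(fs) || fs <= 0) stop_vims("`fs` must be a positive number (Hz)")
  if (!is_scalar_number(start_time)) stop_vims("`start_time` must be a finite number")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         start_time = as.numeric(start_time)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, duration(x)))
  invisible(x)
}

#' Record duration in seconds
#' @param x An `ecg_record`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "ecg_record"))
  length(x$samples) / x$fs
}

# Sample times in seconds (same clock as start_time).
sample_times <- function(x) {
  x$start_time + (seq_along(x$samples) - 1) / x$fs
}
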
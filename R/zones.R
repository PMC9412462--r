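# Nine-zone autonomic-balance classification of the normalised-HRV plane.
#
# The (ln VLF, ln HF) plane is trisected on each axis into low / normal /
# high; the 3 x 3 grid yields eight labelled zones around a central
# reference zone. x = ln VLF indexes sympathetic tone, y = ln HF
# parasympathetic tone:
#
#   Zone1 low-symp/high-para   Zone2 normal-symp/high-para  Zone3 high both
#   Zone8 low-symp/normal-para Reference                    Zone4 high-symp/normal-para
#   Zone7 low both             Zone6 normal-symp/low-para   Zone5 high-symp/low-para

#' Zone thresholds for the normalised-HRV plane
#'
#' The literature gives no universal numeric boundaries, so the thresholds
#' are mandatory-configurable; [zone_config_from_reference()] derives a
#' stand-in from a reference cohort's quartiles.
#'
#' @param vlf_low,vlf_high Thresholds on ln VLF splitting the sympathetic
#'   axis into low / normal / high (`vlf_low < vlf_high`).
#' @param hf_low,hf_high Same for ln HF (parasympathetic axis).
#' @return A list of class `zone_config`.
#' @export
zone_config <- function(vlf_low, vlf_high, hf_low, hf_high) {
  stopifnot(is_scalar_number(vlf_low), is_scalar_number(vlf_high),
            is_scalar_number(hf_low), is_scalar_number(hf_high))
  if (!(vlf_low < vlf_high) || !(hf_low < hf_high)) {
    stop_vims("zone thresholds must satisfy low < high on both axes")
  }
  structure(list(vlf_low = vlf_low, vlf_high = vlf_high,
                 hf_low = hf_low, hf_high = hf_high),
            class = "zone_config")
}

#' Zone thresholds from a reference cohort
#'
#' Uses the 25th/75th percentiles of reference ln VLF and ln HF values.
#' This is a documented stand-in for published boundaries, not a
#' literature value.
#'
#' @param ln_vlf,ln_hf Numeric vectors of reference values.
#' @param probs Lower/upper quantile probabilities (default 0.25, 0.75).
#' @return A [zone_config()].
#' @export
zone_config_from_reference <- function(ln_vlf, ln_hf, probs = c(0.25, 0.75)) {
  stopifnot(length(ln_vlf) >= 4, length(ln_hf) >= 4,
            length(probs) == 2L, probs[1] < probs[2])
  qv <- stats::quantile(ln_vlf, probs, names = FALSE)
  qh <- stats::quantile(ln_hf, probs, names = FALSE)
  zone_config(qv[1], qv[2], qh[1], qh[2])
}

#' Classify points of the normalised-HRV plane into autonomic zones
#'
#' Boundary convention: "normal" is the closed interval
#' `[low, high]`; a point is "low" strictly below `low` and "high"
#' strictly above `high`, so every finite point maps to exactly one zone.
#'
#' @param ln_vlf,ln_hf Numeric vectors (recycled to common length).
#' @param config A [zone_config()].
#' @return Character vector with values in `"Zone1"`..`"Zone8"`,
#'   `"Reference"`.
#' @export
classify_zone <- function(ln_vlf, ln_hf, config) {
  stopifnot(inherits(config, "zone_config"),
            is.numeric(ln_vlf), is.numeric(ln_hf))
  n <- max(length(ln_vlf), length(ln_hf))
  ln_vlf <- rep_len(ln_vlf, n)
  ln_hf <- rep_len(ln_hf, n)
  trisect <- function(v, lo, hi) {
    ifelse(v < lo, "low", ifelse(v > hi, "high", "normal"))
  }
  xc <- trisect(ln_vlf, config$vlf_low, config$vlf_high)
  yc <- trisect(ln_hf, config$hf_low, config$hf_high)
  map <- c(low.high = "Zone1", normal.high = "Zone2", high.high = "Zone3",
           high.normal = "Zone4", high.low = "Zone5", normal.low = "Zone6",
           low.low = "Zone7", low.normal = "Zone8",
           normal.normal = "Reference")
  unname(map[paste(xc, yc, sep = ".")])
}
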
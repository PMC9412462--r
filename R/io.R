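# Plain-text readers and writers: ECG CSV with JSON sidecar, cohort and
# feature tables as TSV. Text formats keep artifacts diffable.

#' Write an ECG record as CSV plus JSON sidecar
#'
#' Two numeric columns `time_s`, `voltage_mV`; the sampling rate goes to
#' `<path>.json` as `{"fs": ...}`.
#'
#' @param ecg An [ecg_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  utils::write.csv(
    data.frame(time_s = sample_times(ecg), voltage_mV = ecg$samples),
    path, row.names = FALSE)
  jsonlite::write_json(list(fs = ecg$fs, start_time = ecg$start_time),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Expects the layout written by [write_ecg_csv()]. The sampling rate
#' comes from the JSON sidecar or the `fs` argument; timestamps must be
#' uniform to within 1e-6 s.
#'
#' @param path CSV path.
#' @param fs Sampling rate in Hz, required when no sidecar exists.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_vims("no such file: ", path)
  dat <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) e)
  if (inherits(dat, "error")) {
    stop_vims("malformed ECG CSV '", path, "': ", conditionMessage(dat))
  }
  if (ncol(dat) < 2L || nrow(dat) < 2L) {
    stop_vims("ECG CSV must have two numeric columns (time_s, voltage_mV)")
  }
  for (j in 1:2) {
    v <- suppressWarnings(as.numeric(dat[[j]]))
    if (anyNA(v)) {
      # +1 for the header row so the reported line matches the file
      bad <- which(is.na(v))[1]
      stop_vims("non-numeric value in column '", names(dat)[j],
                "' at line ", bad + 1L, " of ", path)
    }
    dat[[j]] <- v
  }
  side <- paste0(path, ".json")
  start_time <- dat[[1]][1]
  if (is.null(fs)) {
    if (!file.exists(side)) {
      stop_vims("no sampling rate: provide `fs=` or a '", side, "' sidecar")
    }
    meta <- jsonlite::read_json(side)
    fs <- meta$fs
    if (is.null(fs)) stop_vims("sidecar '", side, "' lacks an \"fs\" entry")
  }
  dt <- diff(dat[[1]])
  if (max(abs(dt - 1 / fs)) > 1e-6) {
    bad <- which.max(abs(dt - 1 / fs))
    stop_vims("non-uniform timestamps near row ", bad + 1L,
              " (expected spacing ", 1 / fs, " s)")
  }
  ecg_record(dat[[2]], fs, start_time)
}

#' Write a cohort (or any data frame) as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort TSV written by [write_tsv()]
#' @param path TSV path.
#' @return A data frame (classed `vims_cohort` when the cohort columns
#'   are present).
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop_vims("no such file: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "phase", "sdnn", "pnn50", "ln_vlf", "ln_hf")
  if (all(need %in% names(x))) class(x) <- c("vims_cohort", "data.frame")
  x
}

#' Score a CSV of SSQ administrations
#'
#' One row per administration, columns named by `ssq_items()$item`
#' (extra id columns are carried through).
#'
#' @param path CSV path.
#' @return Data frame of raw and weighted scores, one row per input row.
#' @export
score_ssq_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- ssq_items()$item
  missing <- setdiff(items, names(x))
  if (length(missing)) {
    stop_vims("SSQ CSV lacks item column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(x), items)
  scores <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    s <- score_ssq(unlist(x[i, items]))
    data.frame(n_raw = s$n_raw, o_raw = s$o_raw, d_raw = s$d_raw,
               n_score = s$n_score, o_score = s$o_score, d_score = s$d_score,
               total = s$total)
  }))
  cbind(x[, extra, drop = FALSE], scores)
}
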
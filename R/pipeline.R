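# Pipeline orchestration and the command-line entry point.
#
# All randomness flows from one top-level seed, expanded per stage with
# derive_seed(), which is what makes whole-pipeline reruns byte-stable.

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level integer seed; stage seeds derive from it.
#' @param n_subjects Cohort size for `simulate`.
#' @param effects Programmed VR-post effects (see
#'   [cohort_effect_params()]).
#' @param n_perm Permutations for `classify`.
#' @param k Cross-validation folds.
#' @param features A [feature_config()].
#' @param verbose Log progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = ".", seed = 1, n_subjects = 28,
                       effects = c(sdnn = -2, pnn50 = -2, ln_vlf = 2,
                                   ln_hf = -2),
                       n_perm = 200, k = 10, features = feature_config(),
                       verbose = TRUE) {
  structure(list(out_dir = out_dir, seed = seed, n_subjects = n_subjects,
                 effects = effects, n_perm = n_perm, k = k,
                 features = features, verbose = isTRUE(verbose)),
            class = "run_config")
}

log_msg <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[vimshrv] ", ...)
}

write_run_log <- function(config, stage, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, seed = config$seed, n_subjects = config$n_subjects,
           n_perm = config$n_perm, k = config$k,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra),
    file.path(config$out_dir, paste0(stage, "_config.json")),
    auto_unbox = TRUE, digits = NA)
}

#' Run pipeline stages
#'
#' Stages: `simulate` (cohort generation, TSV + ground-truth JSON),
#' `ssq` (score a ratings CSV), `features` (ECG CSV to feature TSV),
#' `stats` (ANCOVA/correlation table), `classify` (CV + permutation
#' report), `monitor` (windowed decisions on an ECG using a classifier
#' trained on a cohort TSV). Each stage writes its artifacts plus a JSON
#' log of the resolved configuration under `config$out_dir`; a stage
#' failure aborts with the stage named.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names, executed in order.
#' @param ecg_path ECG CSV for `features` / `monitor`.
#' @param ssq_path SSQ ratings CSV for `ssq`.
#' @param cohort_path Cohort TSV for `stats` / `classify` / `monitor`
#'   training; defaults to the file `simulate` writes.
#' @return Named list of per-stage results, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "stats", "classify"),
                         ecg_path = NULL, ssq_path = NULL,
                         cohort_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- cohort_path %||% file.path(config$out_dir, "cohort.tsv")
  results <- list()
  for (stage in stages) {
    log_msg(config, "stage: ", stage)
    res <- tryCatch(switch(stage,
      simulate = stage_simulate(config, cohort_path),
      ssq = stage_ssq(config, ssq_path),
      features = stage_features(config, ecg_path),
      stats = stage_stats(config, cohort_path),
      classify = stage_classify(config, cohort_path),
      monitor = stage_monitor(config, ecg_path, cohort_path),
      stop_vims("unknown stage: ", stage)
    ), error = function(e) {
      stop_vims("stage '", stage, "' failed: ", conditionMessage(e))
    })
    results[[stage]] <- res
  }
  invisible(results)
}

stage_simulate <- function(config, cohort_path) {
  params <- cohort_effect_params(n_subjects = config$n_subjects,
                                 effects = config$effects,
                                 seed = derive_seed(config$seed, 1))
  cohort <- generate_cohort(params)
  write_tsv(cohort, cohort_path)
  jsonlite::write_json(
    list(effects = as.list(params$effects), n_subjects = params$n_subjects,
         prepost_cor = params$prepost_cor, seed = params$seed),
    file.path(config$out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  write_run_log(config, "simulate")
  cohort
}

stage_ssq <- function(config, ssq_path) {
  if (is.null(ssq_path)) stop_vims("`ssq_path` is required")
  scores <- score_ssq_csv(ssq_path)
  write_tsv(scores, file.path(config$out_dir, "ssq_scores.tsv"))
  write_run_log(config, "ssq")
  scores
}

stage_features <- function(config, ecg_path) {
  if (is.null(ecg_path)) stop_vims("`ecg_path` is required")
  ecg <- read_ecg_csv(ecg_path)
  fv <- extract_features(ecg, config$features)
  write_tsv(as.data.frame(fv), file.path(config$out_dir, "features.tsv"))
  write_run_log(config, "features")
  fv
}

stage_stats <- function(config, cohort_path) {
  cohort <- read_cohort_tsv(cohort_path)
  tab <- run_feature_stats(cohort)
  write_tsv(tab, file.path(config$out_dir, "stats.tsv"))
  write_tsv(attr(tab, "partial_correlations"),
            file.path(config$out_dir, "partial_correlations.tsv"))
  write_run_log(config, "stats")
  tab
}

stage_classify <- function(config, cohort_path) {
  cohort <- read_cohort_tsv(cohort_path)
  res <- classify_cohort(cohort, k = config$k, n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 2))
  write_tsv(res$summary, file.path(config$out_dir, "classification.tsv"))
  jsonlite::write_json(
    list(summary = res$summary,
         null_accuracies = lapply(res$permutations, `[[`, "null_accuracies")),
    file.path(config$out_dir, "classification.json"), digits = NA)
  write_run_log(config, "classify")
  res
}

stage_monitor <- function(config, ecg_path, cohort_path) {
  if (is.null(ecg_path)) stop_vims("`ecg_path` is required")
  cohort <- read_cohort_tsv(cohort_path)
  post <- cohort[cohort$phase == "post", ]
  feats <- c("sdnn", "pnn50", "ln_vlf", "ln_hf", "ln_ratio")
  clf <- train_classifier(classifier_spec("LSVM"), as.matrix(post[, feats]),
                          post$condition, positive = "VR")
  ecg <- read_ecg_csv(ecg_path)
  mc <- monitor_config(clf, window_length = min(300, duration(ecg)),
                       stride = 10, features = config$features)
  log <- monitor(ecg, mc)
  write_tsv(log, file.path(config$out_dir, "monitor_log.tsv"))
  write_run_log(config, "monitor")
  log
}

#' Command-line entry point
#'
#' Thin wrapper used by the `exec/vims` script:
#' `vims <simulate|ssq|features|stats|classify|monitor> [--seed N]
#' [--out DIR] [--ecg FILE] [--ssq FILE] [--cohort FILE] [--n-perm N]
#' [--subjects N]`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
vims_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: vims <simulate|ssq|features|stats|classify|monitor> [options]")
    return(invisible(1L))
  }
  stage <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  config <- run_config(
    out_dir = opt("--out", "."),
    seed = as.numeric(opt("--seed", 1)),
    n_subjects = as.numeric(opt("--subjects", 28)),
    n_perm = as.numeric(opt("--n-perm", 200))
  )
  run_pipeline(config, stages = stage,
               ecg_path = opt("--ecg"), ssq_path = opt("--ssq"),
               cohort_path = opt("--cohort"))
  invisible(0L)
}
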
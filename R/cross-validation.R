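# Stratified k-fold cross-validation, performance metrics, ROC/AUC and
# the label-permutation significance test.

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin. Uses the current RNG state.
stratified_folds <- function(y01, k) {
  folds <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- which(y01 == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

# Out-of-fold labels and scores for one spec. X is the raw feature
# matrix; standardization (if requested) is fit inside each training fold.
cv_core <- function(spec, X, y01, folds) {
  k <- max(folds)
  oof_label <- integer(length(y01))
  oof_score <- numeric(length(y01))
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(unique(y01[tr])) < 2L) {
      stop_vims("a class is absent from the training rows of fold ", f)
    }
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (spec$standardize) {
      std <- standardize_fit_apply(Xtr, Xte)
      Xtr <- std$train
      Xte <- std$test
    }
    m <- fit_model(spec, Xtr, y01[tr])
    pr <- predict_model(spec, m, Xte)
    oof_label[te] <- pr$label
    oof_score[te] <- pr$score
  }
  list(label = oof_label, score = oof_score)
}

# ROC by score-threshold sweep; AUC by trapezoid.
roc_points <- function(score, y01) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  pos <- sum(y01 == 1)
  neg <- sum(y01 == 0)
  tpr <- vapply(thr, function(t) sum(score >= t & y01 == 1) / pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & y01 == 0) / neg, numeric(1))
  data.frame(fpr = fpr, tpr = tpr)
}

auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

confusion_metrics <- function(label01, y01) {
  tp <- sum(label01 == 1 & y01 == 1)
  tn <- sum(label01 == 0 & y01 == 0)
  fp <- sum(label01 == 1 & y01 == 0)
  fn <- sum(label01 == 0 & y01 == 1)
  acc <- 100 * (tp + tn) / length(y01)
  rec <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else NA_real_
  list(confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(predicted = c("neg", "pos"),
                                          actual = c("neg", "pos"))),
       accuracy = acc, recall = rec, precision = prec, f1 = f1)
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Folds are stratified by class and drawn from `seed`; standardization is
#' fit inside each training fold only. Out-of-fold predictions and scores
#' are pooled into a single confusion matrix, metric set, ROC curve and
#' AUC.
#'
#' @param spec A [classifier_spec()].
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold construction.
#' @param positive Positive-class label (default `"VR"` when present).
#' @return A `classifier_report`: `accuracy`, `recall`, `precision`, `f1`
#'   (percent), `auc`, `roc_points`, `confusion`, `fold_assignments`.
#' @export
cross_validate <- function(spec, X, y, k = 10, seed = 1, positive = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop_vims("labels must be binary")
  if (nrow(X) < k) stop_vims("need at least k observations")
  positive <- positive %||% (if ("VR" %in% levels(y)) "VR" else levels(y)[2])
  y01 <- as.integer(y == positive)
  folds <- with_seed(seed, stratified_folds(y01, k))
  oof <- cv_core(spec, X, y01, folds)
  cm <- confusion_metrics(oof$label, y01)
  roc <- roc_points(oof$score, y01)
  structure(
    c(cm, list(auc = auc_trapezoid(roc), roc_points = roc,
               fold_assignments = folds, kind = spec$kind,
               positive = positive)),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> %s: acc %.1f%% | recall %.1f%% | precision %.1f%% | F1 %.1f%% | AUC %.2f\n",
    x$kind, x$accuracy, x$recall, x$precision, x$f1, x$auc))
  invisible(x)
}

#' Permutation test of cross-validated accuracy
#'
#' The observed statistic is the stratified k-fold CV accuracy; the null
#' distribution is built by re-running the identical CV on uniformly
#' permuted labels. p-value uses the add-one formula
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of label permutations (the reference analysis
#'   used 10,000; scale down for quick checks).
#' @return A `permutation_result`: `observed_accuracy`,
#'   `null_accuracies`, `n_perm`, `p_value`.
#' @export
permutation_test <- function(spec, X, y, n_perm = 10000, k = 10, seed = 1,
                             positive = NULL) {
  if (n_perm < 1) stop_vims("`n_perm` must be >= 1")
  X <- as.matrix(X)
  y <- factor(y)
  positive <- positive %||% (if ("VR" %in% levels(y)) "VR" else levels(y)[2])
  y01 <- as.integer(y == positive)
  with_seed(seed, {
    folds <- stratified_folds(y01, k)
    obs <- confusion_metrics(cv_core(spec, X, y01, folds)$label, y01)$accuracy
    null_acc <- vapply(seq_len(n_perm), function(b) {
      yp <- y01[sample.int(length(y01))]
      fb <- stratified_folds(yp, k)
      confusion_metrics(cv_core(spec, X, yp, fb)$label, yp)$accuracy
    }, numeric(1))
    structure(
      list(observed_accuracy = obs, null_accuracies = null_acc,
           n_perm = as.integer(n_perm),
           p_value = (1 + sum(null_acc >= obs)) / (1 + n_perm)),
      class = "permutation_result"
    )
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.1f%% vs null mean %.1f%% (%d perms), p = %.4g\n",
    x$observed_accuracy, mean(x$null_accuracies), x$n_perm, x$p_value))
  invisible(x)
}

#' Classify a cohort: CV + permutation test for each classifier
#'
#' Builds the feature matrix from exactly the five statistically
#' significant indicators (SDNN, pNN50, ln VLF, ln HF, ln VLF/ln HF;
#' heart rate is excluded) of the post-viewing rows, labels rows by
#' viewing condition (VR = positive), and runs [cross_validate()] and
#' [permutation_test()] for every spec.
#'
#' @param cohort A `vims_cohort` (or data frame with the same columns).
#' @param specs Named list of [classifier_spec()]s (default all four).
#' @param k Folds (default 10).
#' @param n_perm Permutations per classifier.
#' @param seed Integer seed.
#' @return A list of class `cohort_classification`: `reports` (per
#'   classifier), `permutations` (per classifier) and `summary` (one row
#'   per classifier: accuracy, recall, precision, F1, AUC, permutation
#'   p).
#' @export
classify_cohort <- function(cohort, specs = default_classifiers(), k = 10,
                            n_perm = 10000, seed = 1) {
  feats <- c("sdnn", "pnn50", "ln_vlf", "ln_hf", "ln_ratio")
  need <- c("condition", "phase", feats)
  if (!all(need %in% names(cohort))) {
    stop_vims("cohort is missing columns: ",
              paste(setdiff(need, names(cohort)), collapse = ", "))
  }
  post <- cohort[cohort$phase == "post", ]
  X <- as.matrix(post[, feats])
  y <- post$condition
  reports <- lapply(specs, function(s) {
    cross_validate(s, X, y, k = k, seed = seed, positive = "VR")
  })
  perms <- lapply(specs, function(s) {
    permutation_test(s, X, y, n_perm = n_perm, k = k, seed = seed,
                     positive = "VR")
  })
  summary <- data.frame(
    classifier = names(specs),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    recall = vapply(reports, `[[`, numeric(1), "recall"),
    precision = vapply(reports, `[[`, numeric(1), "precision"),
    f1 = vapply(reports, `[[`, numeric(1), "f1"),
    auc = vapply(reports, `[[`, numeric(1), "auc"),
    perm_p = vapply(perms, `[[`, numeric(1), "p_value"),
    row.names = NULL
  )
  structure(list(reports = reports, permutations = perms, summary = summary),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat("<cohort_classification>\n")
  print(x$summary, digits = 3)
  invisible(x)
}
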
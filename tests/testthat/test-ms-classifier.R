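# Standardization, the four classifiers, cross-validation metrics,
# ROC/AUC and the permutation test.

test_that("standardize_fit_apply uses training parameters only", {
  d <- vimshrv:::with_seed(1, list(tr = matrix(rnorm(60, 5, 3), ncol = 3),
                                   te = matrix(rnorm(30, 5, 3), ncol = 3)))
  std <- standardize_fit_apply(d$tr, d$te)
  expect_equal(unname(colMeans(std$train)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(std$train, 2, sd)), rep(1, 3), tolerance = 1e-10)
  expect_equal(std$test, sweep(sweep(d$te, 2, std$center), 2, std$scale, "/"))
  bad <- cbind(d$tr, constant = 1)
  expect_error(standardize_fit_apply(bad), "constant")
})

test_that("LSVM separates a wide-margin problem perfectly", {
  d <- separable_data()
  pr <- fit_predict(classifier_spec("LSVM"), d$X, d$y, d$X)
  expect_equal(pr$label, d$y)
  # scores orient towards the positive (VR) class
  expect_true(all(pr$score[d$y == "VR"] > pr$score[d$y == "2D"]))
})

test_that("LDA agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  for (seed in 1:5) {
    d <- vimshrv:::with_seed(seed, {
      X <- rbind(matrix(rnorm(40 * 3), ncol = 3),
                 matrix(rnorm(40 * 3, mean = 1), ncol = 3))
      list(X = X, y = rep(c("a", "b"), each = 40))
    })
    pr <- fit_predict(classifier_spec("LDA", standardize = FALSE),
                      d$X, d$y, d$X, positive = "b")
    ref <- MASS::lda(d$X, grouping = d$y)
    expect_equal(pr$label, as.character(predict(ref, d$X)$class))
  }
})

test_that("decision tree respects the 2-split budget", {
  d <- vimshrv:::with_seed(3, {
    X <- matrix(rnorm(200), ncol = 2)
    list(X = X, y = ifelse(X[, 1] > 0.3, "VR", ifelse(X[, 2] > 0.5, "VR", "2D")))
  })
  m <- vimshrv:::fit_dt(d$X, as.integer(d$y == "VR"), max_splits = 2)
  expect_lte(m$n_splits, 2L)
  n_leaves <- sum(vapply(m$nodes, function(nd) isTRUE(nd$leaf), logical(1)))
  expect_lte(n_leaves, 3L)
  pr <- vimshrv:::predict_dt(m, d$X)
  expect_gt(mean((pr$label == 1) == (d$y == "VR")), 0.9)
})

test_that("KNN ties resolve by the nearest neighbour and k is enforced", {
  # 28 training points, exactly 14 per class: every test point ties
  spec <- classifier_spec("KNN")
  X <- matrix(c(seq(-14, -1), seq(1, 14)), ncol = 1)
  y <- rep(c("2D", "VR"), each = 14)
  pr <- fit_predict(classifier_spec("KNN", standardize = FALSE),
                    X, y, matrix(c(-2, 2), ncol = 1))
  expect_equal(pr$label, c("2D", "VR"))  # nearest neighbour breaks the tie
  expect_error(fit_predict(spec, X[1:20, , drop = FALSE], y[1:20],
                           X[1:2, , drop = FALSE]),
               "at least k = 28")
})

test_that("cross_validate is perfect on separable data and reports identities", {
  d <- separable_data()
  for (kind in c("LDA", "KNN", "DT", "LSVM")) {
    rep_ <- cross_validate(classifier_spec(kind), d$X, d$y, seed = 2)
    expect_equal(rep_$accuracy, 100)
    expect_equal(rep_$recall, 100)
    expect_equal(rep_$precision, 100)
    expect_equal(rep_$f1, 100)
    expect_equal(rep_$auc, 1)
  }
})

test_that("metric identities hold on imperfect predictions", {
  d <- vimshrv:::with_seed(9, {
    X <- rbind(matrix(rnorm(28 * 5), ncol = 5),
               matrix(rnorm(28 * 5, mean = 0.8), ncol = 5))
    colnames(X) <- c("sdnn", "pnn50", "ln_vlf", "ln_hf", "ln_ratio")
    list(X = X, y = rep(c("2D", "VR"), each = 28))
  })
  rep_ <- cross_validate(classifier_spec("LDA"), d$X, d$y, seed = 4)
  cm <- rep_$confusion
  expect_equal(sum(cm), 56)
  tp <- cm["pos", "pos"]; fp <- cm["pos", "neg"]; fn <- cm["neg", "pos"]
  expect_equal(rep_$accuracy, 100 * (tp + cm["neg", "neg"]) / 56)
  expect_equal(rep_$recall, 100 * tp / (tp + fn))
  expect_equal(rep_$precision, 100 * tp / (tp + fp))
  expect_equal(rep_$f1,
               2 * rep_$precision * rep_$recall / (rep_$precision + rep_$recall))
  # every subject appears in exactly one fold; folds stratified
  expect_equal(sort(unique(rep_$fold_assignments)), 1:10)

  # AUC equals the Mann-Whitney statistic on the pooled scores
  # (recompute scores by rerunning the identical CV)
  y01 <- as.integer(d$y == "VR")
  folds <- vimshrv:::with_seed(4, vimshrv:::stratified_folds(y01, 10))
  oof <- vimshrv:::cv_core(classifier_spec("LDA"), d$X, y01, folds)
  r <- rank(oof$score)
  n1 <- sum(y01); n0 <- sum(1 - y01)
  auc_mw <- (sum(r[y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_equal(rep_$auc, auc_mw, tolerance = 1e-10)
})

test_that("random labels give chance-level accuracy", {
  accs <- sapply(1:50, function(seed) {
    d <- vimshrv:::with_seed(seed, {
      list(X = matrix(rnorm(40 * 4), ncol = 4),
           y = rep(c("2D", "VR"), each = 20))
    })
    cross_validate(classifier_spec("LDA"), d$X, d$y, k = 5,
                   seed = seed)$accuracy
  })
  expect_gt(mean(accs), 45)
  expect_lt(mean(accs), 55)
})

test_that("permutation test: add-one p, determinism, lower bound", {
  d <- separable_data(n_per_class = 15)
  pt <- permutation_test(classifier_spec("LDA"), d$X, d$y, n_perm = 19,
                         k = 5, seed = 6)
  expect_equal(pt$observed_accuracy, 100)
  expect_length(pt$null_accuracies, 19)
  expect_equal(pt$p_value, 1 / 20)  # observed beats every permutation
  pt2 <- permutation_test(classifier_spec("LDA"), d$X, d$y, n_perm = 19,
                          k = 5, seed = 6)
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
  expect_gte(pt$p_value, 1 / (pt$n_perm + 1))
  expect_error(permutation_test(classifier_spec("LDA"), d$X, d$y, n_perm = 0),
               ">= 1")
})

test_that("permutation p-values are calibrated under the null", {
  # scaled-down calibration run: 120 null datasets, n_perm = 79
  ps <- sapply(1:120, function(i) {
    d <- vimshrv:::with_seed(2000 + i, {
      list(X = matrix(rnorm(40 * 3), ncol = 3),
           y = rep(c("2D", "VR"), each = 20))
    })
    permutation_test(classifier_spec("LDA"), d$X, d$y, n_perm = 79,
                     k = 4, seed = 1000 + i)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("classify_cohort uses the five significant features only", {
  co <- demo_cohort_cached()
  res <- classify_cohort(co, n_perm = 20, seed = 3)
  expect_equal(res$summary$classifier, c("LDA", "KNN", "DT", "LSVM"))
  expect_true(all(res$summary$accuracy > 80))
  expect_true(all(res$summary$perm_p <= 0.5))
  # heart rate must not enter the feature matrix: removing it changes nothing
  co2 <- co; co2$heart_rate <- co2$heart_rate * 0
  res2 <- classify_cohort(co2, n_perm = 20, seed = 3)
  expect_equal(res2$summary, res$summary)
  expect_error(classify_cohort(co[, setdiff(names(co), "ln_ratio")]),
               "missing columns")
})
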
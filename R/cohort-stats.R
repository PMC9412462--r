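# Covariate-adjusted group statistics: ANCOVA with the pre-viewing state
# as baseline covariate, partial eta-squared effect sizes, Bonferroni
# families, and baseline-adjusted partial correlations.

#' ANCOVA of post-viewing values with a baseline covariate
#'
#' Fits `post ~ baseline + group` (homogeneous slopes, group coded as a
#' factor) and F-tests the group term with `df1 = g - 1`,
#' `df2 = n - g - 1` (1 and n - 3 for two groups). Partial eta-squared is
#' computed from the sums of squares; adjusted group means are evaluated
#' at the grand covariate mean.
#'
#' @param post Numeric outcome values.
#' @param group Group labels (two or more levels; the target design has
#'   two viewing conditions).
#' @param baseline Numeric covariate (pre-viewing values).
#' @return An `ancova_result`: `f_stat`, `df1`, `df2`, `p_value`,
#'   `eta_p2`, `adjusted_means`.
#' @export
ancova <- function(post, group, baseline) {
  group <- factor(group)
  n <- length(post)
  if (length(group) != n || length(baseline) != n) {
    stop_vims("`post`, `group` and `baseline` must have equal length")
  }
  if (anyNA(post) || anyNA(baseline) || anyNA(group)) {
    stop_vims("missing values are not allowed")
  }
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    stop_vims("need at least 2 groups with >= 2 observations each")
  }
  dat <- data.frame(post = post, group = group, baseline = baseline)
  fit <- stats::lm(post ~ baseline + group, data = dat)
  if (fit$rank < 1L + 1L + (nlevels(group) - 1L)) {
    stop_vims("singular design: covariate is collinear with the group coding")
  }
  # sequential ANOVA with the group term entered last = partial SS for group
  tab <- stats::anova(fit)
  ss_group <- tab["group", "Sum Sq"]
  ss_res <- tab["Residuals", "Sum Sq"]
  df1 <- tab["group", "Df"]
  df2 <- tab["Residuals", "Df"]
  f <- tab["group", "F value"]
  newdat <- data.frame(group = factor(levels(group), levels = levels(group)),
                       baseline = mean(baseline))
  adj <- stats::predict(fit, newdata = newdat)
  names(adj) <- levels(group)
  structure(
    list(f_stat = f, df1 = df1, df2 = df2,
         p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
         eta_p2 = ss_group / (ss_group + ss_res),
         adjusted_means = adj),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova> F(%d, %d) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
              x$df1, x$df2, x$f_stat, x$p_value, x$eta_p2))
  invisible(x)
}

#' Partial eta-squared from an F statistic
#'
#' `eta_p^2 = F df1 / (F df1 + df2)`, the effect size corresponding to an
#' F test.
#'
#' @param f Non-negative F value.
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return Partial eta-squared in \[0, 1).
#' @examples
#' partial_eta_squared(15.244, 1, 53)  # 0.223
#' @export
partial_eta_squared <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 >= 1), all(df2 >= 1))
  f * df1 / (f * df1 + df2)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param base_alpha Family-wise alpha (default 0.05).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `base_alpha / n_tests` (e.g. 0.0125 for 4 tests, 0.008333...
#'   for 6, printed as 0.0083).
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_tests) {
  if (any(n_tests < 1)) stop_vims("`n_tests` must be >= 1")
  base_alpha / n_tests
}

#' Qualitative interpretation of partial eta-squared
#'
#' Conventional thresholds 0.01 / 0.06 / 0.14 for small / medium / large.
#'
#' @param eta_p2 Value(s) in \[0, 1\].
#' @return Character vector in `{negligible, small, medium, large}`.
#' @export
interpret_effect_size <- function(eta_p2) {
  stopifnot(all(eta_p2 >= 0 & eta_p2 <= 1))
  ifelse(eta_p2 >= 0.14, "large",
         ifelse(eta_p2 >= 0.06, "medium",
                ifelse(eta_p2 >= 0.01, "small", "negligible")))
}

interpret_correlation <- function(r) {
  a <- abs(r)
  ifelse(a < 0.10, "negligible",
         ifelse(a < 0.40, "weak",
                ifelse(a < 0.70, "moderate",
                       ifelse(a < 0.90, "strong", "very strong"))))
}

#' Partial correlation controlling for a covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariate(s); `df = n - 3`, two-sided p via the t
#' transform. With the single-covariate form this equals the textbook
#' closed form `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' Supplying `y_covariate` residualizes each variable on its own baseline
#' (the form used for the SSQ-vs-feature analysis).
#'
#' @param x,y Numeric vectors (n >= 4).
#' @param covariate Covariate for `x` (and for `y` unless `y_covariate`
#'   is given).
#' @param y_covariate Optional separate covariate for `y`.
#' @return A `partial_corr_result`: `r`, `p_value`, `df`,
#'   `interpretation` (negligible / weak / moderate / strong /
#'   very strong bins on |r|).
#' @export
partial_correlation <- function(x, y, covariate, y_covariate = NULL) {
  n <- length(x)
  y_cov <- y_covariate %||% covariate
  if (length(y) != n || length(covariate) != n || length(y_cov) != n) {
    stop_vims("all inputs must have equal length")
  }
  if (n < 4L) stop_vims("partial correlation needs n >= 4")
  for (v in list(x, y, covariate, y_cov)) {
    if (stats::sd(v) == 0) stop_vims("constant input: correlation undefined")
  }
  rx <- stats::resid(stats::lm(x ~ covariate))
  ry <- stats::resid(stats::lm(y ~ y_cov))
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tval <- r * sqrt(df / (1 - r^2))
  structure(
    list(r = r, p_value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
         df = df, interpretation = interpret_correlation(r)),
    class = "partial_corr_result"
  )
}

#' @export
print.partial_corr_result <- function(x, ...) {
  cat(sprintf("<partial correlation> r = %.3f (%s), df = %d, p = %.4g\n",
              x$r, x$interpretation, x$df, x$p_value))
  invisible(x)
}

#' Full ANCOVA + correlation table for a cohort
#'
#' Runs the baseline-adjusted ANCOVA for each of the six cardiac features
#' (Bonferroni family of 6, alpha = 0.05/6) and the four SSQ scores
#' (family of 4, alpha = 0.0125), comparing 2D vs VR post-viewing values
#' with the pre-viewing value as covariate; then partial correlations of
#' the post total SSQ score against each cardiac feature, each variable
#' residualized on its own pre-viewing baseline.
#'
#' @param cohort A `vims_cohort` (or data frame with the same columns).
#' @param base_alpha Family-wise alpha (default 0.05).
#' @return A data frame with one row per outcome (`outcome`, `family`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `eta_p2`, `effect_size`, `alpha`,
#'   `significant`, `adj_diff` = VR minus 2D adjusted means) and an
#'   attribute `partial_correlations`.
#' @export
run_feature_stats <- function(cohort, base_alpha = 0.05) {
  cardiac <- c("heart_rate", "sdnn", "pnn50", "ln_vlf", "ln_hf", "ln_ratio")
  ssq <- c("ssq_n", "ssq_o", "ssq_d", "ssq_total")
  need <- c("subject", "condition", "phase", cardiac, ssq)
  if (!all(need %in% names(cohort))) {
    stop_vims("cohort is missing columns: ",
              paste(setdiff(need, names(cohort)), collapse = ", "))
  }
  pre <- cohort[cohort$phase == "pre", ]
  post <- cohort[cohort$phase == "post", ]
  key <- function(d) paste(d$subject, d$condition)
  pre <- pre[match(key(post), key(pre)), ]
  if (anyNA(pre$subject)) stop_vims("missing pre-viewing cells")

  alpha <- c(stats::setNames(rep(bonferroni_alpha(base_alpha, length(ssq)),
                                 length(ssq)), ssq),
             stats::setNames(rep(bonferroni_alpha(base_alpha, length(cardiac)),
                                 length(cardiac)), cardiac))
  outcomes <- c(ssq, cardiac)
  res <- lapply(outcomes, function(v) {
    a <- ancova(post[[v]], post$condition, pre[[v]])
    data.frame(outcome = v,
               family = if (v %in% ssq) "ssq" else "cardiac",
               f_stat = a$f_stat, df1 = a$df1, df2 = a$df2,
               p_value = a$p_value, eta_p2 = a$eta_p2,
               effect_size = interpret_effect_size(a$eta_p2),
               alpha = alpha[[v]],
               significant = a$p_value < alpha[[v]],
               adj_diff = unname(a$adjusted_means["VR"] - a$adjusted_means["2D"]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  pc <- lapply(cardiac, function(v) {
    r <- partial_correlation(post$ssq_total, post[[v]],
                             covariate = pre$ssq_total,
                             y_covariate = pre[[v]])
    data.frame(feature = v, r = r$r, p_value = r$p_value, df = r$df,
               interpretation = r$interpretation)
  })
  attr(out, "partial_correlations") <- do.call(rbind, pc)
  out
}
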
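# Synthetic 2D-vs-VR within-subject cohort with known ground truth.
#
# Each subject contributes four cells (2D-pre, 2D-post, VR-pre, VR-post).
# Programmed effects are applied only to VR-post; SSQ severity is coupled
# to the programmed shift. The paper plots, but does not tabulate, the
# per-condition cardiac means, so the default effect sizes are stand-ins
# chosen for testability (see the methods vignette), not study values.

#' Cohort-effect parameters
#'
#' @param n_subjects Number of subjects (>= 2; default 28, the study's
#'   sample size).
#' @param effects Named vector of VR-post shifts in between-subject SD
#'   units for `sdnn`, `pnn50`, `ln_vlf`, `ln_hf`. Signs follow the
#'   reported direction of effects (VR: SDNN down, pNN50 down, ln HF
#'   down, ln VLF up).
#' @param means Named vector of 2D-state feature means (`heart_rate` bpm,
#'   `sdnn` ms, `pnn50` %, `ln_vlf`/`ln_hf` ln ms^2).
#' @param between_sd Named vector of between-subject SDs, same units.
#' @param prepost_cor Pre/post correlation within a cell, in \[0, 1).
#' @param ssq_coupling Slope linking the mean absolute programmed effect
#'   to latent SSQ severity under VR viewing.
#' @param seed Integer seed.
#' @param mode `"features"` draws feature vectors directly (fast mode);
#'   `"rr"` additionally attaches a generated RR series per cell whose
#'   spectral content matches the cell's ln VLF / ln HF (end-to-end mode).
#' @return A list of class `cohort_effect_params`.
#' @export
cohort_effect_params <- function(n_subjects = 28,
                                 effects = c(sdnn = -2, pnn50 = -2,
                                             ln_vlf = 2, ln_hf = -2),
                                 means = c(heart_rate = 70, sdnn = 50,
                                           pnn50 = 30, ln_vlf = 6, ln_hf = 5.5),
                                 between_sd = c(heart_rate = 8, sdnn = 8,
                                                pnn50 = 8, ln_vlf = 0.7,
                                                ln_hf = 0.7),
                                 prepost_cor = 0.7, ssq_coupling = 1.5,
                                 seed = 1,
                                 mode = c("features", "rr")) {
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    stop_vims("`n_subjects` must be >= 2")
  }
  if (!is_scalar_number(prepost_cor) || prepost_cor < 0 || prepost_cor >= 1) {
    stop_vims("`prepost_cor` must lie in [0, 1)")
  }
  need <- c("sdnn", "pnn50", "ln_vlf", "ln_hf")
  stopifnot(all(need %in% names(effects)),
            all(c("heart_rate", need) %in% names(means)),
            all(c("heart_rate", need) %in% names(between_sd)),
            all(between_sd > 0))
  structure(list(n_subjects = as.integer(n_subjects), effects = effects,
                 means = means, between_sd = between_sd,
                 prepost_cor = prepost_cor, ssq_coupling = ssq_coupling,
                 seed = seed, mode = match.arg(mode)),
            class = "cohort_effect_params")
}

#' Generate a synthetic 2D-vs-VR cohort
#'
#' For each subject and condition, pre and post feature values share a
#' subject-level component (correlation `prepost_cor`); the programmed
#' shift is added to VR-post only. `ln_ratio` is computed as
#' `ln_vlf / ln_hf`, never drawn. One SSQ response is generated per cell
#' with latent severity low at baseline and coupled to the programmed
#' effect magnitude under VR-post.
#'
#' @param params A [cohort_effect_params()].
#' @return A data frame of class `vims_cohort`: one row per subject x
#'   condition x phase, columns `subject`, `condition` (`"2D"`/`"VR"`),
#'   `phase` (`"pre"`/`"post"`), the six cardiac features, `ssq_n`,
#'   `ssq_o`, `ssq_d`, `ssq_total`. In `mode = "rr"`, attribute
#'   `rr_series` holds one generated `rr_series` per row.
#' @export
generate_cohort <- function(params = cohort_effect_params()) {
  stopifnot(inherits(params, "cohort_effect_params"))
  p <- params
  feats <- c("heart_rate", "sdnn", "pnn50", "ln_vlf", "ln_hf")
  design <- expand.grid(phase = c("pre", "post"), condition = c("2D", "VR"),
                        subject = seq_len(p$n_subjects),
                        stringsAsFactors = FALSE)
  design <- design[, c("subject", "condition", "phase")]
  rho <- p$prepost_cor

  with_seed(p$seed, {
    rows <- vector("list", nrow(design))
    sev_all <- numeric(nrow(design))
    # subject-level latent per feature, shared across all four cells
    z_subj <- matrix(stats::rnorm(p$n_subjects * length(feats)),
                     nrow = p$n_subjects, dimnames = list(NULL, feats))
    for (i in seq_len(nrow(design))) {
      s <- design$subject[i]
      vr_post <- design$condition[i] == "VR" & design$phase[i] == "post"
      val <- vapply(feats, function(f) {
        e <- stats::rnorm(1)
        base <- p$means[[f]] + p$between_sd[[f]] *
          (sqrt(rho) * z_subj[s, f] + sqrt(1 - rho) * e)
        shift <- if (vr_post && f %in% names(p$effects)) {
          p$effects[[f]] * p$between_sd[[f]]
        } else 0
        base + shift
      }, numeric(1))
      # keep pNN50 a valid percentage
      val[["pnn50"]] <- min(max(val[["pnn50"]], 0), 100)
      # latent severities: mildly symptomatic at rest (so SSQ baselines
      # have variance), elevated only under VR viewing
      sev <- if (vr_post) {
        -0.5 + p$ssq_coupling * mean(abs(p$effects)) + stats::rnorm(1, 0, 0.4)
      } else if (design$phase[i] == "post") {
        -0.5 + stats::rnorm(1, 0, 0.4)
      } else {
        -0.7 + stats::rnorm(1, 0, 0.3)
      }
      sev_all[i] <- sev
      rows[[i]] <- c(val, ln_ratio = unname(val[["ln_vlf"]] / val[["ln_hf"]]))
    }
    tab <- cbind(design, do.call(rbind, rows))
    ssq_seeds <- stats::runif(nrow(tab), 0, 2^30)
    ssq <- t(vapply(seq_len(nrow(tab)), function(i) {
      sc <- score_ssq(generate_ssq_response(sev_all[i], seed = ssq_seeds[i]))
      c(ssq_n = sc$n_score, ssq_o = sc$o_score, ssq_d = sc$d_score,
        ssq_total = sc$total)
    }, numeric(4)))
    tab <- cbind(tab, ssq)
    class(tab) <- c("vims_cohort", "data.frame")
    attr(tab, "params") <- p
    if (p$mode == "rr") {
      rr_seeds <- round(stats::runif(nrow(tab), 0, 2^30))
      attr(tab, "rr_series") <- lapply(seq_len(nrow(tab)), function(i) {
        generate_rr_series(rr_params_for_features(
          heart_rate = tab$heart_rate[i], sdnn = tab$sdnn[i],
          ln_vlf = tab$ln_vlf[i], ln_hf = tab$ln_hf[i],
          seed = rr_seeds[i]))
      })
    }
    tab
  })
}

# Map a target feature vector to RR-generator parameters: sinusoid
# amplitudes reproduce the target band powers (a = sqrt(2 exp(ln p)));
# any remaining SDNN variance goes to white jitter.
rr_params_for_features <- function(heart_rate, sdnn, ln_vlf, ln_hf,
                                   duration = 330, seed = 1) {
  vlf_amp <- sqrt(2 * exp(ln_vlf))
  hf_amp <- sqrt(2 * exp(ln_hf))
  resid_var <- max(sdnn^2 - exp(ln_vlf) - exp(ln_hf), 0)
  rr_gen_params(mean_rr = 60000 / heart_rate,
                vlf_amp = vlf_amp, vlf_freq = 0.02,
                hf_amp = hf_amp, hf_freq = 0.25,
                jitter_sd = sqrt(resid_var),
                duration = duration, seed = seed)
}

#' @export
print.vims_cohort <- function(x, ...) {
  cat(sprintf("<vims_cohort> %d subjects x {2D, VR} x {pre, post} (%d rows)\n",
              length(unique(x$subject)), nrow(x)))
  NextMethod()
}
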
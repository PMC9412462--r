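# Generators: RR series, ECG waveforms, SSQ responses, cohorts.

test_that("generate_rr_series: degenerate, deterministic, spectrally true", {
  const <- generate_rr_series(rr_gen_params(mean_rr = 850, vlf_amp = 0,
                                            hf_amp = 0, jitter_sd = 0,
                                            duration = 30, seed = 1))
  expect_true(all(const$intervals == 850))
  expect_equal(const$beat_times, c(0, cumsum(const$intervals) / 1000))
  expect_gte(max(const$beat_times), 30)

  p <- rr_gen_params(duration = 60, seed = 99)
  expect_identical(generate_rr_series(p), generate_rr_series(p))

  # HF band power ~ a^2/2 = 50 ms^2 against the rectangular periodogram
  rr <- hf_only_rr()
  tach <- resample_tachogram(as_nn_series(rr))
  expect_equal(periodogram_band_power(tach$values, 4, c(0.15, 0.4)), 50,
               tolerance = 0.1)
  expect_error(rr_gen_params(mean_rr = -5), "positive")
  expect_error(generate_rr_series(rr_gen_params(mean_rr = 900, duration = 0.5)),
               "fewer than 2 beats")
})

test_that("spectral truth holds across random generator settings", {
  # invariant: per-sinusoid band power within 10% of a^2/2 on noiseless
  # 300-s records (independent periodogram oracle)
  for (seed in 1:5) {
    prm <- vimshrv:::with_seed(seed, rr_gen_params(
      vlf_amp = runif(1, 8, 20), vlf_freq = runif(1, 0.015, 0.032),
      hf_amp = runif(1, 8, 20), hf_freq = runif(1, 0.18, 0.35),
      jitter_sd = 0, duration = 300, seed = seed + 100))
    tach <- resample_tachogram(as_nn_series(generate_rr_series(prm)))
    vlf <- periodogram_band_power(tach$values, 4, c(0.0033, 0.04))
    hf <- periodogram_band_power(tach$values, 4, c(0.15, 0.4))
    expect_equal(vlf, prm$vlf_amp^2 / 2, tolerance = 0.1)
    expect_equal(hf, prm$hf_amp^2 / 2, tolerance = 0.1)
  }
})

test_that("generate_ecg produces a clean template train with ground truth", {
  rr <- generate_rr_series(rr_gen_params(duration = 30, seed = 3))
  gen <- generate_ecg(rr)
  expect_length(gen$r_times, length(rr$beat_times))
  peaks <- detect_r_peaks(bandpass_filter(gen$ecg), raw = gen$ecg)
  sc <- score_detection(peaks$times, gen$r_times, tol = 0.02)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$ppv, 1)
})

test_that("powerline option injects a 60 Hz line absent otherwise", {
  rr <- generate_rr_series(rr_gen_params(duration = 20, seed = 4))
  clean <- generate_ecg(rr, ecg_gen_params(seed = 5))$ecg
  noisy <- generate_ecg(rr, ecg_gen_params(powerline_amp = 0.2, seed = 5))$ecg
  amp60 <- function(rec) {
    n <- length(rec$samples)
    f <- (seq_len(n) - 1) * rec$fs / n
    p <- Mod(stats::fft(rec$samples - mean(rec$samples))) / n
    max(p[abs(f - 60) < 0.5])
  }
  expect_gt(amp60(noisy), 10 * amp60(clean))
  expect_error(ecg_gen_params(fs = 50), ">= 100 Hz")
  tpl <- ecg_gen_params()$beat_template
  tpl$amp[["R"]] <- 0.1
  expect_error(ecg_gen_params(beat_template = tpl), "largest positive")
})

test_that("SSQ generator floors, saturates and is monotone in severity", {
  lo <- generate_ssq_response(-999, seed = 1)
  expect_true(all(lo == 0))
  hi <- generate_ssq_response(999, seed = 1)
  expect_true(all(hi == 3))
  means <- sapply(c(-2, 0, 2), function(sev) {
    mean(sapply(1:300, function(i) {
      score_ssq(generate_ssq_response(sev, seed = 1000 * sev + i))$total
    }))
  })
  expect_true(all(diff(means) > 0))
  # ratings never leave {0,1,2,3}
  for (sev in c(-3, 0.5, 4)) {
    expect_true(all(generate_ssq_response(sev, seed = 2) %in% 0:3))
  }
})

test_that("generate_cohort is deterministic with programmed VR-post effects", {
  p <- cohort_effect_params(n_subjects = 12, seed = 7)
  co <- generate_cohort(p)
  expect_identical(co, generate_cohort(p))
  expect_equal(nrow(co), 12 * 4)
  expect_setequal(unique(co$condition), c("2D", "VR"))
  expect_setequal(unique(co$phase), c("pre", "post"))

  big <- generate_cohort(cohort_effect_params(seed = 8))
  vp <- big[big$condition == "VR" & big$phase == "post", ]
  dp <- big[big$condition == "2D" & big$phase == "post", ]
  expect_gt(mean(vp$ln_vlf), mean(dp$ln_vlf))
  expect_lt(mean(vp$ln_hf), mean(dp$ln_hf))
  expect_lt(mean(vp$sdnn), mean(dp$sdnn))
  expect_gt(mean(vp$ssq_total), mean(dp$ssq_total))
  # ln_ratio is computed, not drawn
  expect_equal(big$ln_ratio, big$ln_vlf / big$ln_hf)
  expect_error(cohort_effect_params(n_subjects = 1), ">= 2")
  expect_error(cohort_effect_params(prepost_cor = 1), "\\[0, 1\\)")
})

test_that("zero-effect cohorts leave 2D-post and VR-post indistinguishable", {
  feats <- c("sdnn", "pnn50", "ln_vlf", "ln_hf")
  null_eff <- c(sdnn = 0, pnn50 = 0, ln_vlf = 0, ln_hf = 0)
  pvals <- sapply(1:100, function(seed) {
    co <- generate_cohort(cohort_effect_params(n_subjects = 14,
                                               effects = null_eff,
                                               seed = seed))
    vp <- co[co$condition == "VR" & co$phase == "post", ]
    dp <- co[co$condition == "2D" & co$phase == "post", ]
    sapply(feats, function(f) {
      suppressWarnings(stats::ks.test(vp[[f]], dp[[f]])$p.value)
    })
  })
  # per feature, KS p > 0.01 in at least 95% of seeds
  expect_true(all(rowMeans(pvals > 0.01) >= 0.95))
})

test_that("rr mode attaches per-cell RR series consistent with the features", {
  co <- generate_cohort(cohort_effect_params(n_subjects = 2, seed = 5,
                                             mode = "rr"))
  rrs <- attr(co, "rr_series")
  expect_length(rrs, nrow(co))
  i_vr <- which(co$condition == "VR" & co$phase == "post")[1]
  i_2d <- which(co$condition == "2D" & co$phase == "post")[1]
  fv <- function(i) {
    suppressWarnings(vimshrv:::features_from_nn(as_nn_series(rrs[[i]])))
  }
  f_vr <- fv(i_vr); f_2d <- fv(i_2d)
  # generated signals carry the programmed spectral shift
  expect_equal(f_vr$ln_vlf, co$ln_vlf[i_vr], tolerance = 0.15)
  expect_equal(f_2d$ln_hf, co$ln_hf[i_2d], tolerance = 0.15)
  expect_gt(f_vr$ln_vlf, f_2d$ln_vlf)
  expect_lt(f_vr$ln_hf, f_2d$ln_hf)
})
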
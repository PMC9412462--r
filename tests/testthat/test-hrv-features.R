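# Time-domain features, tachogram resampling, spectrum, band powers,
# log-normalisation and zone classification.

test_that("sdnn is the sample SD and is order-free and linear", {
  expect_equal(sdnn(make_nn(c(800, 800, 800))), 0)
  expect_equal(sdnn(make_nn(c(800, 810, 790, 800))), sqrt(200 / 3),
               tolerance = 1e-12)  # 8.165 ms
  iv <- vimshrv:::with_seed(3, runif(30, 700, 1100))
  expect_equal(sdnn(make_nn(iv)), sdnn(make_nn(rev(iv))))
  expect_equal(sdnn(make_nn(2.5 * iv)), 2.5 * sdnn(make_nn(iv)))
  expect_error(sdnn(make_nn(800)), "at least 2")
})

test_that("pnn50 counts strict >50 ms differences", {
  # diffs 60, 50, 90: the exact 50 must not count
  expect_equal(pnn50(make_nn(c(800, 860, 810, 900))), 200 / 3,
               tolerance = 1e-12)
  expect_equal(pnn50(make_nn(rep(900, 10))), 0)
  expect_equal(pnn50(make_nn(c(600, 1200))), 100)
  iv <- vimshrv:::with_seed(4, runif(40, 600, 1200))
  p <- pnn50(make_nn(iv))
  expect_gte(p, 0); expect_lte(p, 100)
})

test_that("mean heart rate is 60000 / mean NN", {
  expect_equal(mean_heart_rate(make_nn(rep(1000, 5))), 60)
  expect_equal(mean_heart_rate(make_nn(rep(800, 5))), 75)
  expect_error(mean_heart_rate(make_nn(numeric(0))), "at least 1")
})

test_that("resample_tachogram yields a 4 Hz grid through the knots", {
  nn <- make_nn(rep(800, 13))  # 10 s span of constant 800 ms
  tach <- resample_tachogram(nn)
  expect_equal(tach$fs_resample, 4)
  expect_true(all(abs(tach$values - 800) < 1e-9))
  expect_length(tach$values, floor(sum(rep(800, 12)) / 1000 * 4) + 1)

  iv <- vimshrv:::with_seed(5, runif(20, 700, 1000))
  nn2 <- make_nn(iv)
  tach2 <- resample_tachogram(nn2)
  # interpolant passes through every knot
  f <- stats::splinefun(nn2$onset_times, nn2$intervals, method = "fmm")
  expect_lt(max(abs(f(nn2$onset_times) - nn2$intervals)), 1e-9)
  expect_error(resample_tachogram(make_nn(c(800, 900, 850))), "at least 4")
  expect_error(resample_tachogram(make_nn(rep(300, 6))), "less than 2 s")
})

test_that("hrv_spectrum satisfies Parseval and basic shape invariants", {
  nn <- hf_only_rr()
  tach <- resample_tachogram(as_nn_series(nn))
  spec <- hrv_spectrum(tach)
  expect_true(all(spec$psd >= 0))
  expect_true(all(diff(spec$freqs) > 0))
  df <- spec$freqs[2] - spec$freqs[1]
  expect_lte(max(spec$freqs), 2)
  expect_gte(max(spec$freqs), 2 - df)
  x <- tach$values - mean(tach$values)
  expect_equal(sum(spec$psd) * df, mean(x^2), tolerance = 1e-9)
  # constant input -> zero total power
  flat <- structure(list(values = rep(800, 200), fs_resample = 4, t0 = 0),
                    class = "uniform_tachogram")
  expect_equal(sum(hrv_spectrum(flat)$psd), 0)
  short <- structure(list(values = rep(800, 10), fs_resample = 4, t0 = 0),
                     class = "uniform_tachogram")
  expect_error(hrv_spectrum(short), "at least 64")
})

test_that("band powers recover analytic sinusoid power", {
  # 10-ms HF sinusoid: band power a^2/2 = 50 ms^2
  tach <- resample_tachogram(as_nn_series(hf_only_rr()))
  spec <- hrv_spectrum(tach)
  bp <- suppressWarnings(band_powers(spec))
  expect_equal(bp$hf_power, 50, tolerance = 0.1)
  expect_lt(bp$vlf_power, 0.05 * bp$hf_power)
  # cross-check against the independent rectangular periodogram oracle
  oracle <- periodogram_band_power(tach$values, 4, c(0.15, 0.4))
  expect_equal(bp$hf_power, oracle, tolerance = 0.05)

  # 0.01-Hz sinusoid on a 600-s record: VLF dominates by >= 10x
  rrv <- generate_rr_series(rr_gen_params(vlf_amp = 10, vlf_freq = 0.01,
                                          hf_amp = 0, jitter_sd = 0,
                                          duration = 600, seed = 6))
  specv <- hrv_spectrum(resample_tachogram(as_nn_series(rrv)))
  bpv <- band_powers(specv)
  expect_gt(bpv$vlf_power, 10 * bpv$hf_power)
  # bands are subsets of the full range
  dfv <- specv$freqs[2] - specv$freqs[1]
  expect_lte(bpv$vlf_power + bpv$hf_power, sum(specv$psd) * dfv * 1.001)
  expect_error(band_powers(spec, hf = c(0.15, 3)), "outside spectral range")
})

test_that("ln_features applies the natural log with a documented floor", {
  expect_equal(unlist(ln_features(exp(1), exp(1))), c(ln_vlf = 1, ln_hf = 1, ln_ratio = 1))
  expect_equal(unlist(ln_features(exp(4), exp(2))), c(ln_vlf = 4, ln_hf = 2, ln_ratio = 2))
  expect_warning(lf <- ln_features(exp(2), 0), "floored")
  expect_equal(lf$ln_hf, log(1e-12))
  expect_true(is.finite(lf$ln_ratio))
  expect_error(ln_features(exp(2), 1), "undefined")  # ln HF exactly 0
  expect_equal(ln_features(exp(4), exp(2), ratio_mode = "log_of_ratio")$ln_ratio, 2)
})

test_that("zone map matches the published semantics and partitions the plane", {
  zc <- zone_config(4, 6, 4, 6)
  expect_equal(classify_zone(7, 3, zc), "Zone5")   # high symp / low para
  expect_equal(classify_zone(3, 7, zc), "Zone1")   # low symp / high para
  expect_equal(classify_zone(5, 5, zc), "Reference")
  expect_equal(classify_zone(7, 7, zc), "Zone3")
  expect_equal(classify_zone(3, 3, zc), "Zone7")
  # boundaries belong to "normal" (closed interval)
  expect_equal(classify_zone(4, 6, zc), "Reference")
  expect_equal(classify_zone(6, 4, zc), "Reference")
  # every point maps to exactly one label
  g <- expand.grid(x = seq(0, 10, by = 0.5), y = seq(0, 10, by = 0.5))
  z <- classify_zone(g$x, g$y, zc)
  expect_false(anyNA(z))
  expect_setequal(unique(z), c(paste0("Zone", 1:8), "Reference"))
  expect_error(zone_config(6, 4, 4, 6), "low < high")
})

test_that("zone_config_from_reference uses cohort quartiles", {
  v <- 1:100; h <- 101:200
  zc <- zone_config_from_reference(v, h)
  expect_equal(zc$vlf_low, unname(quantile(v, 0.25)))
  expect_equal(zc$hf_high, unname(quantile(h, 0.75)))
})

test_that("extract_features runs end-to-end and recovers spectral truth", {
  rr <- generate_rr_series(rr_gen_params(mean_rr = 900, vlf_amp = 10,
                                         hf_amp = 15, jitter_sd = 2,
                                         duration = 330, seed = 21))
  gen <- generate_ecg(rr, ecg_gen_params(fs = 250))
  fv <- extract_features(gen$ecg)
  # ln HF within 0.15 of the analytic sinusoid power a^2/2 = 112.5 ms^2
  expect_lt(abs(fv$ln_hf - log(112.5)), 0.15)
  expect_equal(fv$n_rejected, 0L)
  expect_gt(fv$sdnn, 0)
  # determinism
  fv2 <- extract_features(gen$ecg)
  expect_identical(fv, fv2)
})

test_that("extract_features rejects records with no valid NN intervals", {
  rr <- generate_rr_series(rr_gen_params(mean_rr = 500, vlf_amp = 0,
                                         hf_amp = 0, jitter_sd = 0,
                                         duration = 40, seed = 2))
  gen <- generate_ecg(rr)
  expect_error(suppressWarnings(extract_features(gen$ecg)), "no NN intervals")
})
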
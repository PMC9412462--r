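# Shared fixtures and independent oracles for the test suite.
# Heavier shared objects are built lazily and cached for the run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# nn_series straight from a vector of intervals (ms), onsets by cumulation
make_nn <- function(intervals, n_rejected = 0L, start = 0) {
  n <- length(intervals)
  onsets <- start + c(0, cumsum(intervals[-n])) / 1000
  structure(list(intervals = as.numeric(intervals), onset_times = onsets,
                 n_rejected = as.integer(n_rejected)),
            class = "nn_series")
}

# Independent spectral oracle: plain rectangular-window periodogram band
# power (no Hann window, no rescaling; Parseval-exact by construction).
periodogram_band_power <- function(x, fs, band) {
  x <- x - mean(x)
  n <- length(x)
  p2 <- Mod(stats::fft(x))^2 / n^2       # two-sided, sums to mean(x^2)
  f <- (seq_len(n) - 1) * fs / n
  half <- f > 0 & f <= fs / 2
  sum(2 * p2[half][f[half] >= band[1] & f[half] <= band[2]])
}

# Independent nested-model F oracle for the ANCOVA: explicit least
# squares, full model (intercept + baseline + group) vs reduced
# (intercept + baseline).
ancova_oracle <- function(post, group, baseline) {
  g <- as.numeric(factor(group)) - 1
  X1 <- cbind(1, baseline, g)
  X0 <- cbind(1, baseline)
  rss <- function(X) {
    beta <- qr.solve(crossprod(X), crossprod(X, post))
    sum((post - X %*% beta)^2)
  }
  r1 <- rss(X1); r0 <- rss(X0)
  df2 <- length(post) - 3
  f <- (r0 - r1) / (r1 / df2)
  list(f = f, p = stats::pf(f, 1, df2, lower.tail = FALSE),
       eta = (r0 - r1) / r0)
}

# Well-separated two-class clouds in 5 dimensions.
separable_data <- function(n_per_class = 28, gap = 6, seed = 42) {
  vimshrv:::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * 5), ncol = 5),
               matrix(rnorm(n_per_class * 5, mean = gap), ncol = 5))
    colnames(X) <- c("sdnn", "pnn50", "ln_vlf", "ln_hf", "ln_ratio")
    list(X = X, y = rep(c("2D", "VR"), each = n_per_class))
  })
}

# Default large-effect cohort shared by several test files.
demo_cohort_cached <- function() {
  fixture("cohort", function() generate_cohort(cohort_effect_params(seed = 11)))
}

# 300-s noise-free single-sinusoid HF tachogram via the generator.
hf_only_rr <- function() {
  fixture("hf_rr", function() {
    generate_rr_series(rr_gen_params(vlf_amp = 0, hf_amp = 10, hf_freq = 0.25,
                                     jitter_sd = 0, duration = 300, seed = 5))
  })
}
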
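test_that("bandpass rejects DC, passes mid-band, attenuates above the corner", {
  cfg <- estimator_config()
  n <- 6000
  t <- (seq_len(n) - 1) / 2000

  dc <- bandpass(signal_from(rep(1, n)), cfg)
  expect_lt(max(abs(dc$amplitude_uV[2001:n])), 0.1)

  mid <- bandpass(signal_from(sin(2 * pi * 100 * t)), cfg)
  a100 <- tone_amplitude(mid$amplitude_uV, 100)
  expect_gt(a100, 0.89)
  expect_lt(a100, 1.12)

  hi <- bandpass(signal_from(sin(2 * pi * 950 * t)), cfg)
  expect_lt(tone_amplitude(hi$amplitude_uV, 950), 0.5)

  # -3 dB at the corners of the designed transfer function
  filt <- signal::butter(1, c(16, 500) / 1000, type = "pass")
  h <- signal::freqz(filt$b, filt$a, Fs = 2000, n = 8192)
  for (fc in c(16, 500)) {
    expect_equal(abs(h$h[which.min(abs(h$f - fc))]), 1 / sqrt(2), tolerance = 0.01)
  }
})

test_that("segmentation splits and reassembles exactly", {
  x <- signal_from(rnorm(240))
  b <- segment_bins(x)
  expect_equal(dim(b), c(120, 2))
  expect_equal(as.numeric(b), x$amplitude_uV)
  one <- segment_bins(signal_from(1:120))
  expect_equal(as.numeric(one), as.numeric(1:120))
  expect_error(segment_bins(rnorm(119)), "not a multiple")
})

test_that("comb filter subtracts the previous bin and annihilates periodic input", {
  bin <- rnorm(120)
  rep10 <- matrix(rep(bin, 10), nrow = 120)
  out <- comb_filter(rep10)
  expect_identical(out[, 1], rep(0, 120))
  for (k in 2:10) expect_identical(out[, k], rep(0, 120))  # bit-exact

  steps <- matrix(rep(c(0, 1, 2, 3), each = 120), nrow = 120)
  expect_equal(unname(comb_filter(steps)[1, ]), c(0, 1, 1, 1))

  single <- matrix(rnorm(120), ncol = 1)
  expect_identical(comb_filter(single)[, 1], rep(0, 120))

  expect_identical(comb_filter(rep10, enabled = FALSE), rep10)
})

test_that("blanking retains exactly the 80 samples outside both windows", {
  cfg <- estimator_config()
  expect_length(retained_samples(cfg), 80)
  bin <- rnorm(120)
  expect_length(apply_blanking(bin, cfg), 80)

  # contamination confined to either window never reaches the retained set
  first <- numeric(120); first[1:20] <- 100      # samples 0..19
  expect_true(all(apply_blanking(first, cfg) == 0))
  at80 <- numeric(120); at80[81] <- 100          # sample 80
  expect_true(all(apply_blanking(at80, cfg) == 0))
  second <- numeric(120); second[71:90] <- 100   # samples 70..89
  expect_true(all(apply_blanking(second, cfg) == 0))
})

test_that("ARV is the mean rectified value over retained samples", {
  idx <- retained_samples()
  expect_equal(arv(rep(3.5, 120), idx), 3.5)
  expect_equal(arv(rep(c(-1, 1), 60), idx), 1)
  # half-normal expectation sigma*sqrt(2/pi), Monte-Carlo over many bins
  set.seed(31)
  a <- replicate(2000, arv(rnorm(120, sd = 4), idx))
  expect_equal(mean(a), 4 * sqrt(2 / pi), tolerance = 0.02)
  expect_error(arv(rnorm(120), integer(0)), "empty")
})

test_that("IIR smoothing has first-order step response with unity DC gain", {
  cfg <- estimator_config(tau = 1)
  n <- ceiling(10 / 0.06)
  y <- smooth_arv(rep(1, n), cfg)
  expect_equal(y[n], 1, tolerance = 1e-3)          # converged after 10 tau
  k1s <- 17                                         # first bin with t >= 1 s
  expect_equal(y[k1s], 1 - exp(-1), tolerance = 0.02)
  expect_equal(y[n] * 7, smooth_arv(rep(7, n), cfg)[n])  # linear

  tiny <- estimator_config(tau = 0.001)
  x <- runif(20)
  expect_equal(smooth_arv(x, tiny), x, tolerance = 1e-10)
})

test_that("composed estimate equals the manual stage chain bit-exactly", {
  cfg <- estimator_config(tau = 0.7)
  set.seed(41)
  trace <- signal_from(rnorm(120 * 40, sd = 20))
  est <- estimate_vmc(trace, cfg)

  cb <- comb_filter(segment_bins(bandpass(trace, cfg)), cfg$comb)
  a_manual <- apply(cb, 2, function(b) arv(b, retained_samples(cfg)))
  expect_identical(est$arv_uV, unname(a_manual))
  expect_identical(est$vmc_uV, smooth_arv(a_manual, cfg))
})

test_that("quasi-stationary stimulation responses are suppressed", {
  # identical response in every bin, no EMG
  zero <- synthesize_emg(constant_envelope(200, 0), seed = 1)
  rec <- inject_responses(zero, stim_schedule(20, 200), template_only_model(), seed = 1)
  est <- estimate_vmc(rec)
  raw_arv <- arv(segment_bins(bandpass(rec))[, 2], retained_samples())
  expect_gt(raw_arv, 0)
  expect_lt(steady(est$vmc_uV), 0.02 * raw_arv)

  # zero trace -> zero estimate
  z <- estimate_vmc(signal_from(numeric(120 * 5)))
  expect_true(all(z$vmc_uV == 0))
})

test_that("clean-EMG estimate matches the analytic half-normal expectation", {
  # Oracle from the designed transfer functions: half-normal mean, x sqrt(2)
  # for the comb difference, x RMS gain of the 16-500 Hz bandpass over the
  # 20-450 Hz EMG band (frequency-domain, independent of the sample path).
  cfg <- estimator_config()
  expected <- 10 * arv_expectation_factor(cfg)
  emg <- synthesize_emg(constant_envelope(500, 10), seed = 8)
  est <- estimate_vmc(emg, cfg)
  expect_equal(steady(est$vmc_uV), expected, tolerance = 0.07)
  # the sqrt(2)-corrected estimate recovers the half-normal band-weighted mean
  g_band <- arv_expectation_factor(cfg) / (sqrt(2) * sqrt(2 / pi))
  expect_equal(steady(est$vmc_uV) / (sqrt(2) * g_band), 10 * sqrt(2 / pi),
               tolerance = 0.07)
})

test_that("doubling the envelope doubles the steady-state estimate", {
  e1 <- estimate_vmc(synthesize_emg(constant_envelope(200, 5), seed = 9))
  e2 <- estimate_vmc(synthesize_emg(constant_envelope(200, 10), seed = 9))
  expect_equal(2 * e1$vmc_uV, e2$vmc_uV, tolerance = 1e-10)
})

test_that("stage-level estimate is bit-exactly immune to blanked contamination", {
  cfg <- estimator_config()
  set.seed(51)
  bins <- matrix(rnorm(120 * 30, sd = 10), nrow = 120)
  contaminated <- bins
  blanked <- setdiff(seq_len(120), retained_samples(cfg))
  contaminated[blanked, ] <- contaminated[blanked, ] + 1e4 * rnorm(length(blanked) * 30)

  chain <- function(b) {
    cb <- comb_filter(b, cfg$comb)
    smooth_arv(apply(cb, 2, function(x) arv(x, retained_samples(cfg))), cfg)
  }
  expect_identical(chain(bins), chain(contaminated))
})

test_that("estimator configuration is validated", {
  expect_error(estimator_config(blank1 = c(0, 80), blank2 = c(70, 90)), "disjoint")
  expect_error(estimator_config(tau = 0))
  expect_error(estimator_config(blank1 = c(-5, 20)))
})
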
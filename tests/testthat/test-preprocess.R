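make_session <- function(f465, f405, fs = 20, onset = 5) {
  n <- length(f465)
  time <- (seq_len(n) - 1) / fs
  ev <- data.frame(trial = 1L, onset = onset, duration = 5, solution = "sucrose")
  class(ev) <- c("event_log", "data.frame")
  photometry_session(time, f465, f405, fs, ev)
}

test_that("an exact affine relation between channels subtracts to zero", {
  set.seed(1)
  f405 <- 50 + cumsum(rnorm(1200, 0, 0.05))
  s <- make_session(2 * f405 + 1, f405)
  fit <- fit_and_subtract_control(s)
  expect_lt(max(abs(fit$subtracted)), 1e-12)
  expect_equal(unname(fit$control_fit_coefficients), c(1, 2), tolerance = 1e-8)
})

test_that("a boxcar transient survives subtraction while the rest stays near zero", {
  f405 <- rep(50, 1500) + sin(seq_len(1500) / 50)  # slow wiggle, both channels
  box <- numeric(1500); box[600:700] <- 5
  s <- make_session(f405 + box, f405)
  fit <- fit_and_subtract_control(s)
  inside <- 620:680
  outside <- c(1:500, 800:1500)
  expect_gt(min(fit$subtracted[inside]), 0.08)   # ~5/51 = 0.098 minus fit leakage
  expect_lt(max(abs(fit$subtracted[outside])), 0.02)
})

test_that("a constant control channel is a degenerate fit", {
  expect_error(fit_and_subtract_control(make_session(rnorm(300) + 50, rep(10, 300))),
               "zero variance")
})

test_that("bandpass matches the analytic two-pass Butterworth response", {
  for (fs in c(40, 100)) {
    # DC is rejected
    t <- seq(0, 200, by = 1 / fs)
    y <- bandpass_filter(rep(3.7, length(t)), fs)
    expect_lt(max(abs(y)), 1e-10)
    # mid-passband sinusoid within 5% of unit amplitude
    g <- measure_gain(0.75, fs)
    expect_equal(g, 1, tolerance = 0.05)
    expect_equal(g, bandpass_gain(0.75, fs), tolerance = 0.01)
    # stopband
    expect_lt(measure_gain(20 * fs / 100, fs), 1e-3)
    # transition-band point agrees with the closed form
    expect_equal(measure_gain(0.1, fs), bandpass_gain(0.1, fs), tolerance = 0.02)
  }
})

test_that("filtering is zero-phase: passband sinusoid peaks at lag 0", {
  fs <- 40
  t <- seq(0, 300, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * t)
  y <- bandpass_filter(x, fs)
  cc <- ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_length(y, length(x))
})

test_that("invalid cutoffs are rejected", {
  expect_error(bandpass_filter(rnorm(100), 4, low = 0.05, high = 2.25), "Nyquist")
  expect_error(bandpass_filter(rnorm(100), 40, low = 3, high = 2), "Nyquist")
  expect_error(bandpass_filter(rnorm(100), 40, low = 0, high = 2), "Nyquist")
})

test_that("z-scoring uses the whole-session population SD", {
  z <- zscore_normalize(c(2, 4, 6))
  expect_equal(z$z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z$session_sd, sqrt(8 / 3), tolerance = 1e-12)

  set.seed(2)
  x <- rnorm(500)
  z2 <- zscore_normalize(x)
  expect_equal(mean(z2$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z2$z^2)), 1, tolerance = 1e-12)
  # affine invariance
  expect_equal(zscore_normalize(3 * x + 7)$z, z2$z, tolerance = 1e-10)
  expect_error(zscore_normalize(rep(1, 10)), "zero variance")
  expect_error(zscore_normalize(1), "2 samples")
})

test_that("whole-pipeline z output is invariant to joint channel scaling", {
  ev <- small_events(4)
  sim <- simulate_photometry_session(ev, quiet_params())
  s <- sim$session
  pt1 <- preprocess_session(s)
  s2 <- photometry_session(s$time, 2.5 * s$f465, 2.5 * s$f405,
                           s$sampling_rate, s$events, s$metadata)
  pt2 <- preprocess_session(s2)
  expect_equal(pt1$z, pt2$z, tolerance = 1e-8)
  # and the z invariant holds to 1e-6 relative
  expect_lt(abs(mean(pt1$z)), 1e-6)
  expect_equal(sqrt(mean((pt1$z - mean(pt1$z))^2)), 1, tolerance = 1e-6)
})

test_that("trial alignment cuts the stated window with onset at or before the event", {
  fs <- 20
  ev <- small_events(3)
  n <- (max(ev$onset) + 20) * fs
  tensor <- align_trials(rep(0.7, n), ev, pre = 5, post = 10, sampling_rate = fs)
  expect_equal(nrow(tensor), 3)
  expect_equal(ncol(tensor), 15 * fs)
  expect_true(all(tensor == 0.7))
  rel <- attr(tensor, "rel_time")
  expect_equal(rel[1], -5)
  expect_lte(rel[5 * fs + 1], 0)  # onset column maps at or before the event
})

test_that("30 events give 30 rows and out-of-bounds trials are dropped with a warning", {
  fs <- 20
  ev <- make_event_schedule(30, iti_min = 6, iti_max = 8, lead_in = 10, seed = 3)
  n <- round((max(ev$onset) + 6) * fs)
  z <- rnorm(n)
  expect_warning(tensor <- align_trials(z, ev, pre = 5, post = 10, sampling_rate = fs),
                 "excluded")
  expect_lt(nrow(tensor), 30)   # last trial's 10-s post window does not fit
  n2 <- round((max(ev$onset) + 20) * fs)
  tensor2 <- align_trials(rnorm(n2), ev, pre = 5, post = 10, sampling_rate = fs)
  expect_equal(nrow(tensor2), 30)
  ev1 <- make_event_schedule(1, lead_in = 2, seed = 1)
  expect_error(suppressWarnings(
    align_trials(rnorm(100), ev1, pre = 5, post = 10, sampling_rate = 10)),
    "all trials excluded")
})

test_that("infusion-window trial statistics average the stated half-open window", {
  fs <- 10
  ev <- small_events(2)
  n <- (max(ev$onset) + 20) * fs
  z <- rep(1, n)
  tensor <- align_trials(z, ev, sampling_rate = fs)
  st <- infusion_mean_zscore(tensor)
  expect_equal(st$mean_z, c(1, 1))
  expect_equal(attr(st, "session_mean_z"), 1)
  # alternating +1/-1 rows average to zero at the session level
  tensor2 <- tensor
  tensor2[1, ] <- 1; tensor2[2, ] <- -1
  expect_equal(attr(infusion_mean_zscore(tensor2), "session_mean_z"), 0)
  expect_error(infusion_mean_zscore(tensor, window = c(0, 0)), "no samples")
})

test_that("noise-free recovery: trial mean z is monotone in true amplitude", {
  # study-spaced trials: the 0.05 Hz highpass undershoot of one transient
  # has decayed before the next infusion window opens
  ev <- make_event_schedule(20, iti_min = 35, iti_max = 55, seed = 5)
  p <- quiet_params(amplitude_jitter_sd = 0.5)
  p$seed <- 8
  sim <- simulate_photometry_session(ev, p)
  pt <- preprocess_session(sim$session)
  st <- infusion_mean_zscore(align_trials(pt))
  expect_gt(cor(sim$truth$amplitudes, st$mean_z, method = "spearman"), 0.99)
})

test_that("transient onsets are recovered to within one sample (matched filter)", {
  ev <- small_events(5)
  p <- quiet_params()
  sim <- simulate_photometry_session(ev, p)
  pt <- preprocess_session(sim$session)
  tensor <- align_trials(pt, pre = 5, post = 10)
  m <- colMeans(tensor)
  rel <- attr(tensor, "rel_time")
  fs <- attr(tensor, "sampling_rate")
  kern <- ifelse(rel >= 0, exp(-pmax(rel, 0) / p$transient_decay) -
                   exp(-pmax(rel, 0) / p$transient_rise), 0)
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    idx <- seq_along(m)
    sh <- idx + l
    ok <- sh >= 1 & sh <= length(m)
    sum(m[sh[ok]] * kern[idx[ok]])
  }, numeric(1))
  expect_lte(abs(lags[which.max(cc)]), 1)
})
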
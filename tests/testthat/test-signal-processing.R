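# Filter response properties are checked away from the trace ends, where the
# finite-length forward-backward filter necessarily has boundary transients.

test_that("low-pass filter passes DC exactly and attenuates above cutoff", {
  const <- torque_trace(rep(50, 5000), sampling_rate = 1000)
  expect_equal(lowpass_filter(const)$samples, rep(50, 5000), tolerance = 1e-9)

  t <- (0:4999) / 1000
  # one decade above cutoff a 4th-order response is down by >= 40 dB;
  # analog magnitude oracle: 1/sqrt(1 + (f/fc)^(2*4)) = 1e-4 at f = 10 fc
  s100 <- torque_trace(sin(2 * pi * 100 * t), sampling_rate = 1000)
  mid <- 500:4500
  expect_lt(max(abs(lowpass_filter(s100)$samples[mid])), 0.01)

  s1 <- torque_trace(sin(2 * pi * 1 * t), sampling_rate = 1000)
  f1 <- lowpass_filter(s1)$samples
  # passband: amplitude within 2% ...
  expect_equal(max(f1[mid]), 1, tolerance = 0.02)
  # ... and zero phase: no lag maximises the cross-correlation
  lags <- -20:20
  xc <- vapply(lags, function(l) {
    sum(s1$samples[mid] * f1[mid + l])
  }, numeric(1))
  expect_equal(lags[which.max(xc)], 0)
})

test_that("filtering leaves the trigger channel untouched and validates input", {
  sim <- simulate_trial(test_params(), 0.5, seed = 3)
  f <- lowpass_filter(sim$trace)
  expect_identical(f$trigger, sim$trace$trigger)
  expect_error(lowpass_filter(sim$trace, cutoff = 600), "Nyquist")
  expect_error(lowpass_filter(torque_trace(rep(1, 10)), cutoff = 10), "too short")
})

test_that("filtering is idempotent for signals band-limited below cutoff/2", {
  t <- (0:4999) / 1000
  s <- torque_trace(30 + 2 * sin(2 * pi * 2 * t), sampling_rate = 1000)
  once <- lowpass_filter(s)
  twice <- lowpass_filter(once)
  mid <- 500:4500
  expect_equal(twice$samples[mid], once$samples[mid], tolerance = 1e-3)
})

test_that("burst onset detection follows the trigger run", {
  tr <- flat_burst_trace(onset = 2001)
  expect_equal(detect_burst_onset(tr), 2001)

  none <- torque_trace(rep(30, 1000), sampling_rate = 1000)
  expect_identical(detect_burst_onset(none), NA_integer_)

  early <- torque_trace(rep(30, 1000), c(rep(0L, 50), rep(1L, 100), rep(0L, 850)),
                        sampling_rate = 1000)
  expect_error(detect_burst_onset(early), "insufficient pre-burst data")
})

test_that("F_vol is the mean over the 100 ms before onset", {
  tr <- flat_burst_trace(level = 30, onset = 2001)
  expect_equal(extract_fvol(tr, 2001), 30)

  alt <- tr
  alt$samples[1901:2000] <- rep(c(29, 31), 50)
  expect_equal(extract_fvol(alt, 2001), 30)

  expect_error(extract_fvol(tr, 50), "insufficient pre-burst data")
})

test_that("F_stim is the window maximum and dominates the window mean", {
  tr <- flat_burst_trace(level = 30, onset = 2001)
  tr$samples[2100] <- 45
  expect_equal(extract_fstim(tr, 2001), 45)
  win <- tr$samples[2001:2500]
  expect_gte(extract_fstim(tr, 2001), max(win))
  expect_gte(extract_fstim(tr, 2001), mean(win))
  expect_error(extract_fstim(tr, 3900), "too short after onset")
})

test_that("extraction recovers generator ground truth exactly at zero noise", {
  for (k in c(0.6, 1)) {
    sim <- simulate_trial(test_params(efficacy_k = k, noise_sd = 0), 0.5, seed = 1)
    onset <- detect_burst_onset(sim$trace)
    expect_lt(abs(extract_fvol(sim$trace, onset) - sim$truth$f_vol), 1e-6)
    expect_lt(abs(extract_fstim(sim$trace, onset) - sim$truth$f_stim_peak), 1e-6)
  }
})

test_that("extraction error shrinks with the noise level", {
  err_at <- function(sigma) {
    errs <- vapply(1:8, function(s) {
      sim <- simulate_trial(test_params(noise_sd = sigma), 0.5, seed = 100 + s)
      tm <- summarize_trial(sim$trace)
      abs(tm$f_vol - sim$truth$f_vol)
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(0.05), err_at(0.5))
})

test_that("trial summarisation composes extraction and quality control", {
  # clean simulated trial at study noise levels: valid, accurate F_vol
  sim <- simulate_trial(test_params(efficacy_k = 1), 0.5, seed = 21)
  tm <- summarize_trial(sim$trace)
  expect_true(tm$valid)
  expect_length(tm$flags, 0)
  expect_equal(tm$f_vol, sim$truth$f_vol, tolerance = 0.1)
  # the 150-ms burst closes >= 95% of the gap to MFGA (first-order response
  # oracle: 1 - exp(-150/40) = 0.976)
  gap <- sim$truth$f_stim_target - sim$truth$f_vol
  expect_gte(tm$f_stim, sim$truth$f_vol + 0.95 * gap)

  # zero stimulator efficacy: no augmentation, measured central drive ~ 1
  sim0 <- simulate_trial(test_params(efficacy_k = 0), 0.5, seed = 22)
  tm0 <- summarize_trial(sim0$trace)
  expect_equal(tm0$f_stim / tm0$f_vol, 1, tolerance = 0.02)

  # stimulation on a rising ramp: nonsteady, invalid
  ramp <- simulate_trial(test_params(noise_sd = 0), 1, tau_rise = 1.2,
                         enforce_plateau = FALSE, seed = 23)
  tmr <- summarize_trial(ramp$trace)
  expect_in("nonsteady", tmr$flags)
  expect_false(tmr$valid)
  expect_gt(abs(tmr$pre_burst_slope), 2)

  # no burst recorded
  none <- torque_trace(rep(30, 2000), sampling_rate = 1000)
  tmn <- summarize_trial(none)
  expect_identical(tmn$flags, "no_burst")
  expect_false(tmn$valid)
})
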
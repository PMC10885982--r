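test_that("twitch recruitment saturates at the participant's pulse width", {
  pp <- test_params(noise_sd = 0)
  pp$pw_sat <- 400
  ramp <- simulate_twitch_ramp(pp)
  expect_equal(nrow(ramp), 12)
  below <- ramp$twitch_peak[ramp$pulse_width <= 400]
  above <- ramp$twitch_peak[ramp$pulse_width >= 400]
  expect_true(all(diff(below) > 0))
  expect_equal(diff(above), rep(0, length(above) - 1))
  expect_error(simulate_twitch_ramp(pp, widths = c(40, 100)), "\\[50, 600\\]")
})

test_that("pulse-duration selection takes the first width reaching the peak", {
  ramp <- data.frame(pulse_width = seq(50, 250, by = 50),
                     twitch_peak = c(1, 2, 3, 3, 3))
  expect_equal(select_pulse_duration(ramp), 150)
  inc <- data.frame(pulse_width = seq(50, 600, by = 50),
                    twitch_peak = seq_len(12))
  expect_equal(select_pulse_duration(inc), 600)
  flat <- data.frame(pulse_width = seq(50, 600, by = 50),
                     twitch_peak = rep(2, 12))
  expect_equal(select_pulse_duration(flat), 50)
  expect_error(select_pulse_duration(data.frame()), "empty")
})

test_that("selected widths span the physiological saturation range", {
  for (sat in c(350, 600)) {
    pp <- test_params(noise_sd = 0)
    pp$pw_sat <- sat
    ramp <- simulate_twitch_ramp(pp)
    expect_equal(select_pulse_duration(ramp), sat)
  }
})

test_that("simulated trials encode the burst and their own ground truth", {
  sim <- simulate_trial(test_params(noise_sd = 0), 0.5, seed = 1)
  # trigger marks 150 ms starting at the burst time
  expect_equal(sum(sim$trace$trigger), 150)
  expect_equal(detect_burst_onset(sim$trace), 3001)
  # measured central drive ground truth: F_vol / (F_vol + k (MFGA - F_vol))
  expect_equal(sim$truth$measured_cd, 30 / (30 + 0.8 * 30))
  expect_equal(sim$truth$true_cd, 0.5)

  # k = 1, no noise: the burst closes >= 95% of the gap to MFGA
  full <- simulate_trial(test_params(efficacy_k = 1, noise_sd = 0), 0.5, seed = 2)
  onset <- detect_burst_onset(full$trace)
  fstim <- extract_fstim(full$trace, onset)
  expect_gte(fstim, 30 + 0.95 * (60 - 30))
  expect_equal(fstim, 30 + (60 - 30) * (1 - exp(-0.15 / 0.04)), tolerance = 0.05)

  # k = 0: no augmentation beyond the plateau
  none <- simulate_trial(test_params(efficacy_k = 0, noise_sd = 0), 0.5, seed = 3)
  onset0 <- detect_burst_onset(none$trace)
  expect_equal(extract_fstim(none$trace, onset0), 30, tolerance = 1e-9)

  expect_error(simulate_trial(test_params(), 1.5), "\\(0, 1\\]")
  expect_error(simulate_trial(test_params(), 0.5, burst_time_s = 1),
               "plateau before")
})

test_that("every generated trace passes validation and round-trips", {
  for (s in 1:3) {
    sim <- simulate_trial(test_params(noise_sd = 0.3), 0.5, seed = s)
    path <- withr::local_tempfile(fileext = ".csv")
    write_trace(sim$trace, path)
    back <- read_trace(path)
    expect_equal(back$samples, sim$trace$samples, tolerance = 1e-6)
    expect_identical(back$trigger, sim$trace$trigger)
  }
})

test_that("incomplete stimulator efficacy overestimates central drive", {
  set.seed(20)
  for (i in 1:20) {
    k <- runif(1, 0.05, 0.95)
    eff <- runif(1, 0.2, 0.9)
    pp <- test_params(efficacy_k = k, true_cd_max = 0.95, noise_sd = 0)
    sim <- simulate_trial(pp, eff, seed = i)
    expect_gt(sim$truth$measured_cd, sim$truth$true_cd)
  }
  # equality holds only at full voluntary activation (F_vol = MFGA)
  pp1 <- test_params(efficacy_k = 0.7, true_cd_max = 1, noise_sd = 0)
  sim1 <- simulate_trial(pp1, 1, seed = 1)
  expect_equal(sim1$truth$measured_cd, sim1$truth$true_cd)
})

test_that("calibration on simulated data closes the measured-true loop", {
  # noiseless constant-efficacy cohort: fitting then adjusting fresh
  # measurements recovers true central drive within 3 points of central drive
  k <- 0.8
  efforts <- seq(0.1, 1, length.out = 25)
  truths <- t(vapply(efforts, function(e) {
    sim <- simulate_trial(test_params(efficacy_k = k, true_cd_max = 1,
                                      noise_sd = 0), e, seed = 1)
    c(sim$truth$measured_cd, sim$truth$true_cd)
  }, numeric(2)))
  m <- fit_adjustment(truths[, 1], truths[, 2])
  grid_m <- seq(0.2, 0.95, length.out = 100)
  rmse <- sqrt(mean((apply_adjustment(m, grid_m) - constant_k_true(grid_m, k))^2))
  expect_lte(rmse, 0.03)
})

test_that("the calibration experiment produces seven tests per device", {
  cfg <- exp1_config(n_participants = 3)
  e1 <- simulate_experiment1(cfg, seed = 4)
  counts <- table(e1$trials$participant, e1$trials$device)
  expect_true(all(counts == 7))
  expect_equal(nrow(e1$pairs), 3 * 7)
  expect_true(all(e1$pairs$measured >= e1$pairs$true - 1e-9))
})

test_that("identical devices give perfect agreement", {
  cfg <- exp1_config(n_participants = 6, device_b_offset_mean = 0,
                     device_b_offset_sd = 0, noise_sd = 0, effort_sd = 0)
  e1 <- simulate_experiment1(cfg, seed = 5)
  expect_equal(icc_2_1(cbind(e1$mvc$f_vol.dynamometer, e1$mvc$f_vol.cedrs))$icc, 1)
})

test_that("the between-device offset surfaces as the Bland-Altman bias", {
  biases <- vapply(1:30, function(s) {
    e1 <- simulate_experiment1(exp1_config(), seed = 800 + s)
    bland_altman(e1$mvc$f_vol.dynamometer, e1$mvc$f_vol.cedrs)$bias
  }, numeric(1))
  # configured offset 3.7 with SD 6.64 over n = 16: SE of the mean-of-means
  # over 30 seeds is 6.64/sqrt(16*30) ~ 0.30
  expect_equal(mean(biases), 3.7, tolerance = 0.9)
})

test_that("clinical cohort group means track the configured distributions", {
  cohort <- simulate_cohort_exp2(exp2_config(), seed = 6)
  for (g in c("neurotypical", "paretic", "non_paretic")) {
    cfg <- exp2_config()$groups[[g]]
    got <- cohort$limbs$mfga[cohort$limbs$group == g]
    se <- cfg$mfga[2] / sqrt(length(got))
    expect_lt(abs(mean(got) - cfg$mfga[1]), 2.5 * se + 1e-9)
  }
  expect_equal(nrow(cohort$limbs), 26 * 2 + 16)
  expect_equal(sum(cohort$trials$group == "paretic"), 26 * 3)
})

test_that("injected QC violations reduce usable trials at the configured rate", {
  q <- 0.3
  cohort <- simulate_cohort_exp2(exp2_config(qc_violation_rate = q), seed = 7)
  n <- nrow(cohort$trials)
  clean <- sum(cohort$trials$clean)
  # binomial oracle: clean count within 4 SD of (1-q) n
  expect_lt(abs(clean - (1 - q) * n), 4 * sqrt(n * q * (1 - q)))
  # aggregates only use clean trials
  agg_n <- sum(cohort$aggregates$n_valid)
  expect_equal(agg_n, clean)
})

test_that("walk outcomes correlate with paretic central drive as configured", {
  rs <- vapply(1:10, function(s) {
    cohort <- simulate_cohort_exp2(exp2_config(), seed = 900 + s)
    par <- cohort$aggregates[cohort$aggregates$group == "paretic", ]
    merged <- merge(par, cohort$walk, by = "participant")
    pearson_r(merged$adjusted_cd, merged$total_distance)$r
  }, numeric(1))
  expect_equal(mean(rs), 0.65, tolerance = 0.15)
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_cohort_exp2(exp2_config(), seed = 42)
  b <- simulate_cohort_exp2(exp2_config(), seed = 42)
  expect_identical(a$trials, b$trials)
  expect_identical(a$walk, b$walk)
  c2 <- simulate_cohort_exp2(exp2_config(), seed = 43)
  expect_false(identical(a$trials$f_vol, c2$trials$f_vol))
})
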
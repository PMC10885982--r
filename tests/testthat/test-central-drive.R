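test_that("measured central drive is the F_vol/F_stim ratio, capped at one", {
  expect_equal(measured_cd(30, 60)$cd, 0.5)
  r <- measured_cd(60, 60)
  expect_equal(r$cd, 1)
  expect_false(r$capped)
  r2 <- measured_cd(61, 60)
  expect_equal(r2$cd, 1)
  expect_true(r2$capped)
  expect_error(measured_cd(30, 0), "positive")
})

test_that("true central drive is the F_vol/MFGA ratio", {
  expect_equal(true_cd(0, 80), 0)
  expect_equal(true_cd(40, 80), 0.5)
  expect_error(true_cd(40, -1), "positive")
  sim <- simulate_trial(test_params(true_cd_max = 0.7, noise_sd = 0), 1, seed = 2)
  onset <- detect_burst_onset(sim$trace)
  expect_equal(true_cd(extract_fvol(sim$trace, onset), 60), 0.7, tolerance = 1e-6)
})

test_that("origin-constrained cubic fit recovers noiseless relationships exactly", {
  x <- seq(0.1, 1, by = 0.1)
  ident <- fit_adjustment(x, x)
  expect_equal(c(ident$b1, ident$b2, ident$b3), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(ident$r_squared, 1, tolerance = 1e-9)

  m <- fit_adjustment(x, calib_poly(x))
  expect_equal(c(m$b3, m$b2, m$b1), c(0.798, -0.772, 0.868), tolerance = 1e-9)
  expect_equal(m$rmse, 0, tolerance = 1e-6)
})

test_that("fit recovers arbitrary monotone origin cubics from noiseless data", {
  set.seed(7)
  x <- seq(0.05, 1, length.out = 40)
  found <- 0
  while (found < 10) {
    b <- runif(3, -1, 1)
    deriv <- 3 * b[3] * x^2 + 2 * b[2] * x + b[1]
    if (any(deriv <= 0)) next
    found <- found + 1
    y <- b[3] * x^3 + b[2] * x^2 + b[1] * x
    m <- fit_adjustment(x, y)
    expect_equal(c(m$b1, m$b2, m$b3), b, tolerance = 1e-8)
  }
})

test_that("coefficient confidence intervals achieve nominal coverage", {
  hits <- c(b1 = 0, b2 = 0, b3 = 0)
  for (s in 1:100) {
    set.seed(5000 + s)
    x <- runif(112, 0.1, 1)
    y <- calib_poly(x) + rnorm(112, 0, 0.03)
    m <- fit_adjustment(x, y)
    ci <- m$coef_ci
    truth <- c(b1 = 0.868, b2 = -0.772, b3 = 0.798)
    hits <- hits + (truth >= ci[, 1] & truth <= ci[, 2])
  }
  expect_gte(min(hits), 90)
})

test_that("fit rejects degenerate designs", {
  expect_error(fit_adjustment(c(0.5, 0.5), c(0.4, 0.4)), "at least 4")
  expect_error(fit_adjustment(rep(0.5, 6), rep(0.4, 6)), "rank-deficient|span")
})

test_that("the adjustment maps through the cubic and respects the origin", {
  m <- reference_adjustment_model()
  expect_identical(apply_adjustment(m, 0), 0)
  expect_equal(apply_adjustment(m, 0.5), 0.34075)
  expect_equal(apply_adjustment(m, 1), 0.894)
  expect_equal(round(100 * apply_adjustment(m, 1)), 89)
  expect_error(apply_adjustment(m, 1.2), "\\[0, 1\\]")
  expect_error(apply_adjustment(m, -0.1), "\\[0, 1\\]")
  # out-of-range models are clipped with a warning
  bad <- adjustment_model(b1 = 1.5, b2 = 0, b3 = 0)
  expect_warning(y <- apply_adjustment(bad, 0.9), "clipping")
  expect_equal(y, 1)
})

test_that("the reference model is strictly increasing over its domain", {
  expect_true(is_monotone_increasing(reference_adjustment_model(), grid_n = 1000))
})

test_that("inverting the adjustment is the right inverse of applying it", {
  m <- reference_adjustment_model()
  a <- c(0.05, 0.3, 0.5, 0.85)
  expect_equal(apply_adjustment(m, invert_adjustment(m, a)), a, tolerance = 1e-9)
  expect_error(invert_adjustment(m, 0.95), "outside model range")
})

test_that("LOOCV is exact on noiseless data and matches brute-force refits", {
  pid <- rep(1:4, each = 5)
  x <- rep(seq(0.15, 0.95, by = 0.2), 4)
  y <- calib_poly(x)
  cv <- loocv_adjustment(x, y, pid)
  expect_equal(cv$rmse_mean, 0, tolerance = 1e-8)
  expect_equal(cv$rmse_sd, 0, tolerance = 1e-8)

  # shift one participant: their fold error is large and inflates the SD;
  # oracle folds computed here with independent lm refits
  y2 <- y
  y2[pid == 3] <- y2[pid == 3] + 0.2
  cv2 <- loocv_adjustment(x, y2, pid)
  oracle <- vapply(1:4, function(p) {
    fit <- lm(y2[pid != p] ~ 0 + x[pid != p] + I(x[pid != p]^2) + I(x[pid != p]^3))
    xh <- x[pid == p]
    pred <- cbind(xh, xh^2, xh^3) %*% coef(fit)
    sqrt(mean((y2[pid == p] - pred)^2)) * 100
  }, numeric(1))
  expect_equal(unname(cv2$folds$rmse[order(cv2$folds$participant)]), oracle,
               tolerance = 1e-9)
  expect_gt(cv2$rmse_sd, 0)
  expect_gt(max(oracle), 10)
  expect_error(loocv_adjustment(x[pid < 3], y[pid < 3], pid[pid < 3]),
               "at least 3 participants")
})

test_that("LOOCV fold errors are stable across a homogeneous noisy cohort", {
  # with 7 held-out points per fold the relative SD of a fold RMSE is about
  # 1/sqrt(2*7) ~ 0.27 even under perfectly homogeneous noise, so stability
  # is asserted as a mean ratio below 0.35 over seeds
  ratios <- vapply(1:20, function(s) {
    set.seed(6000 + s)
    pid <- rep(1:16, each = 7)
    x <- runif(112, 0.1, 1)
    y <- calib_poly(x) + rnorm(112, 0, 0.03)
    cv <- loocv_adjustment(x, y, pid)
    cv$rmse_sd / cv$rmse_mean
  }, numeric(1))
  expect_lt(mean(ratios), 0.35)
})

test_that("fitted cubic matches the constant-efficacy closed form", {
  k <- 0.75
  x <- seq(0.05, 1, length.out = 60)
  m <- fit_adjustment(x, constant_k_true(x, k))
  grid <- seq(0.2, 0.95, length.out = 200)
  pred <- apply_adjustment(m, grid)
  rmse <- sqrt(mean((pred - constant_k_true(grid, k))^2))
  expect_lte(rmse, 0.03)
})

test_that("Breusch-Pagan statistic behaves at its extremes and detects power", {
  # equal-magnitude residuals: auxiliary regression explains nothing
  res <- rep(c(0.1, -0.1), 10)
  bp <- breusch_pagan(res, seq(0.1, 2, length.out = 20))
  expect_equal(bp$statistic, 0, tolerance = 1e-12)
  expect_equal(bp$p_value, 1)

  # variance proportional to the regressor: rejected most of the time
  rejections <- vapply(1:100, function(s) {
    set.seed(7000 + s)
    x <- runif(200, 0.1, 1)
    r <- rnorm(200, 0, 0.2 * x)
    breusch_pagan(r, x)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.8)

  expect_error(breusch_pagan(c(1, 2, 3), rep(1, 3)), "constant")
})

test_that("Breusch-Pagan agrees with the studentized lmtest implementation", {
  skip_if_not_installed("lmtest")
  set.seed(31)
  x <- runif(50, 0.1, 1)
  y <- calib_poly(x) + rnorm(50, 0, 0.05)
  fit <- lm(y ~ 0 + x + I(x^2) + I(x^3))
  ours <- breusch_pagan(residuals(fit), x)
  theirs <- lmtest::bptest(fit, ~ x)
  expect_equal(ours$statistic, unname(theirs$statistic), tolerance = 1e-8)
  expect_equal(ours$p_value, unname(theirs$p.value), tolerance = 1e-8)
})
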
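# Shared fixtures and independent oracles used across the suite.

# The published device calibration polynomial, written out independently of
# the package's model object so tests compare two separate code paths.
calib_poly <- function(x) 0.798 * x^3 - 0.772 * x^2 + 0.868 * x

# Constant-efficacy relation between measured (m) and true central drive for
# stimulator efficacy k: true = k m / (1 - (1 - k) m).
constant_k_true <- function(m, k) k * m / (1 - (1 - k) * m)

# A flat trace with a rectangular burst trigger, for window arithmetic tests.
flat_burst_trace <- function(level = 30, n = 4000, onset = 2001,
                             burst_len = 150, fs = 1000) {
  trig <- integer(n)
  trig[onset:(onset + burst_len - 1L)] <- 1L
  torque_trace(rep(level, n), trig, sampling_rate = fs)
}

# Default neurotypical generator parameters used in trial-level tests.
test_params <- function(mfga = 60, true_cd_max = 1, efficacy_k = 0.8,
                        noise_sd = 0.2, ...) {
  participant_params("T01", "neurotypical", mfga = mfga,
                     true_cd_max = true_cd_max, efficacy_k = efficacy_k,
                     noise_sd = noise_sd, ...)
}

# ICC(2,1) recomputed from the aov() two-way mean squares -- an independent
# route to the same decomposition the package computes by direct sums.
icc21_aov_oracle <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Consistency-form single-measure ICC(3,1), for the absolute-vs-consistency
# comparison.
icc31_aov_oracle <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  df <- data.frame(
    y = as.vector(mat),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- tab["subject", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse)
}
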
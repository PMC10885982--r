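# Trial-validity rules: a burst-superimposition trial is usable only when
# stimulation was delivered on a steady voluntary plateau. The variance and
# slope rules automate what is otherwise a visual steady-state judgement;
# the submaximal rule guards against stimulation landing after effort has
# dropped off a within-trial peak.

#' Quality-control configuration
#'
#' Thresholds for the per-trial validity rules. Defaults: pre-burst variance
#' above 0.1 (ft-lbs)^2 over the 100-ms F_vol window flags `high_variance`;
#' an absolute pre-burst OLS slope above 2 ft-lbs/s flags `nonsteady` (a
#' deterministic surrogate for the visual rising/falling judgement,
#' conservative relative to plateau noise at 10-Hz bandwidth); F_vol below
#' 90% of the within-trial pre-burst peak flags `submax_90`; an MVC attempt
#' is accepted when F_vol reaches at least 95% of MFGA, with up to 3 attempts.
#'
#' @param variance_threshold Pre-burst variance threshold, (ft-lbs)^2.
#' @param steady_slope_threshold Absolute pre-burst slope threshold, ft-lbs/s.
#' @param submax_ratio Minimum F_vol as a fraction of the pre-burst peak.
#' @param mvc_acceptance_ratio Minimum F_vol as a fraction of MFGA for an
#'   accepted MVC attempt.
#' @param max_mvc_attempts Maximum MVC attempts before dismissal.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(variance_threshold = 0.1, steady_slope_threshold = 2.0,
                      submax_ratio = 0.90, mvc_acceptance_ratio = 0.95,
                      max_mvc_attempts = 3L) {
  stopifnot(
    variance_threshold > 0, steady_slope_threshold > 0,
    submax_ratio > 0, submax_ratio <= 1,
    mvc_acceptance_ratio > 0, mvc_acceptance_ratio <= 1,
    max_mvc_attempts >= 1
  )
  structure(
    list(variance_threshold = variance_threshold,
         steady_slope_threshold = steady_slope_threshold,
         submax_ratio = submax_ratio,
         mvc_acceptance_ratio = mvc_acceptance_ratio,
         max_mvc_attempts = as.integer(max_mvc_attempts)),
    class = "qc_config"
  )
}

#' High-variance flag
#'
#' `TRUE` iff the sample variance (n-1 denominator) of the pre-burst window
#' strictly exceeds the configured threshold.
#'
#' @param window Numeric vector: the 100-ms pre-burst torque window.
#' @param qc A [qc_config()].
#' @return Logical flag.
#' @export
variance_flag <- function(window, qc = qc_config()) {
  if (length(window) < 2L) stop("window too short for a variance", call. = FALSE)
  stats::var(window) > qc$variance_threshold
}

#' Non-steady-state flag
#'
#' `TRUE` (trial non-steady) iff the absolute ordinary-least-squares slope of
#' torque against time over the pre-burst window strictly exceeds the
#' configured threshold. A trial at exactly the threshold passes.
#'
#' @inheritParams variance_flag
#' @param sampling_rate Sampling rate of the window in Hz.
#' @return Logical flag.
#' @export
steady_state_flag <- function(window, qc = qc_config(), sampling_rate = 1000) {
  if (length(window) < 2L) stop("window too short for a slope", call. = FALSE)
  # small epsilon keeps the strict boundary deterministic under float error
  abs(ols_slope(window, sampling_rate)) > qc$steady_slope_threshold + 1e-9
}

#' Submaximal-effort flag
#'
#' `TRUE` iff F_vol is strictly below `submax_ratio` of the within-trial peak
#' torque reached before the burst (i.e., effort peaked and dropped off
#' before stimulation arrived).
#'
#' @param f_vol Pre-burst voluntary torque (ft-lbs).
#' @param pre_burst_peak Peak torque before the burst (ft-lbs), must be > 0.
#' @param qc A [qc_config()].
#' @return Logical flag.
#' @export
submax_flag <- function(f_vol, pre_burst_peak, qc = qc_config()) {
  if (pre_burst_peak <= 0) stop("pre_burst_peak must be positive", call. = FALSE)
  f_vol < qc$submax_ratio * pre_burst_peak
}

#' MVC acceptance rule
#'
#' An MVC attempt is accepted when the voluntary torque reaches at least
#' `mvc_acceptance_ratio` of the participant's MFGA (boundary inclusive).
#' Participants unable to reach the target within `max_mvc_attempts` attempts
#' cannot receive a trustworthy MFGA estimate.
#'
#' @param f_vol Voluntary torque produced in the attempt (ft-lbs).
#' @param mfga Maximum force-generating ability (ft-lbs), must be > 0.
#' @param qc A [qc_config()].
#' @return Logical: `TRUE` when the attempt is accepted.
#' @export
mvc_acceptance <- function(f_vol, mfga, qc = qc_config()) {
  if (mfga <= 0) stop("mfga must be positive", call. = FALSE)
  f_vol >= qc$mvc_acceptance_ratio * mfga
}

#' Aggregate a participant-limb's trials
#'
#' F_vol and F_stim are averaged across the valid (unflagged) trials only.
#' A participant-limb with zero valid trials is a reportable state, not an
#' error: means are `NA` and the limb is excluded downstream.
#'
#' @param trials List of `trial_measurement` objects (see [summarize_trial()]).
#' @param limb Optional limb label carried into the result.
#' @return A list with `limb`, `f_vol_mean`, `f_stim_mean`, `n_valid` and
#'   `n_total`.
#' @export
aggregate_participant <- function(trials, limb = NA_character_) {
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_measurement")))
  valid <- vapply(trials, function(t) isTRUE(t$valid), logical(1))
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    f_vol_mean <- NA_real_
    f_stim_mean <- NA_real_
  } else {
    f_vol_mean <- mean(vapply(trials[valid], `[[`, numeric(1), "f_vol"))
    f_stim_mean <- mean(vapply(trials[valid], `[[`, numeric(1), "f_stim"))
  }
  list(limb = limb, f_vol_mean = f_vol_mean, f_stim_mean = f_stim_mean,
       n_valid = n_valid, n_total = length(trials))
}
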
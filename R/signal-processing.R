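# Torque-trace filtering and extraction of the two forces a burst-
# superimposition trial yields: the voluntary plateau torque F_vol (mean over
# the 100 ms before the burst) and the stimulation-elicited torque F_stim
# (peak after burst onset).

#' Low-pass filter a torque trace
#'
#' Butterworth low-pass filtering with an effective fourth-order magnitude
#' response at a 10 Hz cutoff by default. The default zero-phase mode applies
#' a second-order design forward and backward (squaring its magnitude
#' response), so filtered features are not shifted in time relative to the
#' trigger channel -- essential because F_vol/F_stim windows are defined
#' relative to burst onset. A single-pass causal filter of the full order is
#' available via `zero_phase = FALSE`.
#'
#' Edge effects are controlled by short odd-reflection padding (three times
#' the filter length) combined with steady-state initialisation of each
#' pass, so a constant signal passes through exactly and boundary
#' transients stay local to the trace ends.
#'
#' @param trace A [torque_trace()].
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @param order Effective filter order (even; default 4).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return A filtered copy of `trace`; the trigger channel is untouched.
#' @export
lowpass_filter <- function(trace, cutoff = 10, order = 4, zero_phase = TRUE) {
  stopifnot(inherits(trace, "torque_trace"))
  fs <- trace$sampling_rate
  nyq <- fs / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("cutoff must be positive and below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  x <- trace$samples
  n <- length(x)
  if (n <= 3 * order) stop("trace too short to filter", call. = FALSE)
  if (zero_phase) {
    if (order %% 2 != 0) stop("zero-phase filtering requires an even order", call. = FALSE)
    design_order <- order / 2
  } else {
    design_order <- order
  }
  bf <- signal::butter(design_order, cutoff / nyq, type = "low")
  # DC gain is 1 by design; starting each pass from the steady state of its
  # first sample removes the zero-initial-condition startup transient.
  dc <- sum(bf$b) / sum(bf$a)
  one_pass <- function(v) {
    as.numeric(signal::filter(bf, v - v[1])) + v[1] * dc
  }
  pad <- min(n - 1L, 3L * max(length(bf$a), length(bf$b)))
  xa <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- one_pass(xa)
  if (zero_phase) {
    y <- rev(one_pass(rev(y)))
  }
  out <- trace
  out$samples <- y[(pad + 1L):(pad + n)]
  out
}

#' Locate the burst onset in a trace
#'
#' The burst onset is the first sample of the single contiguous run of 1s in
#' the stimulation-trigger channel. Returns `NA` when no burst was recorded
#' (the caller flags the trial `no_burst`); errs when the onset falls inside
#' the first 100 ms, where the voluntary-torque window would be undefined.
#'
#' @param trace A [torque_trace()].
#' @return 1-based sample index of the first burst sample, or `NA_integer_`
#'   when the trigger channel is all zero.
#' @export
detect_burst_onset <- function(trace) {
  stopifnot(inherits(trace, "torque_trace"))
  runs <- trigger_runs(trace$trigger)
  if (nrow(runs) == 0L) return(NA_integer_)
  if (nrow(runs) > 1L) {
    stop("multiple trigger runs: trace must contain exactly one contiguous burst",
         call. = FALSE)
  }
  onset <- runs$start[1]
  if (onset - 1L < round(0.1 * trace$sampling_rate)) {
    stop("insufficient pre-burst data: burst onset within the first 100 ms",
         call. = FALSE)
  }
  onset
}

#' Voluntary torque before the burst
#'
#' F_vol: the arithmetic mean of the torque over the 100 ms immediately
#' preceding burst onset (half-open window, the onset sample excluded).
#'
#' @param trace A (typically filtered) [torque_trace()].
#' @param onset 1-based burst-onset sample index, as returned by
#'   [detect_burst_onset()].
#' @param window_s Window length in seconds (default 0.1).
#' @return Mean pre-burst torque in ft-lbs.
#' @export
extract_fvol <- function(trace, onset, window_s = 0.1) {
  stopifnot(inherits(trace, "torque_trace"))
  w <- round(window_s * trace$sampling_rate)
  if (is.na(onset) || onset - 1L < w) {
    stop("insufficient pre-burst data: need ", w, " samples before onset",
         call. = FALSE)
  }
  mean(trace$samples[(onset - w):(onset - 1L)])
}

#' Stimulation-elicited torque after the burst
#'
#' F_stim: the peak torque in a window following burst onset. The burst lasts
#' 150 ms and the elicited torque peaks shortly after, so the default 500-ms
#' search window comfortably brackets the peak; the window length is recorded
#' by [summarize_trial()] alongside the measurement.
#'
#' @inheritParams extract_fvol
#' @param post_window_s Search-window length in seconds from burst onset.
#' @return Peak post-onset torque in ft-lbs.
#' @export
extract_fstim <- function(trace, onset, post_window_s = 0.5) {
  stopifnot(inherits(trace, "torque_trace"))
  wp <- round(post_window_s * trace$sampling_rate)
  if (is.na(onset)) stop("no burst onset supplied", call. = FALSE)
  if (length(trace$samples) < onset + wp - 1L) {
    stop("trace too short after onset: need ", wp, " samples", call. = FALSE)
  }
  max(trace$samples[onset:(onset + wp - 1L)])
}

#' Process one burst-superimposition trial
#'
#' Runs the full per-trial chain: low-pass filter, burst-onset detection,
#' F_vol/F_stim extraction, and the quality-control rules of [qc_config()]
#' (pre-burst variance, steady-state slope, and -- optionally -- the
#' submaximal-effort check against the within-trial pre-burst peak). The
#' result is deterministic for a fixed trace and configuration.
#'
#' Because the zero-phase filter is non-causal, the stimulation response
#' would smear backwards in time and contaminate the pre-burst window if the
#' whole trace were filtered in one piece. The voluntary segment (everything
#' before burst onset) is therefore filtered in isolation and supplies
#' F_vol, the pre-burst variance/slope/peak and the QC verdicts, while
#' F_stim is taken from the fully filtered trace.
#'
#' @param trace A raw [torque_trace()].
#' @param qc A [qc_config()].
#' @param cutoff,order,zero_phase Filter settings, see [lowpass_filter()].
#' @param post_window_s F_stim search window, see [extract_fstim()].
#' @param filter Apply the low-pass filter first (default `TRUE`).
#' @param check_submax Apply the submaximal-effort flag (default `TRUE`;
#'   the rule was introduced for post-stroke testing but is safe generally).
#' @return An object of class `trial_measurement`: `f_vol`, `f_stim`,
#'   `pre_burst_variance`, `pre_burst_slope`, `pre_burst_peak`, `flags`
#'   (character subset of `high_variance`, `nonsteady`, `submax_90`,
#'   `no_burst`), and `valid` (`TRUE` iff no flags).
#' @export
summarize_trial <- function(trace, qc = qc_config(), cutoff = 10, order = 4,
                            zero_phase = TRUE, post_window_s = 0.5,
                            filter = TRUE, check_submax = TRUE) {
  stopifnot(inherits(trace, "torque_trace"), inherits(qc, "qc_config"))
  onset <- detect_burst_onset(trace)
  if (is.na(onset)) {
    return(trial_measurement(
      f_vol = NA_real_, f_stim = NA_real_, pre_burst_variance = NA_real_,
      pre_burst_slope = NA_real_, pre_burst_peak = NA_real_,
      flags = "no_burst", onset = NA_integer_,
      post_window_s = post_window_s, meta = trace$meta
    ))
  }
  fs <- trace$sampling_rate
  w <- round(0.1 * fs)
  pre <- trace
  pre$samples <- trace$samples[1:(onset - 1L)]
  pre$trigger <- trace$trigger[1:(onset - 1L)]
  if (filter) {
    pre <- lowpass_filter(pre, cutoff = cutoff, order = order,
                          zero_phase = zero_phase)
  }
  filtered <- if (filter) {
    lowpass_filter(trace, cutoff = cutoff, order = order, zero_phase = zero_phase)
  } else {
    trace
  }
  win <- pre$samples[(onset - w):(onset - 1L)]
  f_vol <- max(0, mean(win))
  f_stim <- max(0, extract_fstim(filtered, onset, post_window_s))
  pre_var <- stats::var(win)
  pre_slope <- ols_slope(win, fs)
  pre_peak <- max(pre$samples)
  flags <- character(0)
  if (variance_flag(win, qc)) flags <- c(flags, "high_variance")
  if (steady_state_flag(win, qc, sampling_rate = fs)) flags <- c(flags, "nonsteady")
  if (check_submax && pre_peak > 0 && submax_flag(f_vol, pre_peak, qc)) {
    flags <- c(flags, "submax_90")
  }
  trial_measurement(
    f_vol = f_vol, f_stim = f_stim, pre_burst_variance = pre_var,
    pre_burst_slope = pre_slope, pre_burst_peak = pre_peak,
    flags = flags, onset = onset, post_window_s = post_window_s,
    meta = trace$meta
  )
}

trial_measurement <- function(f_vol, f_stim, pre_burst_variance, pre_burst_slope,
                              pre_burst_peak, flags, onset, post_window_s,
                              meta = list()) {
  structure(
    list(f_vol = f_vol, f_stim = f_stim,
         pre_burst_variance = pre_burst_variance,
         pre_burst_slope = pre_burst_slope,
         pre_burst_peak = pre_burst_peak,
         flags = flags, valid = length(flags) == 0L,
         onset = onset, post_window_s = post_window_s, meta = meta),
    class = "trial_measurement"
  )
}

#' @export
print.trial_measurement <- function(x, ...) {
  cat("<trial_measurement>\n")
  cat(sprintf("  F_vol: %s ft-lbs   F_stim: %s ft-lbs\n",
              format(x$f_vol, digits = 4), format(x$f_stim, digits = 4)))
  cat(sprintf("  pre-burst variance: %s  slope: %s ft-lbs/s\n",
              format(x$pre_burst_variance, digits = 3),
              format(x$pre_burst_slope, digits = 3)))
  if (x$valid) cat("  valid (no flags)\n")
  else cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# OLS slope of a window against time (ft-lbs/s).
ols_slope <- function(window, sampling_rate) {
  t <- (seq_along(window) - 1) / sampling_rate
  stats::cov(t, window) / stats::var(t)
}
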
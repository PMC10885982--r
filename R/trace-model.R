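# Torque-trace data model and file I/O.
#
# A trace is a uniformly sampled plantarflexion torque record (ft-lbs) with a
# binary stimulation-trigger channel marking the superimposed burst. All
# window conventions downstream assume the first sample of the single trigger
# run is the burst onset.

#' Construct a torque trace
#'
#' Bundles a uniformly sampled torque record with its stimulation-trigger
#' channel and acquisition metadata, validating the invariants every
#' downstream stage relies on: equal channel lengths, finite torque, a binary
#' trigger containing at most one contiguous run of ones (the burst), and a
#' positive sampling rate.
#'
#' @param samples Numeric vector of torque samples (ft-lbs).
#' @param trigger Integer vector of 0/1 stimulation-trigger flags, same length
#'   as `samples`. Defaults to all zeros (no burst).
#' @param sampling_rate Sampling rate in Hz (typically 1000).
#' @param meta Named list of trial metadata (participant id, device label,
#'   limb, trial label, target effort fraction). Free-form; carried along.
#' @return An object of class `torque_trace`: a list with elements `samples`,
#'   `trigger`, `sampling_rate` and `meta`.
#' @examples
#' tr <- torque_trace(rep(30, 1000), sampling_rate = 1000)
#' tr
#' @export
torque_trace <- function(samples, trigger = NULL, sampling_rate = 1000, meta = list()) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n == 0L) {
    stop("empty trace: at least one torque sample is required", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("non-finite torque value in trace", call. = FALSE)
  }
  if (is.null(trigger)) trigger <- integer(n)
  if (length(trigger) != n) {
    stop("trigger channel length (", length(trigger),
         ") does not match sample count (", n, ")", call. = FALSE)
  }
  trigger <- as.integer(trigger)
  if (anyNA(trigger) || !all(trigger %in% c(0L, 1L))) {
    stop("trigger values must be 0 or 1", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive finite scalar (Hz)", call. = FALSE)
  }
  runs <- trigger_runs(trigger)
  if (nrow(runs) > 1L) {
    stop("multiple trigger runs: trace must contain exactly one contiguous burst",
         call. = FALSE)
  }
  structure(
    list(samples = samples, trigger = trigger,
         sampling_rate = as.numeric(sampling_rate), meta = meta),
    class = "torque_trace"
  )
}

#' @export
print.torque_trace <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<torque_trace: %d samples @ %g Hz (%.3f s)>\n",
              n, x$sampling_rate, n / x$sampling_rate))
  runs <- trigger_runs(x$trigger)
  if (nrow(runs) == 1L) {
    cat(sprintf("  burst: samples %d-%d (onset %.3f s)\n",
                runs$start, runs$end, (runs$start - 1) / x$sampling_rate))
  } else {
    cat("  burst: none\n")
  }
  cat(sprintf("  torque range: [%.2f, %.2f] ft-lbs\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

# Contiguous runs of 1s in a 0/1 vector; data.frame of 1-based start/end.
trigger_runs <- function(trigger) {
  r <- rle(as.integer(trigger))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep], end = ends[keep])
}

#' Read a torque trace from CSV
#'
#' Reads the package's interchange trace format: a comma-separated, headered
#' file with columns `time_s`, `torque_ftlb` and `stim_trigger`. The sampling
#' rate is inferred from the median time step and every step is checked for
#' uniformity within 1% of the median.
#'
#' @param path Path to the CSV file.
#' @param meta Optional metadata list attached to the returned trace.
#' @return A validated [torque_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, meta = list()) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  required <- c("time_s", "torque_ftlb", "stim_trigger")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in trace file: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) < 2L) stop("trace file must contain at least two samples", call. = FALSE)
  dt <- diff(df$time_s)
  med <- stats::median(dt)
  if (med <= 0) stop("non-increasing time stamps in trace file", call. = FALSE)
  if (any(abs(dt - med) > 0.01 * med)) {
    stop("non-uniform sampling: time steps deviate more than 1% from the median",
         call. = FALSE)
  }
  torque_trace(df$torque_ftlb, df$stim_trigger, sampling_rate = 1 / med, meta = meta)
}

#' Write a torque trace to CSV
#'
#' Writes the interchange format read by [read_trace()]: header
#' `time_s,torque_ftlb,stim_trigger`, time starting at 0 in steps of
#' `1/sampling_rate`. Round-tripping preserves samples to better than
#' 1e-6 ft-lbs.
#'
#' @param trace A [torque_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "torque_trace"))
  n <- length(trace$samples)
  df <- data.frame(
    time_s = (seq_len(n) - 1L) / trace$sampling_rate,
    torque_ftlb = trace$samples,
    stim_trigger = trace$trigger
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Exact ft-lb -> N m conversion factor.
.FTLB_TO_NM <- 1.3558179483314004

#' Convert torque units
#'
#' The pipeline's native unit is ft-lbs (the unit in which device torque is
#' reported and all thresholds are expressed); conversion to N m is provided
#' for interoperability and is never applied implicitly.
#'
#' @param value Numeric torque value(s).
#' @param from,to Unit names: `"ft-lb"` (synonyms `"ftlb"`, `"ft-lbs"`) or
#'   `"Nm"` (synonyms `"N m"`, `"newton-metre"`).
#' @return Converted numeric value(s). 1 ft-lb = 1.3558179483314004 N m.
#' @examples
#' convert_torque(1, "ft-lb", "Nm")
#' @export
convert_torque <- function(value, from, to) {
  norm <- function(u) {
    key <- gsub("[^a-z]", "", tolower(u))
    if (key %in% c("ftlb", "ftlbs", "footpound", "footpounds")) return("ftlb")
    if (key %in% c("nm", "newtonmetre", "newtonmeter")) return("nm")
    stop("unknown torque unit: ", u, call. = FALSE)
  }
  from <- norm(from)
  to <- norm(to)
  if (from == to) return(value)
  if (from == "ftlb") value * .FTLB_TO_NM else value / .FTLB_TO_NM
}

#' Burst stimulation parameters
#'
#' The supramaximal stimulation burst delivered during a central drive test:
#' a 150-ms, 100-Hz, 150-mA train (15 biphasic pulses), with a
#' participant-specific pulse width selected by the twitch ramp protocol
#' (see [select_pulse_duration()]).
#'
#' @param duration_ms Burst duration in milliseconds.
#' @param frequency_hz Pulse frequency in Hz.
#' @param amplitude_ma Pulse amplitude in mA.
#' @param pulse_width_us Pulse width in microseconds, in \[50, 600\].
#' @return An object of class `burst_spec` with the parameters plus the
#'   implied pulse count `n_pulses = round(duration_ms * frequency_hz / 1000)`.
#' @examples
#' burst_spec()$n_pulses  # 15
#' @export
burst_spec <- function(duration_ms = 150, frequency_hz = 100,
                       amplitude_ma = 150, pulse_width_us = 500) {
  stopifnot(duration_ms > 0, frequency_hz > 0, amplitude_ma > 0)
  if (pulse_width_us < 50 || pulse_width_us > 600) {
    stop("pulse_width_us must lie in [50, 600]", call. = FALSE)
  }
  structure(
    list(duration_ms = duration_ms, frequency_hz = frequency_hz,
         amplitude_ma = amplitude_ma, pulse_width_us = pulse_width_us,
         n_pulses = round(duration_ms * frequency_hz / 1000)),
    class = "burst_spec"
  )
}

#' Six-minute walk test record
#'
#' Stores per-minute distances, the total distance, and the distance-induced
#' percent change in walking speed between the first and sixth minutes
#' (see [pct_delta_6mwt()]; positive = sped up).
#'
#' @param minute_distances Numeric vector of 6 nonnegative per-minute
#'   distances (m); the first must be positive.
#' @return An object of class `walk_test` with elements `minute_distances`,
#'   `total_distance` and `pct_delta_speed`.
#' @export
walk_test <- function(minute_distances) {
  pct <- pct_delta_6mwt(minute_distances)
  structure(
    list(minute_distances = as.numeric(minute_distances),
         total_distance = sum(minute_distances),
         pct_delta_speed = pct),
    class = "walk_test"
  )
}
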
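# Synthetic torque traces, twitch ramps, participants and cohorts.
#
# The forward model is deliberately simple: a voluntary plateau reached by a
# smooth ramp, a first-order burst response that closes a fraction k of the
# gap between the plateau and MFGA (k < 1 is the incomplete stimulator
# efficacy that makes measured central drive overestimate true central
# drive), saturating-linear twitch recruitment with pulse width, additive
# Gaussian noise, and a per-device gain/offset. Every generated object
# carries its ground truth so downstream extraction, calibration and cohort
# statistics can be checked against known values.

#' Simulated participant parameters
#'
#' @param id Participant identifier.
#' @param group `"neurotypical"` or `"post-stroke"`.
#' @param limb `"dominant"`, `"paretic"`, `"non-paretic"` or `"neurotypical"`.
#' @param mfga Maximum force-generating ability, ft-lbs (> 0).
#' @param true_cd_max Volitional ceiling: maximum attainable F_vol as a
#'   fraction of MFGA, in (0, 1\].
#' @param efficacy_k Stimulator efficacy: the fraction of the F_vol-to-MFGA
#'   gap the burst elicits, in (0, 1\]. Values below 1 produce the
#'   overestimation of central drive the adjustment equation corrects.
#' @param pw_sat Twitch saturation pulse width, microseconds, in \[350, 600\].
#' @param noise_sd Additive torque noise SD, ft-lbs.
#' @param device_offset,device_gain Per-device affine measurement error.
#' @return An object of class `participant_params`.
#' @export
participant_params <- function(id, group = c("neurotypical", "post-stroke"),
                               limb = "dominant", mfga, true_cd_max = 0.95,
                               efficacy_k = 0.8, pw_sat = 450, noise_sd = 0.2,
                               device_offset = 0, device_gain = 1) {
  group <- match.arg(group)
  stopifnot(mfga > 0,
            true_cd_max > 0, true_cd_max <= 1,
            efficacy_k >= 0, efficacy_k <= 1,
            pw_sat >= 350, pw_sat <= 600,
            noise_sd >= 0, device_gain > 0)
  structure(
    list(id = id, group = group, limb = limb, mfga = mfga,
         true_cd_max = true_cd_max, efficacy_k = efficacy_k,
         pw_sat = pw_sat, noise_sd = noise_sd,
         device_offset = device_offset, device_gain = device_gain),
    class = "participant_params"
  )
}

# Evaluate code with a temporarily fixed RNG state (restores the caller's).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-unit seed split, kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483629L)
  for (i in seq_along(idx)) {
    s <- (s * 48271 + idx[i] * 16807 + 1) %% 2147483629
  }
  as.integer(s) + 1L
}

#' Simulate a twitch pulse-duration ramp
#'
#' Resting twitch responses to single pulses of progressively increasing
#' width. Twitch peak torque follows a saturating-linear recruitment curve:
#' proportional to pulse width up to the participant's saturation width
#' `pw_sat`, constant beyond it, with peak amplitude `twitch_fraction` of
#' MFGA, plus additive noise.
#'
#' @param params A [participant_params()].
#' @param widths Pulse widths in microseconds, ascending within \[50, 600\]
#'   (default 50 to 600 in 50-us steps: 12 stimulation levels).
#' @param twitch_fraction Peak twitch torque as a fraction of MFGA.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return A data.frame with columns `pulse_width` and `twitch_peak`.
#' @seealso [select_pulse_duration()]
#' @export
simulate_twitch_ramp <- function(params, widths = seq(50, 600, by = 50),
                                 twitch_fraction = 0.12, seed = NULL) {
  stopifnot(inherits(params, "participant_params"))
  if (any(widths < 50) || any(widths > 600)) {
    stop("pulse widths must lie in [50, 600] us", call. = FALSE)
  }
  if (is.unsorted(widths, strictly = TRUE)) {
    stop("pulse widths must be strictly ascending", call. = FALSE)
  }
  with_seed(seed, {
    t_max <- twitch_fraction * params$mfga
    peaks <- t_max * pmin(1, widths / params$pw_sat) +
      stats::rnorm(length(widths), 0, params$noise_sd)
    data.frame(pulse_width = widths, twitch_peak = peaks)
  })
}

#' Select the stimulation pulse duration from a twitch ramp
#'
#' The minimum pulse width whose twitch peak reaches at least
#' `(1 - rel_tolerance)` of the largest twitch response in the ramp --
#' i.e. the smallest width that already elicits the (near-)maximal twitch.
#'
#' @param ramp A data.frame with columns `pulse_width` and `twitch_peak`
#'   (see [simulate_twitch_ramp()]).
#' @param rel_tolerance Relative tolerance below the maximum (default 0).
#' @return Selected pulse width (microseconds).
#' @export
select_pulse_duration <- function(ramp, rel_tolerance = 0) {
  if (NROW(ramp) == 0L) stop("empty twitch ramp", call. = FALSE)
  stopifnot(all(c("pulse_width", "twitch_peak") %in% names(ramp)))
  mx <- max(ramp$twitch_peak)
  ramp$pulse_width[which(ramp$twitch_peak >= (1 - rel_tolerance) * mx)[1]]
}

#' Simulate one burst-superimposition trial
#'
#' Generates a torque trace at 1 kHz: the voluntary torque rises along a
#' raised-cosine ramp that reaches the plateau `F_vol = effort_fraction *
#' true_cd_max * MFGA` exactly at `4 * tau_rise` seconds; the stimulation
#' burst (trigger = 1 for its duration) drives torque first-order (time
#' constant `tau_burst`) toward `F_vol + k (MFGA - F_vol)` and the elicited
#' torque decays back (time constant `tau_decay`) after the burst ends. The
#' device applies gain and offset, and Gaussian noise is added.
#'
#' The ground-truth record carries both the asymptotic stimulated-force
#' target `F_vol + k (MFGA - F_vol)` (which defines the ground-truth
#' measured central drive `F_vol / (F_vol + k (MFGA - F_vol))`) and the
#' attainable noiseless peak on the sampling grid (`f_stim_peak`), which is
#' what noise-free extraction recovers: a 150-ms burst with `tau_burst` =
#' 40 ms closes 97.6% of the gap.
#'
#' @param params A [participant_params()].
#' @param effort_fraction Target effort as a fraction of the volitional
#'   ceiling, in (0, 1\].
#' @param burst A [burst_spec()].
#' @param duration_s Trial length in seconds.
#' @param burst_time_s Burst-onset time in seconds; must leave a full
#'   plateau of at least 100 ms before and 500 ms of trace after the burst.
#' @param tau_rise Voluntary ramp time scale (s); plateau at `4 * tau_rise`.
#' @param tau_burst,tau_decay Burst response rise/decay time constants (s).
#' @param device Device label stored in the trace metadata.
#' @param enforce_plateau Require the voluntary ramp to have reached its
#'   plateau at least 100 ms before the burst (default). Set to `FALSE` to
#'   generate protocol-violating trials where stimulation lands on a rising
#'   ramp (used for quality-control testing).
#' @param seed Optional RNG seed.
#' @return A list with `trace` (a [torque_trace()]) and `truth` (named list:
#'   `f_vol`, `f_stim_target`, `f_stim_peak` -- all in device units --,
#'   `measured_cd`, `true_cd`, `effort_fraction`, `efficacy_k`).
#' @export
simulate_trial <- function(params, effort_fraction, burst = burst_spec(),
                           duration_s = 6, burst_time_s = 3,
                           tau_rise = 0.5, tau_burst = 0.04, tau_decay = 0.15,
                           device = "A", enforce_plateau = TRUE, seed = NULL) {
  stopifnot(inherits(params, "participant_params"), inherits(burst, "burst_spec"))
  if (effort_fraction <= 0 || effort_fraction > 1) {
    stop("effort_fraction must lie in (0, 1]", call. = FALSE)
  }
  burst_dur <- burst$duration_ms / 1000
  ramp_end <- 4 * tau_rise
  if (burst_time_s < 0.2) {
    stop("burst_time_s must leave at least 100 ms of trace before the burst",
         call. = FALSE)
  }
  if (enforce_plateau && burst_time_s < ramp_end + 0.1) {
    stop("burst_time_s must leave at least 100 ms of plateau before the burst",
         call. = FALSE)
  }
  if (duration_s < burst_time_s + burst_dur + 0.5) {
    stop("duration_s must extend at least 500 ms beyond the burst", call. = FALSE)
  }
  fs <- 1000
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  f_vol <- effort_fraction * params$true_cd_max * params$mfga
  gap <- params$efficacy_k * (params$mfga - f_vol)
  rise <- 0.5 * (1 - cos(pi * pmin(t, ramp_end) / ramp_end))
  onset_idx <- round(burst_time_s * fs) + 1L
  burst_len <- round(burst_dur * fs)
  in_burst <- seq_len(n) >= onset_idx & seq_len(n) < onset_idx + burst_len
  post <- seq_len(n) >= onset_idx + burst_len
  rel <- t - (onset_idx - 1L) / fs
  resp <- numeric(n)
  resp[in_burst] <- gap * (1 - exp(-rel[in_burst] / tau_burst))
  peak_end <- gap * (1 - exp(-burst_dur / tau_burst))
  resp[post] <- peak_end * exp(-(rel[post] - burst_dur) / tau_decay)
  clean <- params$device_gain * (f_vol * rise + resp) + params$device_offset
  samples <- with_seed(seed, clean + stats::rnorm(n, 0, params$noise_sd))
  trigger <- as.integer(in_burst)
  onset <- which(in_burst)[1]
  wp <- round(0.5 * fs)
  truth <- list(
    f_vol = params$device_gain * f_vol + params$device_offset,
    f_stim_target = params$device_gain * (f_vol + gap) + params$device_offset,
    f_stim_peak = max(clean[onset:(onset + wp - 1L)]),
    measured_cd = if (f_vol + gap > 0) f_vol / (f_vol + gap) else NA_real_,
    true_cd = effort_fraction * params$true_cd_max,
    effort_fraction = effort_fraction,
    efficacy_k = params$efficacy_k
  )
  meta <- list(id = params$id, group = params$group, limb = params$limb,
               device = device, effort_fraction = effort_fraction)
  list(trace = torque_trace(samples, trigger, fs, meta = meta), truth = truth)
}

#' Configuration for the two-device calibration experiment
#'
#' Defaults emulate the calibration study conditions: 16 neurotypical
#' participants, each completing seven central drive tests (one MVC plus two
#' at each of 25/50/75% of MFGA) on both a stationary dynamometer and the
#' portable device, the portable device differing by a per-participant
#' offset drawn from N(3.7, 6.64^2) ft-lbs. MFGA is drawn from the
#' neurotypical distribution N(76.47, 13.59^2) ft-lbs; stimulator efficacy
#' is Uniform(0.6, 0.9) per participant so the measured-to-true central
#' drive mapping is nonlinear across the cohort.
#'
#' @param n_participants Number of participants.
#' @param mfga_mean,mfga_sd MFGA distribution, ft-lbs.
#' @param true_cd_max_mean,true_cd_max_sd Volitional-ceiling distribution.
#' @param efficacy_range Range of the per-participant stimulator efficacy k.
#' @param device_b_offset_mean,device_b_offset_sd Between-device offset
#'   distribution, ft-lbs.
#' @param noise_sd Trace noise SD, ft-lbs.
#' @param effort_sd Relative SD of trial-to-trial effort around its target.
#' @param efforts Submaximal target effort fractions.
#' @param trials_per_effort Trials at each submaximal effort per device.
#' @param traces Also generate full torque traces (slower; default `FALSE`
#'   returns analytic ground truth only).
#' @return A list of class `exp1_config`.
#' @export
exp1_config <- function(n_participants = 16,
                        mfga_mean = 76.47, mfga_sd = 13.59,
                        true_cd_max_mean = 0.95, true_cd_max_sd = 0.03,
                        efficacy_range = c(0.6, 0.9),
                        device_b_offset_mean = 3.7, device_b_offset_sd = 6.64,
                        noise_sd = 0.2, effort_sd = 0.03,
                        efforts = c(0.25, 0.50, 0.75), trials_per_effort = 2,
                        traces = FALSE) {
  stopifnot(n_participants >= 0, mfga_sd >= 0, true_cd_max_sd >= 0,
            length(efficacy_range) == 2, efficacy_range[1] > 0,
            efficacy_range[2] <= 1, noise_sd >= 0, effort_sd >= 0,
            trials_per_effort >= 1)
  structure(as.list(environment()), class = "exp1_config")
}

#' Simulate the two-device calibration experiment
#'
#' Per participant and device: one maximal and `2 x 3` submaximal burst-
#' superimposition tests (seven in total). Returns per-trial ground truth,
#' the MVC torque per device (for agreement statistics), and the
#' (measured, true) central drive pairs from the portable device used to fit
#' the adjustment equation.
#'
#' @param config An [exp1_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `exp1_cohort`: `participants` (data.frame of
#'   generator parameters), `trials` (per-trial ground truth and noisy
#'   measurements), `mvc` (per-device MVC torque), `pairs` (calibration
#'   pairs from the portable device), `traces` (list of [torque_trace()]
#'   objects or `NULL`), `config`, `seed`.
#' @export
simulate_experiment1 <- function(config = exp1_config(), seed = 1) {
  stopifnot(inherits(config, "exp1_config"))
  participants <- with_seed(derive_seed(seed, 1), {
    n <- config$n_participants
    data.frame(
      participant = if (n > 0) paste0("P", sprintf("%02d", seq_len(n))) else character(0),
      mfga = pmax(10, stats::rnorm(n, config$mfga_mean, config$mfga_sd)),
      true_cd_max = pmin(1, pmax(0.6, stats::rnorm(n, config$true_cd_max_mean,
                                                   config$true_cd_max_sd))),
      efficacy_k = stats::runif(n, config$efficacy_range[1], config$efficacy_range[2]),
      pw_sat = stats::runif(n, 350, 600),
      offset_b = stats::rnorm(n, config$device_b_offset_mean, config$device_b_offset_sd)
    )
  })
  efforts <- c(1, rep(config$efforts, each = config$trials_per_effort))
  devices <- c("dynamometer", "cedrs")
  rows <- list()
  traces <- if (config$traces) list() else NULL
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    for (d in seq_along(devices)) {
      offset <- if (devices[d] == "cedrs") p$offset_b else 0
      pp <- participant_params(
        id = p$participant, group = "neurotypical", limb = "dominant",
        mfga = p$mfga, true_cd_max = p$true_cd_max, efficacy_k = p$efficacy_k,
        pw_sat = p$pw_sat, noise_sd = config$noise_sd, device_offset = offset
      )
      for (j in seq_along(efforts)) {
        trial_seed <- derive_seed(seed, i, d, j)
        row <- with_seed(trial_seed, {
          eff <- min(1, max(0.05, efforts[j] * (1 + stats::rnorm(1, 0, config$effort_sd))))
          f_vol_p <- eff * p$true_cd_max * p$mfga
          gap <- p$efficacy_k * (p$mfga - f_vol_p)
          # measurement-level noise: F_vol averages ~100 samples, F_stim is a peak
          f_vol_m <- offset + f_vol_p + stats::rnorm(1, 0, config$noise_sd / 10)
          f_stim_m <- offset + f_vol_p + gap * (1 - exp(-0.15 / 0.04)) +
            stats::rnorm(1, 0, config$noise_sd)
          data.frame(
            participant = p$participant, device = devices[d],
            target_effort = efforts[j], effort = eff, is_mvc = j == 1L,
            f_vol = f_vol_m, f_stim = f_stim_m,
            measured_cd_truth = f_vol_p / (f_vol_p + gap),
            true_cd_truth = eff * p$true_cd_max
          )
        })
        rows[[length(rows) + 1L]] <- row
        if (config$traces) {
          pp_eff <- pp
          sim <- simulate_trial(pp_eff, effort_fraction = row$effort,
                                device = devices[d],
                                seed = derive_seed(seed, i, d, j, 7))
          traces[[length(traces) + 1L]] <- sim$trace
        }
      }
    }
  }
  trials <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(0), device = character(0))
  mvc <- if (nrow(trials)) {
    mv <- trials[trials$is_mvc, c("participant", "device", "f_vol")]
    stats::reshape(mv, idvar = "participant", timevar = "device", direction = "wide")
  } else {
    data.frame(participant = character(0))
  }
  pairs <- if (nrow(trials)) {
    ced <- trials[trials$device == "cedrs", ]
    md <- measured_cd(ced$f_vol, ced$f_stim)
    data.frame(participant = ced$participant, measured = md$cd,
               capped = md$capped, true = ced$true_cd_truth)
  } else {
    data.frame(participant = character(0), measured = numeric(0), true = numeric(0))
  }
  structure(
    list(participants = participants, trials = trials, mvc = mvc,
         pairs = pairs, traces = traces, config = config, seed = seed),
    class = "exp1_cohort"
  )
}

#' Configuration for the clinical cohort simulation
#'
#' Defaults emulate the clinical study conditions: 26 post-stroke
#' participants contributing a paretic and a non-paretic limb (3 MVC
#' burst-superimposition trials each) plus 16 neurotypical limbs (one MVC
#' test each), with per-group MFGA and adjusted central drive drawn from the
#' cohort distributions (ft-lbs; central drive as a fraction):
#' neurotypical MFGA 76.47 +/- 13.59 and central drive 0.8873 +/- 0.0171,
#' paretic 41.07 +/- 13.41 and 0.5039 +/- 0.2144, non-paretic 56.54 +/-
#' 15.71 and 0.7012 +/- 0.2025. Six-minute-walk-test outcomes are generated
#' to correlate with paretic central drive at `r_target` (default 0.65).
#'
#' @param n_stroke,n_neurotypical Group sizes.
#' @param groups Per-group `mfga = c(mean, sd)` and `cd = c(mean, sd)`
#'   (adjusted central drive, fraction) lists; override to move the cohort.
#' @param trials_stroke,trials_neurotypical MVC trials per limb.
#' @param efficacy_range Range of per-limb stimulator efficacy.
#' @param effort_sd Relative trial-to-trial F_vol variability.
#' @param fstim_noise_sd Additive F_stim measurement noise, ft-lbs.
#' @param qc_violation_rate Probability a trial is generated in violation of
#'   the steady-state rule (ground-truth labelled).
#' @param r_target Target correlation between paretic adjusted central drive
#'   and both walk outcomes.
#' @param walk_total_mean,walk_total_sd 6MWT total distance distribution (m).
#' @param walk_delta_mean,walk_delta_sd Distance-induced percent speed
#'   change distribution.
#' @param model Adjustment model used to translate target adjusted central
#'   drive into generator parameters (and by the pipeline to adjust).
#' @param traces Also generate full torque traces (default `FALSE`).
#' @return A list of class `exp2_config`.
#' @export
exp2_config <- function(n_stroke = 26, n_neurotypical = 16,
                        groups = list(
                          neurotypical = list(mfga = c(76.47, 13.59), cd = c(0.8873, 0.0171)),
                          paretic = list(mfga = c(41.07, 13.41), cd = c(0.5039, 0.2144)),
                          non_paretic = list(mfga = c(56.54, 15.71), cd = c(0.7012, 0.2025))
                        ),
                        trials_stroke = 3, trials_neurotypical = 1,
                        efficacy_range = c(0.6, 0.9), effort_sd = 0.03,
                        fstim_noise_sd = 0.5, qc_violation_rate = 0,
                        r_target = 0.65,
                        walk_total_mean = 321.09, walk_total_sd = 103.34,
                        walk_delta_mean = -5, walk_delta_sd = 15,
                        model = reference_adjustment_model(),
                        traces = FALSE) {
  stopifnot(n_stroke >= 0, n_neurotypical >= 0,
            all(c("neurotypical", "paretic", "non_paretic") %in% names(groups)),
            trials_stroke >= 1, trials_neurotypical >= 1,
            qc_violation_rate >= 0, qc_violation_rate <= 1,
            abs(r_target) <= 1, inherits(model, "adjustment_model"))
  structure(as.list(environment()), class = "exp2_config")
}

# Draw one limb's generator parameters from its group distribution: target
# adjusted central drive is inverted through the model and the constant-k
# map to a volitional ceiling.
draw_limb <- function(group_cfg, model, efficacy_range) {
  ceiling_adj <- min(1, eval_adjustment(model, 1)) - 1e-4
  mfga <- max(5, stats::rnorm(1, group_cfg$mfga[1], group_cfg$mfga[2]))
  adj <- min(ceiling_adj, max(0.02, stats::rnorm(1, group_cfg$cd[1], group_cfg$cd[2])))
  k <- stats::runif(1, efficacy_range[1], efficacy_range[2])
  m <- invert_adjustment(model, adj)
  v <- k * m / (1 - (1 - k) * m)  # true central drive implied by measured m
  list(mfga = mfga, target_adjusted_cd = adj, efficacy_k = k,
       measured_cd = m, true_cd_max = v)
}

#' Simulate the clinical cohort
#'
#' Generates paretic and non-paretic limbs for each post-stroke participant
#' and a neurotypical comparison group, runs the MVC burst-superimposition
#' trials at measurement level (optionally as full traces), aggregates valid
#' trials per limb, applies the adjustment model, and generates per-minute
#' six-minute-walk-test distances whose total and first-to-sixth-minute
#' speed change correlate with paretic adjusted central drive at the
#' configured strength.
#'
#' @param config An [exp2_config()].
#' @param seed Integer seed.
#' @return A list of class `exp2_cohort`: `limbs` (generator ground truth
#'   per participant-limb), `trials` (per-trial measurements with
#'   ground-truth `clean` labels), `aggregates` (per-limb means over clean
#'   trials, measured and adjusted central drive), `walk` (per-participant
#'   minute distances, total, percent speed change), `traces`, `config`,
#'   `seed`.
#' @export
simulate_cohort_exp2 <- function(config = exp2_config(), seed = 1) {
  stopifnot(inherits(config, "exp2_config"))
  model <- config$model
  limb_defs <- rbind(
    if (config$n_stroke > 0) {
      data.frame(
        participant = rep(paste0("S", sprintf("%02d", seq_len(config$n_stroke))), 2),
        group = rep(c("paretic", "non_paretic"), each = config$n_stroke),
        n_trials = config$trials_stroke
      )
    },
    if (config$n_neurotypical > 0) {
      data.frame(
        participant = paste0("N", sprintf("%02d", seq_len(config$n_neurotypical))),
        group = "neurotypical",
        n_trials = config$trials_neurotypical
      )
    }
  )
  if (is.null(limb_defs) || nrow(limb_defs) == 0L) {
    return(structure(list(limbs = data.frame(), trials = data.frame(),
                          aggregates = data.frame(), walk = data.frame(),
                          traces = NULL, config = config, seed = seed),
                     class = "exp2_cohort"))
  }
  limbs <- do.call(rbind, lapply(seq_len(nrow(limb_defs)), function(i) {
    with_seed(derive_seed(seed, 10, i), {
      d <- draw_limb(config$groups[[limb_defs$group[i]]], model, config$efficacy_range)
      data.frame(participant = limb_defs$participant[i], group = limb_defs$group[i],
                 mfga = d$mfga, true_cd_max = d$true_cd_max,
                 efficacy_k = d$efficacy_k, measured_cd_truth = d$measured_cd,
                 target_adjusted_cd = d$target_adjusted_cd,
                 n_trials = limb_defs$n_trials[i])
    })
  }))
  traces <- if (config$traces) list() else NULL
  trials <- do.call(rbind, lapply(seq_len(nrow(limbs)), function(i) {
    l <- limbs[i, ]
    do.call(rbind, lapply(seq_len(l$n_trials), function(j) {
      with_seed(derive_seed(seed, 20, i, j), {
        violated <- stats::runif(1) < config$qc_violation_rate
        f_vol_p <- l$true_cd_max * l$mfga *
          min(1 / l$true_cd_max, max(0.5, 1 + stats::rnorm(1, 0, config$effort_sd)))
        gap <- l$efficacy_k * (l$mfga - f_vol_p)
        f_vol_m <- f_vol_p + stats::rnorm(1, 0, 0.02)
        f_stim_m <- f_vol_p + gap * (1 - exp(-0.15 / 0.04)) +
          stats::rnorm(1, 0, config$fstim_noise_sd)
        data.frame(participant = l$participant, group = l$group, trial = j,
                   f_vol = f_vol_m, f_stim = max(f_stim_m, f_vol_m, 0.1),
                   clean = !violated)
      })
    }))
  }))
  if (config$traces) {
    for (i in seq_len(nrow(limbs))) {
      l <- limbs[i, ]
      for (j in seq_len(l$n_trials)) {
        pp <- participant_params(
          id = l$participant,
          group = if (l$group == "neurotypical") "neurotypical" else "post-stroke",
          limb = chartr("_", "-", l$group), mfga = l$mfga,
          true_cd_max = l$true_cd_max, efficacy_k = l$efficacy_k
        )
        row_clean <- trials$clean[trials$participant == l$participant &
                                    trials$group == l$group & trials$trial == j]
        tr_seed <- derive_seed(seed, 30, i, j)
        sim <- if (row_clean) {
          simulate_trial(pp, effort_fraction = 1, device = "cedrs", seed = tr_seed)
        } else {
          # steady-state violation: voluntary torque still rising at the burst
          simulate_trial(pp, effort_fraction = 1, device = "cedrs", seed = tr_seed,
                         tau_rise = 1.2, enforce_plateau = FALSE)
        }
        sim$trace$meta$trial <- j
        sim$trace$meta$clean <- row_clean
        traces[[length(traces) + 1L]] <- sim$trace
      }
    }
  }
  aggregates <- do.call(rbind, lapply(seq_len(nrow(limbs)), function(i) {
    l <- limbs[i, ]
    tr <- trials[trials$participant == l$participant & trials$group == l$group &
                   trials$clean, ]
    if (nrow(tr) == 0L) {
      data.frame(participant = l$participant, group = l$group,
                 f_vol_mean = NA_real_, f_stim_mean = NA_real_,
                 n_valid = 0L, measured_cd = NA_real_, adjusted_cd = NA_real_)
    } else {
      fv <- mean(tr$f_vol)
      fsm <- mean(tr$f_stim)
      md <- measured_cd(fv, fsm)
      data.frame(participant = l$participant, group = l$group,
                 f_vol_mean = fv, f_stim_mean = fsm, n_valid = nrow(tr),
                 measured_cd = md$cd,
                 adjusted_cd = pmin(1, pmax(0, eval_adjustment(model, md$cd))))
    }
  }))
  walk <- if (config$n_stroke > 0) {
    par_adj <- aggregates[aggregates$group == "paretic", ]
    par_adj <- par_adj[match(paste0("S", sprintf("%02d", seq_len(config$n_stroke))),
                             par_adj$participant), ]
    cd_vals <- par_adj$adjusted_cd
    cd_ref <- ifelse(is.na(cd_vals), mean(cd_vals, na.rm = TRUE), cd_vals)
    z <- if (stats::sd(cd_ref) > 0) (cd_ref - mean(cd_ref)) / stats::sd(cd_ref) else
      rep(0, length(cd_ref))
    with_seed(derive_seed(seed, 40), {
      r <- config$r_target
      e1 <- stats::rnorm(config$n_stroke)
      e2 <- stats::rnorm(config$n_stroke)
      total <- pmax(30, config$walk_total_mean +
                      config$walk_total_sd * (r * z + sqrt(1 - r^2) * e1))
      pct <- config$walk_delta_mean +
        config$walk_delta_sd * (r * z + sqrt(1 - r^2) * e2)
      d1 <- total / (6 + 0.03 * pct)
      slope <- d1 * pct / 500
      minutes <- t(vapply(seq_len(config$n_stroke), function(i) {
        m <- d1[i] + (0:5) * slope[i]
        m[2:5] <- pmax(0, m[2:5] + stats::rnorm(4, 0, 1))
        m
      }, numeric(6)))
      colnames(minutes) <- paste0("minute", 1:6)
      data.frame(participant = par_adj$participant, minutes,
                 total_distance = rowSums(minutes),
                 pct_delta_speed = apply(minutes, 1, pct_delta_6mwt))
    })
  } else {
    data.frame()
  }
  structure(
    list(limbs = limbs, trials = trials, aggregates = aggregates, walk = walk,
         traces = traces, config = config, seed = seed),
    class = "exp2_cohort"
  )
}
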
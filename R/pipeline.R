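# End-to-end orchestration: simulate -> process -> calibrate -> adjust ->
# report, with YAML run configuration and deterministic, seedable outputs.
# The per-stage functions also run standalone; `run_study()` is the
# in-memory composition used in analyses and examples.

#' Run configuration
#'
#' Assembles and validates the configuration for a pipeline run. Unknown
#' keys are rejected so that typos in YAML files fail loudly.
#'
#' @param mode `"experiment1"` (two-device calibration) or `"cohort"`
#'   (clinical cohort).
#' @param seed Integer seed for all randomness.
#' @param qc Named list of [qc_config()] overrides.
#' @param filter Named list of filter overrides (`cutoff`, `order`,
#'   `zero_phase`, `post_window_s`).
#' @param simulate Named list of [exp1_config()] / [exp2_config()] overrides.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(mode = c("experiment1", "cohort"), seed = 1,
                       qc = list(), filter = list(), simulate = list()) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed), length(seed) == 1)
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(qc, names(formals(qc_config)), "qc")
  check_keys(filter, c("cutoff", "order", "zero_phase", "post_window_s"), "filter")
  sim_allowed <- if (mode == "experiment1") names(formals(exp1_config)) else
    names(formals(exp2_config))
  check_keys(simulate, sim_allowed, "simulate")
  structure(list(mode = mode, seed = as.integer(seed), qc = qc,
                 filter = filter, simulate = simulate),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys are the arguments of
#'   [run_config()]. Unknown keys are rejected.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), names(formals(run_config)))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, raw)
}

build_sim_config <- function(config) {
  if (config$mode == "experiment1") {
    do.call(exp1_config, config$simulate)
  } else {
    do.call(exp2_config, config$simulate)
  }
}

#' Simulate a cohort to disk
#'
#' Runs the simulator for the configured mode and writes a cohort directory:
#' `truth.json` (per-trial ground truth), `cohort.json` (per-participant or
#' per-limb generator parameters), `config_snapshot.yaml`, and -- when trace
#' generation is enabled in the simulate config -- one trace CSV per trial
#' under `traces/`. Output is deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The simulation object ([simulate_experiment1()] or
#'   [simulate_cohort_exp2()] result), invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- build_sim_config(config)
  sim <- if (config$mode == "experiment1") {
    simulate_experiment1(sim_cfg, seed = config$seed)
  } else {
    simulate_cohort_exp2(sim_cfg, seed = config$seed)
  }
  write_json_file(sim$trials, file.path(out_dir, "truth.json"))
  cohort_tab <- if (config$mode == "experiment1") sim$participants else sim$limbs
  write_json_file(cohort_tab, file.path(out_dir, "cohort.json"))
  snapshot <- config
  class(snapshot) <- NULL
  yaml::write_yaml(snapshot, file.path(out_dir, "config_snapshot.yaml"))
  if (!is.null(sim$traces)) {
    tdir <- file.path(out_dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_along(sim$traces)) {
      tr <- sim$traces[[i]]
      fname <- sprintf("trial_%04d_%s_%s.csv", i,
                       tr$meta$id %||% "unknown",
                       chartr("-", "_", tr$meta$limb %||% tr$meta$device %||% "x"))
      write_trace(tr, file.path(tdir, fname))
      meta_path <- file.path(tdir, sprintf("trial_%04d_meta.json", i))
      write_json_file(tr$meta, meta_path)
    }
  }
  invisible(sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Process a cohort of torque traces
#'
#' Reads every trace in a cohort directory (or takes an in-memory list of
#' traces), runs [summarize_trial()] on each, and aggregates valid trials
#' per participant-limb with [aggregate_participant()]. Participant-limbs
#' with zero valid trials are retained in the output with `NA` means and
#' counted in the QC summary; reprocessing the same inputs is idempotent.
#'
#' @param cohort Either a cohort directory written by [run_simulate()] (its
#'   `traces/` subdirectory is read) or a list of [torque_trace()] objects.
#' @param qc A [qc_config()].
#' @param out_dir Optional directory to write `trials.json` and
#'   `participants.json`.
#' @param ... Passed to [summarize_trial()] (filter settings).
#' @return A list with `trials` (one row per trace: measurements and flags)
#'   and `participants` (per participant-limb aggregates).
#' @export
run_process <- function(cohort, qc = qc_config(), out_dir = NULL, ...) {
  traces <- if (is.character(cohort)) {
    tdir <- file.path(cohort, "traces")
    if (!dir.exists(tdir)) stop("no traces/ directory under ", cohort, call. = FALSE)
    files <- sort(list.files(tdir, pattern = "\\.csv$", full.names = TRUE))
    lapply(files, function(f) {
      meta_path <- file.path(dirname(f),
                             sub("^(trial_[0-9]+).*$", "\\1_meta.json", basename(f)))
      meta <- if (file.exists(meta_path)) {
        jsonlite::read_json(meta_path, simplifyVector = TRUE)
      } else {
        list()
      }
      read_trace(f, meta = meta)
    })
  } else {
    cohort
  }
  stopifnot(all(vapply(traces, inherits, logical(1), "torque_trace")))
  measurements <- lapply(traces, summarize_trial, qc = qc, ...)
  trials <- do.call(rbind, lapply(seq_along(measurements), function(i) {
    m <- measurements[[i]]
    meta <- traces[[i]]$meta
    data.frame(
      index = i,
      participant = meta$id %||% NA_character_,
      limb = meta$limb %||% NA_character_,
      device = meta$device %||% NA_character_,
      f_vol = m$f_vol, f_stim = m$f_stim,
      pre_burst_variance = m$pre_burst_variance,
      pre_burst_slope = m$pre_burst_slope,
      flags = paste(m$flags, collapse = ";"),
      valid = m$valid
    )
  }))
  key <- interaction(trials$participant, trials$limb, trials$device, drop = TRUE)
  participants <- do.call(rbind, lapply(split(seq_len(nrow(trials)), key), function(idx) {
    agg <- aggregate_participant(measurements[idx], limb = trials$limb[idx[1]])
    data.frame(
      participant = trials$participant[idx[1]],
      limb = agg$limb, device = trials$device[idx[1]],
      f_vol_mean = agg$f_vol_mean, f_stim_mean = agg$f_stim_mean,
      n_valid = agg$n_valid, n_total = agg$n_total
    )
  }))
  rownames(participants) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_json_file(trials, file.path(out_dir, "trials.json"))
    write_json_file(participants, file.path(out_dir, "participants.json"))
  }
  list(trials = trials, participants = participants)
}

#' Run the full validation study in memory
#'
#' Composes the whole pipeline at measurement level: simulates the
#' two-device calibration experiment, computes device agreement (ICC(2,1)
#' and Bland-Altman limits on the MVC torques), fits and cross-validates the
#' adjustment equation on the calibration pairs, simulates the clinical
#' cohort, compares groups (one-way ANOVA, eta-squared, Sidak pairwise) on
#' voluntary torque, MFGA and adjusted central drive, and correlates paretic
#' adjusted central drive with the six-minute-walk-test outcomes.
#'
#' @param seed Integer seed driving both simulations.
#' @param exp1 An [exp1_config()].
#' @param exp2 An [exp2_config()].
#' @param use_fitted_model Adjust the clinical cohort with the freshly
#'   fitted equation (default) rather than the one in `exp2$model`.
#' @return A list of class `study_results`: `agreement` (`icc`, `bland_altman`),
#'   `model`, `group_table`, `anova` (per variable), `pairwise` (per
#'   variable), `correlations`, `qc_counts`, plus the two simulation objects.
#' @export
run_study <- function(seed = 1, exp1 = exp1_config(), exp2 = exp2_config(),
                      use_fitted_model = TRUE) {
  e1 <- simulate_experiment1(exp1, seed = seed)
  mvc_a <- e1$mvc$f_vol.dynamometer
  mvc_b <- e1$mvc$f_vol.cedrs
  agreement <- list(
    icc = icc_2_1(cbind(dynamometer = mvc_a, cedrs = mvc_b)),
    bland_altman = bland_altman(mvc_a, mvc_b)
  )
  model <- fit_adjustment(e1$pairs$measured, e1$pairs$true, e1$pairs$participant)
  if (use_fitted_model) exp2$model <- model
  e2 <- simulate_cohort_exp2(exp2, seed = seed)
  agg <- e2$aggregates[!is.na(e2$aggregates$adjusted_cd), ]
  group_levels <- c("neurotypical", "paretic", "non_paretic")
  vars <- c(f_vol = "f_vol_mean", mfga = "f_stim_mean", adjusted_cd = "adjusted_cd")
  groups_of <- function(var) {
    lapply(stats::setNames(group_levels, group_levels),
           function(g) agg[[var]][agg$group == g])
  }
  anova <- lapply(vars, function(v) one_way_anova_eta(groups_of(v)))
  pairwise <- lapply(vars, function(v) sidak_pairwise(groups_of(v)))
  group_table <- do.call(rbind, lapply(names(vars), function(nm) {
    v <- vars[[nm]]
    row <- vapply(group_levels, function(g) {
      x <- agg[[v]][agg$group == g]
      sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
    }, character(1))
    data.frame(variable = nm, Neurotypical = row["neurotypical"],
               Paretic = row["paretic"], `Non-Paretic` = row["non_paretic"],
               check.names = FALSE)
  }))
  rownames(group_table) <- NULL
  correlations <- if (nrow(e2$walk) > 0) {
    par <- e2$aggregates[e2$aggregates$group == "paretic", ]
    merged <- merge(par[, c("participant", "adjusted_cd")], e2$walk,
                    by = "participant")
    merged <- merged[!is.na(merged$adjusted_cd), ]
    list(
      distance = pearson_r(merged$adjusted_cd, merged$total_distance),
      pct_delta = pearson_r(merged$adjusted_cd, merged$pct_delta_speed)
    )
  } else {
    NULL
  }
  qc_counts <- list(
    limbs_total = nrow(e2$aggregates),
    limbs_excluded = sum(is.na(e2$aggregates$adjusted_cd)),
    trials_total = nrow(e2$trials),
    trials_clean = sum(e2$trials$clean)
  )
  structure(
    list(agreement = agreement, model = model, group_table = group_table,
         anova = anova, pairwise = pairwise, correlations = correlations,
         qc_counts = qc_counts, exp1 = e1, exp2 = e2, seed = seed),
    class = "study_results"
  )
}

#' Render a study report
#'
#' Plain-text report mirroring the validation structure: device agreement,
#' adjustment-equation diagnostics, group comparison table (Neurotypical /
#' Paretic / Non-Paretic), and walk-test correlations.
#'
#' @param results A `study_results` object from [run_study()].
#' @return Character vector of report lines.
#' @export
report_text <- function(results) {
  stopifnot(inherits(results, "study_results"))
  icc <- results$agreement$icc
  ba <- results$agreement$bland_altman
  m <- results$model
  lines <- c(
    "== Device agreement (MVC torque) ==",
    sprintf("ICC(2,1) = %.3f [%.3f, %.3f], p = %.3g",
            icc$icc, icc$ci[1], icc$ci[2], icc$p_value),
    sprintf("Bland-Altman bias = %.2f +/- %.2f ft-lbs, LoA [%.2f, %.2f]",
            ba$bias, ba$sd_diff, ba$loa_lower, ba$loa_upper),
    "",
    "== Adjustment equation ==",
    sprintf("adjusted = %.3f x^3 %+.3f x^2 %+.3f x", m$b3, m$b2, m$b1),
    sprintf("R^2 = %.3f, RMSE = %.2f%%, LOOCV RMSE = %.2f +/- %.2f%%, BP p = %.3f",
            m$r_squared, m$rmse, m$loocv_rmse_mean, m$loocv_rmse_sd, m$bp_p_value),
    "",
    "== Group comparisons ==",
    utils::capture.output(print(results$group_table))
  )
  for (nm in names(results$anova)) {
    a <- results$anova[[nm]]
    lines <- c(lines, sprintf(
      "%s: F(%d,%d) = %.2f, p = %.3g, eta^2 = %.3f [%.3f, %.3f]",
      nm, a$df[1], a$df[2], a$f_statistic, a$p_value,
      a$eta_squared, a$eta_ci[1], a$eta_ci[2]))
  }
  if (!is.null(results$correlations)) {
    co <- results$correlations
    lines <- c(lines, "",
               "== Walk-test associations (paretic adjusted central drive) ==",
               sprintf("6MWT total distance: r = %.3f, p = %.3g (n = %d)",
                       co$distance$r, co$distance$p_value, co$distance$n),
               sprintf("%%delta 6MWT speed:    r = %.3f, p = %.3g (n = %d)",
                       co$pct_delta$r, co$pct_delta$p_value, co$pct_delta$n))
  }
  qc <- results$qc_counts
  c(lines, "",
    sprintf("QC: %d/%d limbs usable; %d/%d trials clean",
            qc$limbs_total - qc$limbs_excluded, qc$limbs_total,
            qc$trials_clean, qc$trials_total))
}

#' @export
print.study_results <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `results.json` (agreement, model coefficients and diagnostics,
#' ANOVA summaries, correlations, QC accounting) and `report.txt` (the
#' [report_text()] rendering).
#'
#' @param results A `study_results` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_report <- function(results, out_dir) {
  stopifnot(inherits(results, "study_results"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  icc <- results$agreement$icc
  ba <- results$agreement$bland_altman
  m <- results$model
  payload <- list(
    agreement = list(
      icc = icc$icc, icc_ci = icc$ci, icc_p = icc$p_value,
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa = c(ba$loa_lower, ba$loa_upper)
    ),
    model = list(
      b3 = m$b3, b2 = m$b2, b1 = m$b1,
      r_squared = m$r_squared, r_squared_uncentered = m$r_squared_uncentered,
      rmse = m$rmse, loocv_rmse_mean = m$loocv_rmse_mean,
      loocv_rmse_sd = m$loocv_rmse_sd, bp_p_value = m$bp_p_value
    ),
    anova = lapply(results$anova, function(a) {
      list(f = a$f_statistic, df = a$df, p = a$p_value,
           eta_squared = a$eta_squared, eta_ci = a$eta_ci)
    }),
    pairwise = results$pairwise,
    correlations = if (!is.null(results$correlations)) {
      lapply(results$correlations, function(co) {
        list(r = co$r, p = co$p_value, n = co$n)
      })
    },
    qc_counts = results$qc_counts,
    seed = results$seed
  )
  write_json_file(payload, file.path(out_dir, "results.json"))
  writeLines(report_text(results), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
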
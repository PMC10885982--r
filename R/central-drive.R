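# Central drive ratios and the device adjustment equation.
#
# Electrically evoked contractions do not always activate all of the force-
# generating capacity left unaccessed by volition, so the device-measured
# ratio F_vol/F_stim overestimates the true ratio F_vol/MFGA. An origin-
# constrained cubic fitted on a calibration cohort (where MFGA is measurable)
# maps measured central drive to an adjusted estimate of true central drive.

#' Device-measured central drive
#'
#' The ratio of voluntary to stimulation-elicited torque, F_vol/F_stim.
#' Under measurement noise F_vol can exceed F_stim (no augmentation was
#' measured); such ratios are capped at 1 and flagged, keeping the value in
#' the domain of the adjustment equation.
#'
#' @param f_vol Voluntary torque(s), ft-lbs.
#' @param f_stim Stimulation-elicited torque(s), ft-lbs; must be positive.
#' @return A data.frame with columns `cd` (ratio in \[0, 1\]) and `capped`
#'   (logical).
#' @examples
#' measured_cd(30, 60)   # cd 0.5
#' measured_cd(61, 60)   # capped at 1
#' @export
measured_cd <- function(f_vol, f_stim) {
  if (any(!is.finite(f_stim)) || any(f_stim <= 0)) {
    stop("f_stim must be positive", call. = FALSE)
  }
  ratio <- f_vol / f_stim
  capped <- ratio > 1
  ratio[capped] <- 1
  data.frame(cd = ratio, capped = capped)
}

#' True central drive
#'
#' The ratio of voluntary torque to the participant's maximum
#' force-generating ability, F_vol/MFGA; capped at 1.
#'
#' @param f_vol Voluntary torque(s), ft-lbs.
#' @param mfga Maximum force-generating ability, ft-lbs; must be positive.
#' @return Numeric ratio(s) in \[0, 1\].
#' @export
true_cd <- function(f_vol, mfga) {
  if (any(!is.finite(mfga)) || any(mfga <= 0)) {
    stop("mfga must be positive", call. = FALSE)
  }
  pmin(1, f_vol / mfga)
}

#' Construct an adjustment model from known coefficients
#'
#' An adjustment model is the origin-constrained cubic
#' `adjusted = b3 x^3 + b2 x^2 + b1 x` mapping device-measured central drive
#' `x` to an estimate of true central drive. Use [fit_adjustment()] to
#' calibrate one from data; this constructor builds one from coefficients
#' (e.g. a previously published device calibration).
#'
#' @param b1,b2,b3 Linear, quadratic and cubic coefficients.
#' @param source Free-text provenance note.
#' @return An object of class `adjustment_model`.
#' @export
adjustment_model <- function(b1, b2, b3, source = "coefficients") {
  stopifnot(is.finite(b1), is.finite(b2), is.finite(b3))
  structure(
    list(b1 = b1, b2 = b2, b3 = b3,
         coef_ci = NULL, r_squared = NA_real_, r_squared_uncentered = NA_real_,
         rmse = NA_real_, loocv_rmse_mean = NA_real_, loocv_rmse_sd = NA_real_,
         bp_statistic = NA_real_, bp_p_value = NA_real_,
         n = NA_integer_, n_participants = NA_integer_, source = source),
    class = "adjustment_model"
  )
}

#' Reference CEDRS adjustment model
#'
#' The adjustment equation shipped with the package for the portable
#' plantarflexor central drive system (CEDRS):
#' `adjusted = 0.798 x^3 - 0.772 x^2 + 0.868 x`. It is applied to cohorts
#' that lack their own calibration data (clinical cohorts, where MFGA cannot
#' be measured reliably). The polynomial is strictly increasing on \[0, 1\]
#' and tops out at 0.894 at a measured central drive of 1, so adjusted values
#' cannot exceed 89% -- a known ceiling of this calibration.
#'
#' @return An `adjustment_model` (see [adjustment_model()]).
#' @examples
#' m <- reference_adjustment_model()
#' apply_adjustment(m, c(0, 0.5, 1))
#' @export
reference_adjustment_model <- function() {
  adjustment_model(b1 = 0.868, b2 = -0.772, b3 = 0.798,
                   source = "reference CEDRS calibration")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("<adjustment_model> adjusted = ",
      sprintf("%.4g x^3 %+.4g x^2 %+.4g x", x$b3, x$b2, x$b1), "\n", sep = "")
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 = %.3f (uncentered %.3f), RMSE = %.2f%%\n",
                x$r_squared, x$r_squared_uncentered, x$rmse))
  }
  if (!is.na(x$loocv_rmse_mean)) {
    cat(sprintf("  LOOCV RMSE = %.2f +/- %.2f%% across %d participants\n",
                x$loocv_rmse_mean, x$loocv_rmse_sd, x$n_participants))
  }
  if (!is.na(x$bp_p_value)) {
    cat(sprintf("  Breusch-Pagan p = %.3f\n", x$bp_p_value))
  }
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Fit the origin-constrained cubic adjustment equation
#'
#' Ordinary least squares of true central drive on the basis
#' `{x, x^2, x^3}` of measured central drive, with no intercept: a measured
#' central drive of 0 must map to a true central drive of 0, so the curve is
#' fixed at the origin by construction. Reports 95% coefficient confidence
#' intervals from the linear-model covariance, R-squared against the mean of
#' the response (the uncentered variant is reported alongside, as the two
#' conventions differ for no-intercept fits), RMSE in percentage points of
#' central drive, the Breusch-Pagan heteroscedasticity test of the residuals
#' against measured central drive, and -- when participant identifiers are
#' given -- leave-one-participant-out cross-validated RMSE.
#'
#' @param measured Device-measured central drive values in \[0, 1\].
#' @param true True central drive values in \[0, 1\].
#' @param participant Optional participant identifiers (used for LOOCV).
#' @param conf_level Confidence level for coefficient intervals.
#' @return A fitted `adjustment_model` (see [adjustment_model()]).
#' @seealso [apply_adjustment()], [loocv_adjustment()], [breusch_pagan()]
#' @export
fit_adjustment <- function(measured, true, participant = NULL, conf_level = 0.95) {
  measured <- as.numeric(measured)
  true <- as.numeric(true)
  if (length(measured) != length(true)) {
    stop("measured and true must have equal length", call. = FALSE)
  }
  if (length(measured) < 4L) {
    stop("need at least 4 calibration pairs", call. = FALSE)
  }
  if (length(unique(measured)) < 2L) {
    stop("rank-deficient design: measured values must span more than one value",
         call. = FALSE)
  }
  fit <- stats::lm(true ~ 0 + measured + I(measured^2) + I(measured^3))
  if (fit$rank < 3L) stop("rank-deficient design", call. = FALSE)
  b <- unname(stats::coef(fit))
  ci <- stats::confint(fit, level = conf_level)
  rownames(ci) <- c("b1", "b2", "b3")
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  r2 <- 1 - rss / sum((true - mean(true))^2)
  r2u <- 1 - rss / sum(true^2)
  bp <- breusch_pagan(res, measured)
  model <- adjustment_model(b1 = b[1], b2 = b[2], b3 = b[3],
                            source = sprintf("fit to %d pairs", length(measured)))
  model$coef_ci <- ci
  model$r_squared <- r2
  model$r_squared_uncentered <- r2u
  model$rmse <- sqrt(mean(res^2)) * 100
  model$bp_statistic <- bp$statistic
  model$bp_p_value <- bp$p_value
  model$n <- length(measured)
  if (!is.null(participant)) {
    ids <- unique(participant)
    model$n_participants <- length(ids)
    if (length(ids) >= 3L) {
      cv <- loocv_adjustment(measured, true, participant)
      model$loocv_rmse_mean <- cv$rmse_mean
      model$loocv_rmse_sd <- cv$rmse_sd
    }
  }
  model
}

#' Apply an adjustment model
#'
#' Evaluates the origin-constrained cubic at measured central drive `x`.
#' Predictions outside \[0, 1\] (possible for a poorly calibrated model) are
#' clipped with a warning.
#'
#' @param model An `adjustment_model`.
#' @param x Measured central drive value(s) in \[0, 1\].
#' @return Adjusted central drive value(s) in \[0, 1\].
#' @examples
#' apply_adjustment(reference_adjustment_model(), 0.5)  # 0.34075
#' @export
apply_adjustment <- function(model, x) {
  stopifnot(inherits(model, "adjustment_model"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("measured central drive must lie in [0, 1]", call. = FALSE)
  }
  y <- eval_adjustment(model, x)
  if (any(y < 0) || any(y > 1)) {
    warning("adjusted central drive outside [0, 1]; clipping", call. = FALSE)
    y <- pmin(1, pmax(0, y))
  }
  y
}

# Raw polynomial evaluation, no domain/range policing.
eval_adjustment <- function(model, x) {
  model$b3 * x^3 + model$b2 * x^2 + model$b1 * x
}

#' Invert an adjustment model
#'
#' Solves `apply_adjustment(model, x) = adjusted` for `x` on \[0, 1\] by
#' bisection; requires the model to be strictly increasing on \[0, 1\] (true
#' for the reference calibration). Used by the cohort simulator to translate
#' target adjusted central drive into generator parameters.
#'
#' @param model An `adjustment_model`.
#' @param adjusted Adjusted central drive value(s), within the model's range
#'   over \[0, 1\].
#' @return Measured central drive value(s).
#' @export
invert_adjustment <- function(model, adjusted) {
  stopifnot(inherits(model, "adjustment_model"))
  if (!is_monotone_increasing(model)) {
    stop("adjustment model is not monotone increasing on [0, 1]", call. = FALSE)
  }
  ymax <- eval_adjustment(model, 1)
  vapply(adjusted, function(a) {
    if (!is.finite(a) || a < 0 || a > ymax) {
      stop("adjusted value ", a, " outside model range [0, ", signif(ymax, 4), "]",
           call. = FALSE)
    }
    if (a == 0) return(0)
    stats::uniroot(function(x) eval_adjustment(model, x) - a,
                   c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}

#' Check monotonicity of an adjustment model
#'
#' Evaluates the cubic's derivative on a dense grid over \[0, 1\].
#'
#' @param model An `adjustment_model`.
#' @param grid_n Number of grid points (default 1000).
#' @return `TRUE` iff the derivative is strictly positive at every grid point.
#' @export
is_monotone_increasing <- function(model, grid_n = 1000) {
  x <- seq(0, 1, length.out = grid_n)
  all(3 * model$b3 * x^2 + 2 * model$b2 * x + model$b1 > 0)
}

#' Leave-one-participant-out cross-validation of the adjustment fit
#'
#' For each participant, refits the origin-constrained cubic on the remaining
#' participants and computes the RMSE (percentage points of central drive) on
#' the held-out participant's pairs. The mean and SD of the per-participant
#' RMSEs summarise whether fit error is stable across participants, i.e.
#' whether any single participant drives the calibration.
#'
#' @inheritParams fit_adjustment
#' @param participant Participant identifier per pair; at least 3 distinct.
#' @return A list with `rmse_mean`, `rmse_sd`, and `folds` (a data.frame of
#'   per-participant RMSEs).
#' @export
loocv_adjustment <- function(measured, true, participant) {
  measured <- as.numeric(measured)
  true <- as.numeric(true)
  if (length(measured) != length(true) || length(participant) != length(true)) {
    stop("measured, true and participant must have equal length", call. = FALSE)
  }
  ids <- unique(participant)
  if (length(ids) < 3L) stop("need at least 3 participants for LOOCV", call. = FALSE)
  rmse <- vapply(ids, function(id) {
    hold <- participant == id
    x <- measured[!hold]
    y <- true[!hold]
    fit <- stats::lm(y ~ 0 + x + I(x^2) + I(x^3))
    b <- unname(stats::coef(fit))
    xh <- measured[hold]
    pred <- b[1] * xh + b[2] * xh^2 + b[3] * xh^3
    sqrt(mean((true[hold] - pred)^2)) * 100
  }, numeric(1))
  list(rmse_mean = mean(rmse), rmse_sd = stats::sd(rmse),
       folds = data.frame(participant = ids, rmse = rmse))
}

#' Breusch-Pagan heteroscedasticity test
#'
#' The Lagrange-multiplier form: squared residuals are regressed on an
#' intercept and the regressor; the statistic is `n` times the R-squared of
#' that auxiliary regression, referred to a chi-square distribution with one
#' degree of freedom. A large p-value indicates residual error that does not
#' change systematically with the regressor (here, the magnitude of
#' device-measured central drive).
#'
#' @param residuals Model residuals.
#' @param regressor Explanatory variable of the auxiliary regression
#'   (typically the measured central drive values); must be non-constant.
#' @return A list with `statistic` and `p_value`.
#' @export
breusch_pagan <- function(residuals, regressor) {
  n <- length(residuals)
  if (n < 3L) stop("need at least 3 residuals", call. = FALSE)
  if (length(regressor) != n) {
    stop("residuals and regressor must have equal length", call. = FALSE)
  }
  if (stats::var(regressor) == 0) stop("regressor is constant", call. = FALSE)
  u2 <- residuals^2
  r2 <- if (stats::var(u2) == 0) 0 else stats::cor(u2, regressor)^2
  statistic <- n * r2
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}
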
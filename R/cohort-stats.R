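# Agreement and group-comparison statistics used to validate the device:
# ICC(2,1) and Bland-Altman limits of agreement between devices; one-way
# ANOVA with eta-squared and Sidak-adjusted pairwise tests across limbs; and
# the six-minute-walk-test association metrics.

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Computed from the two-way ANOVA decomposition of an n-subjects by k-raters
#' matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' where MSR, MSC and MSE are the subject, rater and residual mean squares.
#' Absolute agreement charges systematic rater differences (MSC) against the
#' correlation, unlike the consistency form. The confidence interval uses the
#' F-based method for this ICC form, and the p-value tests MSR/MSE against
#' F(n-1, (n-1)(k-1)).
#'
#' @param ratings Numeric matrix, subjects in rows, raters/devices in
#'   columns; no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `agreement_icc` with `icc`, `ci` (length-2),
#'   `f_value`, `p_value`, `n`, `k`, and the mean squares `ms`.
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells in ratings matrix", call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters", call. = FALSE)
  gm <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  sst <- sum((ratings - gm)^2)
  if (sst == 0) stop("degenerate ratings: zero total variance", call. = FALSE)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  # F-based interval for the absolute-agreement single-measure form.
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  fv <- msr / mse
  structure(
    list(icc = icc, ci = c(lower, upper), f_value = fv,
         p_value = stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE),
         n = n, k = k, ms = list(msr = msr, msc = msc, mse = mse)),
    class = "agreement_icc"
  )
}

#' @export
print.agreement_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f [%.3f, %.3f], F = %.2f, p = %.3g (n = %d, k = %d)\n",
              x$icc, x$ci[1], x$ci[2], x$f_value, x$p_value, x$n, x$k))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Paired differences `d = b - a`; bias is their mean and the limits of
#' agreement are `bias +/- 1.96 SD(d)` (n-1 denominator).
#'
#' @param a,b Paired measurement vectors of equal length (>= 2), e.g. the
#'   reference and the new device.
#' @param multiplier Width of the agreement interval in SDs (default 1.96).
#' @return A list of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper` and `n`.
#' @export
bland_altman <- function(a, b, multiplier = 1.96) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- b - a
  bias <- mean(d)
  s <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = s,
         loa_lower = bias - multiplier * s, loa_upper = bias + multiplier * s,
         n = length(d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f +/- %.2f ft-lbs, LoA [%.2f, %.2f] (n = %d)\n",
              x$bias, x$sd_diff, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' One-way ANOVA with eta-squared effect size
#'
#' Standard between/within decomposition via [stats::aov()];
#' `eta^2 = SS_between / SS_total` with a 95% confidence interval obtained by
#' inverting the noncentral-F distribution at the observed F statistic
#' (profile over the noncentrality parameter, converted through
#' `eta^2 = lambda / (lambda + N)`). Effect sizes of 0.01/0.06/0.14 are
#' conventionally read as small/medium/large.
#'
#' @param groups Named or unnamed list of numeric vectors, one per group;
#'   each group needs at least 2 values.
#' @param conf_level Confidence level for the eta-squared interval.
#' @return A list of class `group_comparison` with `f_statistic`, `df`,
#'   `p_value`, `eta_squared`, `eta_ci`, and group sizes `n`.
#' @export
one_way_anova_eta <- function(groups, conf_level = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), sizes), levels = names(groups))
  fit <- stats::aov(values ~ fac)
  tab <- summary(fit)[[1]]
  ssb <- tab["fac", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  df1 <- tab["fac", "Df"]
  df2 <- tab["Residuals", "Df"]
  f <- tab["fac", "F value"]
  p <- tab["fac", "Pr(>F)"]
  eta <- if (ssb + ssw == 0) 0 else ssb / (ssb + ssw)
  # degenerate decompositions (zero within- and/or between-group variance)
  # give a non-finite F; the interval then collapses onto the point estimate
  ci <- if (is.finite(f) && f < 1e12) eta_squared_ci(f, df1, df2, conf_level) else
    c(eta, eta)
  structure(
    list(f_statistic = f, df = c(df1, df2), p_value = p,
         eta_squared = eta, eta_ci = ci, n = sizes),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g, eta^2 = %.3f [%.3f, %.3f]\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value,
              x$eta_squared, x$eta_ci[1], x$eta_ci[2]))
  invisible(x)
}

# Noncentral-F inversion for the eta-squared interval.
eta_squared_ci <- function(f, df1, df2, conf_level = 0.95) {
  alpha <- 1 - conf_level
  n_total <- df1 + df2 + 1
  solve_ncp <- function(target) {
    # largest lambda with P(F_{df1,df2,lambda} <= f) = target; pf is
    # decreasing in lambda so bisection via uniroot on an expanding bracket
    if (stats::pf(f, df1, df2, ncp = 0) <= target) return(0)
    hi <- max(10, 2 * f * df1)
    while (stats::pf(f, df1, df2, ncp = hi) > target && hi < 1e8) hi <- hi * 2
    stats::uniroot(function(l) stats::pf(f, df1, df2, ncp = l) - target,
                   c(0, hi), tol = 1e-8)$root
  }
  lambda_lower <- solve_ncp(1 - alpha / 2)
  lambda_upper <- solve_ncp(alpha / 2)
  c(lambda_lower / (lambda_lower + n_total),
    lambda_upper / (lambda_upper + n_total))
}

#' Sidak adjustment of a p-value
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons; monotone in both arguments
#' and never smaller than the raw p-value.
#'
#' @param p Raw p-value(s).
#' @param m Number of comparisons.
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0), all(p <= 1), m >= 1)
  pmax(p, 1 - (1 - p)^m)
}

#' Sidak-adjusted pairwise comparisons
#'
#' Two-sample pooled-variance t tests for every pair of groups, with Sidak
#' adjustment over the number of pairs.
#'
#' @inheritParams one_way_anova_eta
#' @return A data.frame with columns `group1`, `group2`, `t`, `p_raw` and
#'   `p_adjusted`.
#' @export
sidak_pairwise <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  prs <- utils::combn(names(groups), 2)
  m <- ncol(prs)
  res <- apply(prs, 2, function(pair) {
    tt <- stats::t.test(groups[[pair[1]]], groups[[pair[2]]], var.equal = TRUE)
    c(t = unname(tt$statistic), p_raw = tt$p.value)
  })
  data.frame(
    group1 = prs[1, ], group2 = prs[2, ],
    t = res["t", ], p_raw = res["p_raw", ],
    p_adjusted = sidak_adjust(res["p_raw", ], m),
    row.names = NULL
  )
}

#' Pearson correlation with significance test
#'
#' Sample Pearson correlation with a two-sided p-value from the t transform
#' with n-2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return A list with `r`, `p_value` and `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Distance-induced change in six-minute-walk-test speed
#'
#' `100 * (d6 - d1) / d1`: the percent change in distance covered between the
#' first and sixth minutes. Positive values mean the participant sped up over
#' the test, negative values that they slowed down.
#'
#' @param minute_distances Numeric vector of 6 nonnegative per-minute
#'   distances (m); the first must be positive.
#' @return Percent change (scalar).
#' @examples
#' pct_delta_6mwt(c(60, 58, 55, 52, 48, 45))  # -25
#' @export
pct_delta_6mwt <- function(minute_distances) {
  if (length(minute_distances) != 6L) {
    stop("exactly 6 per-minute distances are required", call. = FALSE)
  }
  if (any(minute_distances < 0)) stop("distances must be nonnegative", call. = FALSE)
  d1 <- minute_distances[1]
  if (d1 <= 0) stop("first-minute distance must be positive", call. = FALSE)
  100 * (minute_distances[6] - d1) / d1
}
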
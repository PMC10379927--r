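#' Fit the external-standard calibration line
#'
#' Ordinary least squares of peak area on concentration, with every replicate
#' injection entering as its own (x, y) point. This is the first stage of the
#' calibration-significance chain; [regression_dispersions()],
#' [coefficient_significance()] and [regression_f_test()] add the dispersion
#' and test statistics, and [calibrate()] runs the whole chain.
#'
#' The normal equations are solved in closed form with the design determinant
#' `D = n * sum(x^2) - (sum(x))^2`, the same quantity that later scales the
#' coefficient standard deviations.
#'
#' @param levels Either a data.frame with columns `level` (or `concentration`)
#'   and `area`, or a list of lists with elements `concentration` and `areas`
#'   (replicate areas per level).
#' @return An object of class `calibration_fit` with elements `a` (slope), `b`
#'   (intercept), `r_squared`, `n`, `residuals`, `x`, `y`, and the sums and
#'   determinant `D` needed downstream. Dispersion/test fields are `NA` until
#'   the later stages run.
#' @examples
#' pts <- data.frame(level = c(1, 2, 3, 4), area = c(10, 12, 15, 19))
#' fit <- fit_line(pts)
#' c(fit$a, fit$b)
#' @export
fit_line <- function(levels) {
  pts <- as_calibration_points(levels)
  x <- pts$x; y <- pts$y
  n <- length(x)
  if (n < 2L) stop("at least two calibration points are required")
  if (length(unique(x)) < 2L)
    stop("all concentrations identical: design determinant D = 0, no line can be fitted")
  Sx <- sum(x); Sy <- sum(y); Sxx <- sum(x^2); Sxy <- sum(x * y)
  D <- n * Sxx - Sx^2
  a <- (n * Sxy - Sx * Sy) / D
  b <- (Sy * Sxx - Sx * Sxy) / D
  resid <- y - (a * x + b)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(resid^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(a = a, b = b, r_squared = r2, n = n, residuals = resid,
         x = x, y = y, sum_x = Sx, sum_x2 = Sxx, D = D,
         s_y = NA_real_, s_a = NA_real_, s_b = NA_real_,
         t_a = NA_real_, t_b = NA_real_, t_critical = NA_real_,
         f_stat = NA_real_, f_critical = NA_real_,
         confidence = NA_real_,
         verdicts = list(slope = NA, intercept = NA, regression = NA),
         degenerate_df = (n == 2L)),
    class = "calibration_fit")
}

as_calibration_points <- function(levels) {
  if (is.data.frame(levels)) {
    xcol <- intersect(c("level", "concentration", "concentration_ug_ml"),
                      names(levels))[1]
    if (is.na(xcol) || !"area" %in% names(levels))
      stop("calibration data.frame needs a concentration column and an 'area' column")
    return(data.frame(x = levels[[xcol]], y = levels$area))
  }
  if (is.list(levels)) {
    x <- unlist(lapply(levels, function(l)
      rep(l$concentration, length(l$areas))))
    y <- unlist(lapply(levels, `[[`, "areas"))
    return(data.frame(x = x, y = y))
  }
  stop("unsupported calibration input")
}

#' Residual and coefficient dispersions of a calibration fit
#'
#' Adds to the fit the residual standard deviation and the standard deviations
#' of the slope and intercept:
#' \deqn{S_y^2 = \sum d_i^2 / (n - 2), \quad
#'       S_a^2 = S_y^2 \, n / D, \quad
#'       S_b^2 = S_y^2 \, \sum x_i^2 / D,}
#' where `d_i` are the vertical residuals and `D` the design determinant. These
#' are the dispersions that feed the coefficient t tests and regression F test.
#'
#' @param fit A [calibration_fit] from [fit_line()] with `n >= 3`.
#' @return The fit with `s_y`, `s_a`, `s_b` populated.
#' @export
regression_dispersions <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$n < 3L)
    stop("n - 2 = 0: residual dispersion undefined with only two points")
  s_y2 <- sum(fit$residuals^2) / (fit$n - 2)
  fit$s_y <- sqrt(s_y2)
  fit$s_a <- sqrt(s_y2 * fit$n / fit$D)
  fit$s_b <- sqrt(s_y2 * fit$sum_x2 / fit$D)
  fit
}

#' Student's t tests for the calibration coefficients
#'
#' Computes `t = |coefficient| / SD` for the slope and the intercept and
#' compares each against the two-sided Student quantile at the requested
#' confidence with `n - 2` degrees of freedom. A coefficient is significant —
#' and must remain in the calibration equation — when its t statistic exceeds
#' the critical value. An exact fit (zero dispersion with a nonzero
#' coefficient) reports `Inf` and is deemed significant.
#'
#' @param fit A [calibration_fit] with dispersions computed.
#' @param confidence Confidence level, default 0.95.
#' @return The fit with `t_a`, `t_b`, `t_critical`, `confidence` and the
#'   slope/intercept verdicts filled in.
#' @export
coefficient_significance <- function(fit, confidence = 0.95) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (is.na(fit$s_a)) stop("run regression_dispersions() first")
  t_of <- function(coef, sd) {
    if (sd > 0) abs(coef) / sd else if (coef != 0) Inf else 0
  }
  fit$t_a <- t_of(fit$a, fit$s_a)
  fit$t_b <- t_of(fit$b, fit$s_b)
  fit$t_critical <- stats::qt(1 - (1 - confidence) / 2, df = fit$n - 2)
  fit$confidence <- confidence
  fit$verdicts$slope <- fit$t_a > fit$t_critical
  fit$verdicts$intercept <- fit$t_b > fit$t_critical
  fit
}

#' Regression F test for the calibration line
#'
#' `F = MS_regression / MS_residual` with 1 and `n - 2` degrees of freedom,
#' which for a straight-line fit equals the square of the slope t statistic.
#' The regression is significant — i.e. there is a linear relation between
#' concentration and area — when F exceeds the critical value, regardless of
#' the value of R^2. Zero residual variance reports `Inf` (significant).
#'
#' @param fit A [calibration_fit] with dispersions computed.
#' @param confidence Confidence level, default 0.95.
#' @return The fit with `f_stat`, `f_critical` and the regression verdict.
#' @export
regression_f_test <- function(fit, confidence = 0.95) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (is.na(fit$s_y)) stop("run regression_dispersions() first")
  ss_res <- sum(fit$residuals^2)
  fitted <- fit$a * fit$x + fit$b
  ss_reg <- sum((fitted - mean(fit$y))^2)
  fit$f_stat <- if (ss_res > 0) ss_reg / (ss_res / (fit$n - 2)) else Inf
  fit$f_critical <- stats::qf(confidence, df1 = 1, df2 = fit$n - 2)
  fit$verdicts$regression <- fit$f_stat > fit$f_critical
  fit
}

#' Fit and test a calibration line in one call
#'
#' Runs [fit_line()], [regression_dispersions()],
#' [coefficient_significance()] and [regression_f_test()].
#'
#' @inheritParams fit_line
#' @inheritParams coefficient_significance
#' @return A fully populated [calibration_fit].
#' @export
calibrate <- function(levels, confidence = 0.95) {
  fit <- regression_dispersions(fit_line(levels))
  fit <- coefficient_significance(fit, confidence)
  regression_f_test(fit, confidence)
}

#' Invert the calibration line: area to concentration
#'
#' `x = (area - b) / a`. Results outside the fitted concentration range are
#' flagged `extrapolated`; quantifying them requires dilution or a wider curve.
#'
#' @param fit A [calibration_fit] with nonzero slope.
#' @param area Peak area(s), same units as the calibration areas.
#' @return Numeric concentration(s) in the calibration's concentration units,
#'   with logical attribute `extrapolated`.
#' @export
invert_calibration <- function(fit, area) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$a == 0) stop("slope is zero: calibration cannot be inverted")
  conc <- (area - fit$b) / fit$a
  rng <- range(fit$x)
  structure(conc, extrapolated = conc < rng[1] | conc > rng[2])
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> y = %.4g x + %.4g   R^2 = %.4f   n = %d\n",
              x$a, x$b, x$r_squared, x$n))
  if (!is.na(x$s_y))
    cat(sprintf("  S_y = %.4g  S_a = %.4g  S_b = %.4g  (D = %.6g)\n",
                x$s_y, x$s_a, x$s_b, x$D))
  if (!is.na(x$t_a))
    cat(sprintf("  t(a) = %.2f, t(b) = %.2f vs t_crit = %.3f (%.0f%%): slope %s, intercept %s\n",
                x$t_a, x$t_b, x$t_critical, 100 * x$confidence,
                ifelse(isTRUE(x$verdicts$slope), "significant", "not significant"),
                ifelse(isTRUE(x$verdicts$intercept), "significant", "not significant")))
  if (!is.na(x$f_stat))
    cat(sprintf("  F = %.2f vs F_crit = %.3f: regression %s\n",
                x$f_stat, x$f_critical,
                ifelse(isTRUE(x$verdicts$regression), "significant", "not significant")))
  invisible(x)
}

#' Serialize a calibration fit to a plain list (for JSON)
#'
#' @param fit A [calibration_fit].
#' @return A named list of scalars/vectors suitable for
#'   [jsonlite::write_json()].
#' @export
calibration_fit_record <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  list(slope = fit$a, intercept = fit$b, r_squared = fit$r_squared,
       n = fit$n, s_y = fit$s_y, s_a = fit$s_a, s_b = fit$s_b,
       determinant = fit$D, t_slope = fit$t_a, t_intercept = fit$t_b,
       t_critical = fit$t_critical, f_stat = fit$f_stat,
       f_critical = fit$f_critical, confidence = fit$confidence,
       verdicts = fit$verdicts,
       concentration_range = range(fit$x))
}
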
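#' Intraday / interday precision
#'
#' Computes, per concentration level, the sample standard deviation
#' `S = sqrt(sum((x_i - mean)^2) / (n - 1))` and the coefficient of variation
#' `CV = 100 * S / mean`.
#'
#' For `mode = "intraday"` the replicates within each level (of a single day)
#' are pooled directly. For `mode = "interday"` the day means are computed per
#' level first and the CV is taken across day means, which isolates
#' between-day variability from injection scatter. The summary CV reported
#' alongside is the mean of the per-level CVs.
#'
#' @param replicates data.frame with columns `level` and `area` (any
#'   measurement column named `area` or `value`), plus `day` for interday.
#' @param mode `"intraday"` or `"interday"`.
#' @return An object of class `precision_result`: data.frame with `level`,
#'   `mean`, `sd`, `cv`, `n`, plus attributes `mode` and `summary_cv`.
#' @export
precision <- function(replicates, mode = c("intraday", "interday")) {
  mode <- match.arg(mode)
  vcol <- intersect(c("area", "value"), names(replicates))[1]
  if (is.na(vcol) || !"level" %in% names(replicates))
    stop("replicates need columns 'level' and 'area' (or 'value')")
  vals <- replicates[[vcol]]
  if (mode == "interday") {
    if (!"day" %in% names(replicates) || length(unique(replicates$day)) < 2L)
      stop("interday precision requires a 'day' column with at least 2 distinct days")
    agg <- stats::aggregate(vals,
                            by = list(level = replicates$level, day = replicates$day),
                            FUN = mean)
    replicates <- data.frame(level = agg$level, value = agg$x)
    vals <- replicates$value
  }
  out <- do.call(rbind, lapply(split(seq_along(vals), replicates$level), function(i) {
    v <- vals[i]
    if (length(v) < 2L) stop("each level needs at least 2 values for a CV")
    m <- mean(v); s <- stats::sd(v)
    if (m == 0) {
      warning("mean is zero: CV undefined for a level")
      cv <- NA_real_
    } else cv <- 100 * s / m
    data.frame(level = replicates$level[i[1]], mean = m, sd = s, cv = cv,
               n = length(v))
  }))
  out <- out[order(out$level), ]
  rownames(out) <- NULL
  structure(out, mode = mode, summary_cv = mean(out$cv, na.rm = TRUE),
            class = c("precision_result", "data.frame"))
}

#' System suitability from consecutive injections
#'
#' Repeatability of retention time and peak area over consecutive injections of
#' one standard level (conventionally an intermediate calibration point, e.g.
#' 40 ug/mL, injected 10 times). Reports the relative standard deviation (RSD,
#' same quantity as CV) of both series; the test passes when both RSDs are at
#' or below the threshold. A default acceptance of 2% is used, with guideline
#' practice often quoting roughly 1%; pass/fail at both levels is reported.
#'
#' @param injections data.frame with columns `rt` (minutes) and `area`.
#' @param rsd_threshold Pass threshold in percent (default 2).
#' @param min_injections Minimum number of injections required (default 6).
#' @return List with `rt_rsd`, `area_rsd` (percent), `n`, `threshold`, `pass`,
#'   and `pass_strict` (against 1%).
#' @export
system_suitability <- function(injections, rsd_threshold = 2,
                               min_injections = 6) {
  stopifnot(all(c("rt", "area") %in% names(injections)))
  n <- nrow(injections)
  if (n < min_injections)
    stop(sprintf("at least %d consecutive injections are required (got %d)",
                 min_injections, n))
  rsd <- function(v) 100 * stats::sd(v) / mean(v)
  rt_rsd <- rsd(injections$rt)
  area_rsd <- rsd(injections$area)
  list(rt_rsd = rt_rsd, area_rsd = area_rsd, n = n,
       threshold = rsd_threshold,
       pass = rt_rsd <= rsd_threshold && area_rsd <= rsd_threshold,
       pass_strict = rt_rsd <= 1 && area_rsd <= 1)
}

#' Limits of detection and quantification
#'
#' Two numeric estimators are provided:
#' * `"signal-to-noise"`: `LOD = 3 * noise_sd / slope`,
#'   `LOQ = 10 * noise_sd / slope` (noise SD in area units);
#' * `"residual-sd"`: `LOD = 3.3 * s_y / slope`, `LOQ = 10 * s_y / slope`,
#'   using the calibration residual SD.
#'
#' The LOQ/LOD ratio is therefore fixed at 10/3 or 10/3.3 by construction. A
#' validation report should confirm LOD falls below the lowest calibration
#' level.
#'
#' @param fit A [calibration_fit] with positive slope (and dispersions
#'   computed, for the residual method).
#' @param noise_sd Baseline noise SD in area units (signal-to-noise method).
#' @param method `"signal-to-noise"` or `"residual-sd"`.
#' @return An object of class `detection_limits`: list with `lod`, `loq`
#'   (concentration units) and `method`.
#' @export
detection_limits <- function(fit, noise_sd = NULL,
                             method = c("signal-to-noise", "residual-sd")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$a <= 0) stop("slope must be positive")
  if (method == "signal-to-noise") {
    if (is.null(noise_sd) || noise_sd <= 0)
      stop("signal-to-noise method requires a positive noise_sd")
    lod <- 3 * noise_sd / fit$a
    loq <- 10 * noise_sd / fit$a
  } else {
    if (is.na(fit$s_y)) stop("residual-sd method requires dispersions; run regression_dispersions()")
    if (fit$s_y <= 0) stop("residual SD is zero: limits undefined for an exact fit")
    lod <- 3.3 * fit$s_y / fit$a
    loq <- 10 * fit$s_y / fit$a
  }
  structure(list(lod = lod, loq = loq, method = method),
            class = "detection_limits")
}

#' Selectivity verdicts from peak purities
#'
#' A peak is considered pure — and the method selective for that analyte —
#' when its three-point UV purity reaches the threshold (inclusive at exactly
#' the threshold; default 0.95).
#'
#' @param purities Named numeric vector of per-analyte purity fractions in
#'   `[0, 1]`.
#' @param threshold Pass threshold, default 0.95.
#' @return data.frame with `analyte`, `purity`, `pass`.
#' @export
selectivity_report <- function(purities, threshold = 0.95) {
  if (any(purities < 0 | purities > 1)) stop("purities must lie in [0, 1]")
  data.frame(analyte = if (is.null(names(purities)))
    paste0("analyte_", seq_along(purities)) else names(purities),
    purity = as.numeric(purities),
    pass = as.numeric(purities) >= threshold,
    row.names = NULL)
}

#' Assemble a validation report
#'
#' Aggregates the calibration fit, precision results, system suitability,
#' detection limits and selectivity into one serializable report — the
#' package's analogue of a published method-validation summary table. Every
#' pass flag is derivable from the stored numbers and thresholds.
#'
#' @param fit A fully populated [calibration_fit] (see [calibrate()]).
#' @param precision List of [precision()] results (e.g. intraday and interday).
#' @param suitability A [system_suitability()] record.
#' @param limits A [detection_limits()] record.
#' @param selectivity A [selectivity_report()] data.frame.
#' @return An object of class `validation_report`.
#' @export
build_report <- function(fit, precision, suitability, limits, selectivity) {
  missing_of <- function(x, what) if (is.null(x)) stop("missing component: ", what)
  missing_of(fit, "fit"); missing_of(precision, "precision")
  missing_of(suitability, "suitability"); missing_of(limits, "limits")
  missing_of(selectivity, "selectivity")
  stopifnot(inherits(fit, "calibration_fit"), inherits(limits, "detection_limits"))
  if (inherits(precision, "precision_result")) precision <- list(precision)
  structure(list(fit = fit, precision = precision, suitability = suitability,
                 limits = limits, selectivity = selectivity),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(report_markdown(x))
  invisible(x)
}

#' Render a validation report as a Markdown table
#'
#' Produces a compact Markdown summary mirroring the conventional layout of a
#' method-validation table: calibration line with t/F statistics, precision
#' CVs, suitability RSDs and LOD/LOQ.
#'
#' @param report A [build_report()] result.
#' @param digits Rounding for display (default 2).
#' @return A single character string of Markdown.
#' @export
report_markdown <- function(report, digits = 2) {
  stopifnot(inherits(report, "validation_report"))
  f <- report$fit
  rnd <- function(v) formatC(v, format = "f", digits = digits)
  lines <- c(
    "| Parameter | Value | Verdict |",
    "|---|---|---|",
    sprintf("| Analytical curve | y = %.1fx + %.1f, R^2 = %.4f | %s |",
            f$a, f$b, f$r_squared,
            ifelse(isTRUE(f$verdicts$regression), "linear", "not linear")),
    sprintf("| Slope t test | t = %s vs %s | %s |", rnd(f$t_a), rnd(f$t_critical),
            ifelse(isTRUE(f$verdicts$slope), "significant", "not significant")),
    sprintf("| Intercept t test | t = %s vs %s | %s |", rnd(f$t_b), rnd(f$t_critical),
            ifelse(isTRUE(f$verdicts$intercept), "significant", "not significant")),
    sprintf("| Regression F test | F = %s vs %s | %s |", rnd(f$f_stat),
            rnd(f$f_critical),
            ifelse(isTRUE(f$verdicts$regression), "significant", "not significant")))
  for (p in report$precision)
    lines <- c(lines, sprintf("| Precision (%s) | CV = %s%% | n/a |",
                              attr(p, "mode"), rnd(attr(p, "summary_cv"))))
  s <- report$suitability
  lines <- c(lines,
             sprintf("| System suitability | RT RSD %s%%, area RSD %s%% | %s |",
                     rnd(s$rt_rsd), rnd(s$area_rsd),
                     ifelse(isTRUE(s$pass), "pass", "fail")),
             sprintf("| LOD / LOQ (%s) | %s / %s | %s |",
                     report$limits$method, rnd(report$limits$lod),
                     rnd(report$limits$loq),
                     ifelse(report$limits$lod < min(f$x), "below lowest level",
                            "above lowest level")))
  for (i in seq_len(nrow(report$selectivity)))
    lines <- c(lines, sprintf("| Selectivity (%s) | purity %s | %s |",
                              report$selectivity$analyte[i],
                              rnd(report$selectivity$purity[i]),
                              ifelse(report$selectivity$pass[i], "pure", "not pure")))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Serialize a validation report to a plain list (for JSON)
#'
#' The output of this function, written with [jsonlite::write_json()] and read
#' back with [jsonlite::read_json()], reproduces every stored number.
#'
#' @param report A [build_report()] result.
#' @return A named list.
#' @export
report_record <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  list(
    fit = calibration_fit_record(report$fit),
    precision = lapply(report$precision, function(p)
      list(mode = attr(p, "mode"), summary_cv = attr(p, "summary_cv"),
           levels = as.data.frame(p))),
    suitability = report$suitability,
    limits = unclass(report$limits),
    selectivity = report$selectivity)
}
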
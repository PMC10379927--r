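#' Sequential-extraction series
#'
#' Per-extraction peak areas for one sample x analyte, together with the
#' reconstitution volume and extracted powder mass that define the unit chain
#' from vial concentration to dry-weight amount. Defaults (3 mL, 0.5 g) match
#' the standard workup: each sequential extract evaporated and redissolved in
#' 3 mL methanol from 0.5 g of freeze-dried powder.
#'
#' @param records data.frame with columns `sample`, `analyte`, `extraction`
#'   (1-based contiguous ordinals) and `area`.
#' @param volume Reconstitution volume, mL (> 0).
#' @param mass Powder mass, g (> 0).
#' @return An object of class `extraction_series`.
#' @export
extraction_series <- function(records, volume = 3, mass = 0.5) {
  stopifnot(is.data.frame(records),
            all(c("sample", "analyte", "extraction", "area") %in% names(records)))
  if (volume <= 0 || mass <= 0) stop("volume and mass must be positive")
  records <- records[order(records$extraction), , drop = FALSE]
  if (!identical(as.integer(records$extraction), seq_len(nrow(records))))
    stop("extraction indices must be contiguous from 1")
  rownames(records) <- NULL
  structure(list(records = records, volume = volume, mass = mass),
            class = "extraction_series")
}

#' @export
print.extraction_series <- function(x, ...) {
  r <- x$records
  cat(sprintf("<extraction_series> %s / %s: %d extractions (V = %g mL, m = %g g)\n",
              r$sample[1], r$analyte[1], nrow(r), x$volume, x$mass))
  print(r, ...)
  invisible(x)
}

#' Convert a peak area to concentration and dry-weight amount
#'
#' Inverts the calibration line (`conc = (area - b) / a`, ug/mL) and applies
#' the unit chain to the matrix: `amount = conc * volume / mass * 0.1` in
#' mg per 100 g dry weight (the factor 0.1 converts ug/g to mg/100 g).
#' Negative concentrations map to amount 0 and are flagged; concentrations
#' outside the calibration range are flagged `extrapolated`.
#'
#' @param area Peak area(s).
#' @param fit A [calibration_fit].
#' @param volume Reconstitution volume, mL.
#' @param mass Powder mass, g.
#' @return data.frame with `concentration` (ug/mL), `amount` (mg/100 g),
#'   `negative` and `extrapolated` flags.
#' @examples
#' fit <- fit_line(data.frame(level = c(1, 5, 10, 20, 40, 60, 80, 100),
#'                            area = 2333.5 * c(1, 5, 10, 20, 40, 60, 80, 100) + 2956.2))
#' amount_from_area(2333.5 * 36.783 + 2956.2, fit)  # ~22.07 mg/100 g
#' @export
amount_from_area <- function(area, fit, volume = 3, mass = 0.5) {
  if (volume <= 0 || mass <= 0) stop("volume and mass must be positive")
  conc <- invert_calibration(fit, area)
  extrap <- attr(conc, "extrapolated")
  conc <- as.numeric(conc)
  neg <- conc < 0
  amount <- pmax(conc, 0) * volume / mass * 0.1
  data.frame(concentration = conc, amount = amount,
             negative = neg, extrapolated = extrap)
}

#' Quantify an extraction series through a calibration line
#'
#' Adds `concentration`, `amount`, `negative` and `extrapolated` columns to the
#' series records via [amount_from_area()] using the series' own volume and
#' mass.
#'
#' @param series An [extraction_series()].
#' @param fit A [calibration_fit].
#' @return The series with quantified records.
#' @export
quantify_series <- function(series, fit) {
  stopifnot(inherits(series, "extraction_series"))
  q <- amount_from_area(series$records$area, fit,
                        volume = series$volume, mass = series$mass)
  series$records <- cbind(series$records, q)
  series
}

#' Censor quantified records below the limit of quantification
#'
#' Records whose concentration falls below the LOQ are marked censored
#' (a concentration exactly at the LOQ remains quantifiable). Censored records
#' keep their raw areas — recovery percentages are computed from areas of all
#' extractions, censored or not — but their amounts are excluded from totals.
#'
#' @param series A quantified [extraction_series()] (see [quantify_series()]).
#' @param limits A [detection_limits()] record (or a list with `loq`).
#' @return The series with a logical `censored` column.
#' @export
censor <- function(series, limits) {
  stopifnot(inherits(series, "extraction_series"))
  if (is.null(limits$loq) || limits$loq <= 0) stop("limits must provide a positive loq")
  if (!"concentration" %in% names(series$records))
    stop("series must be quantified first (see quantify_series())")
  # strict inequality with a relative guard so a concentration computed to be
  # exactly at the LOQ (up to round-off) stays quantifiable
  series$records$censored <-
    series$records$concentration < limits$loq * (1 - 1e-9)
  series
}

#' Per-extraction recovery percentages from raw areas
#'
#' Recovery of extraction x is its share of the total signal over all
#' sequential extractions: `R% = A_x / sum(A_n) * 100`, computed from raw areas
#' of every record including censored ones. Cumulative recovery is the prefix
#' sum. Per-index values sum to exactly 100 and the cumulative series ends at
#' 100.
#'
#' @param series An [extraction_series()] (raw or quantified) with at least one
#'   positive area.
#' @return An object of class `recovery_matrix`: data.frame with `extraction`,
#'   `recovery` and `cumulative` (percent).
#' @seealso [recovery_from_percent()] for building the same object from
#'   already-reported percentages.
#' @export
recovery_matrix <- function(series) {
  stopifnot(inherits(series, "extraction_series"))
  a <- series$records$area
  total <- sum(a)
  if (total <= 0) stop("all areas are zero: recovery undefined")
  r <- a / total * 100
  structure(data.frame(extraction = series$records$extraction,
                       recovery = r, cumulative = cumsum(r)),
            class = c("recovery_matrix", "data.frame"))
}

#' Recovery matrix from reported per-extraction percentages
#'
#' Builds a [recovery_matrix] directly from per-extraction recovery
#' percentages as they are conventionally reported (rounded to two decimals).
#' The values are taken as final — no renormalization — so the cumulative
#' column is the plain prefix sum, exactly the arithmetic used when summing a
#' published recovery row over the first k extractions. The input must sum to
#' 100 within `tol`; the default of 1.5 accommodates published rows whose
#' rounded entries fall visibly short of 100.
#'
#' @param percent Numeric vector of per-extraction recovery percentages.
#' @param tol Largest tolerated deviation of `sum(percent)` from 100.
#' @return A `recovery_matrix`.
#' @export
recovery_from_percent <- function(percent, tol = 1.5) {
  if (any(percent < 0)) stop("recovery percentages must be non-negative")
  if (abs(sum(percent) - 100) > tol)
    stop(sprintf("recovery percentages must sum to 100 within %g", tol))
  structure(data.frame(extraction = seq_along(percent),
                       recovery = as.numeric(percent),
                       cumulative = cumsum(as.numeric(percent))),
            class = c("recovery_matrix", "data.frame"))
}

#' Number of sequential extractions needed to reach a recovery threshold
#'
#' The smallest k whose cumulative recovery reaches the threshold. With the
#' default 90% threshold, typical exhaustive-extraction depletion patterns are
#' satisfied by two sequential extractions.
#'
#' @param matrix A [recovery_matrix].
#' @param threshold Percent in `(0, 100]` (default 90).
#' @return Integer count of extractions.
#' @export
extractions_needed <- function(matrix, threshold = 90) {
  stopifnot(inherits(matrix, "recovery_matrix"))
  if (threshold <= 0 || threshold > 100) stop("threshold must lie in (0, 100]")
  k <- which(matrix$cumulative >= threshold - 1e-9)
  if (length(k) == 0L)
    stop("cumulative recovery never reaches the threshold")
  as.integer(k[1])
}

#' Per-analyte and per-clone totals across extraction series
#'
#' Totals each sample x analyte by summing the amounts of non-censored
#' extractions (censored records contribute 0), then sums analytes into a
#' per-clone grand total, and reports the min/max grand totals across clones.
#' Clones missing one or more catalog analytes are totalled over the analytes
#' present and flagged incomplete.
#'
#' @param series_list List of quantified, censored [extraction_series()]
#'   objects — or a single data.frame with columns `sample`, `analyte`,
#'   `amount` and `censored` (per-extraction records), or with `sample`,
#'   `analyte` and `total` (per-analyte totals as published, e.g. from
#'   [reference_extraction_amounts()]), from which only the grand totals and
#'   range are derived.
#' @param expected_analytes Optional character vector; clones lacking any of
#'   these are flagged incomplete.
#' @return An object of class `quant_report`: list with `analyte_totals`
#'   (sample, analyte, total, n_quantified), `clone_totals` (sample,
#'   grand_total, incomplete) and `range` (min/max grand totals with their
#'   samples).
#' @export
clone_totals <- function(series_list, expected_analytes = NULL) {
  if (is.data.frame(series_list) && "total" %in% names(series_list) &&
      !"amount" %in% names(series_list)) {
    # already-totalled per-analyte amounts: pass straight through
    recs <- data.frame(sample = series_list$sample,
                       analyte = series_list$analyte,
                       amount = series_list$total, censored = FALSE)
  } else if (is.data.frame(series_list)) {
    recs <- series_list
  } else {
    recs <- do.call(rbind, lapply(series_list, function(s) {
      stopifnot(inherits(s, "extraction_series"))
      if (!all(c("amount", "censored") %in% names(s$records)))
        stop("every series must be quantified and censored first")
      s$records
    }))
  }
  stopifnot(all(c("sample", "analyte", "amount", "censored") %in% names(recs)))
  contrib <- ifelse(recs$censored, 0, recs$amount)
  at <- stats::aggregate(list(total = contrib),
                         by = list(sample = recs$sample, analyte = recs$analyte),
                         FUN = sum)
  nq <- stats::aggregate(list(n_quantified = !recs$censored),
                         by = list(sample = recs$sample, analyte = recs$analyte),
                         FUN = sum)
  at <- merge(at, nq, by = c("sample", "analyte"))
  ct <- stats::aggregate(list(grand_total = at$total),
                         by = list(sample = at$sample), FUN = sum)
  if (!is.null(expected_analytes)) {
    have <- split(at$analyte, at$sample)
    ct$incomplete <- vapply(ct$sample, function(s)
      !all(expected_analytes %in% have[[s]]), logical(1))
  } else ct$incomplete <- FALSE
  i_min <- which.min(ct$grand_total); i_max <- which.max(ct$grand_total)
  structure(list(
    analyte_totals = at[order(at$sample, at$analyte), ],
    clone_totals = ct[order(ct$sample), ],
    range = list(min = ct$grand_total[i_min], min_sample = ct$sample[i_min],
                 max = ct$grand_total[i_max], max_sample = ct$sample[i_max])),
    class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n  per-analyte totals (mg/100 g):\n")
  print(x$analyte_totals, row.names = FALSE)
  cat("  per-clone grand totals:\n")
  print(x$clone_totals, row.names = FALSE)
  cat(sprintf("  range: %.2f (%s) to %.2f (%s)\n",
              x$range$min, x$range$min_sample, x$range$max, x$range$max_sample))
  invisible(x)
}
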
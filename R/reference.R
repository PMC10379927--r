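#' Reference calibration and validation constants for the anacardic-acid method
#'
#' Published summary constants of the validated HPLC-DAD method for the triene
#' anacardic-acid external standard: the calibration line fitted over eight
#' levels (1--100 ug/mL, in triplicate), the reported coefficient standard
#' deviations and tabulated critical values, precision and suitability CVs, and
#' the visually assessed LOD/LOQ. These are worked-example inputs and
#' cross-check metadata, not quantities this package computes; the tabulated
#' critical values in particular are stored as-is and do not match the
#' quantiles at n - 2 degrees of freedom that [calibrate()] computes.
#'
#' @return A list with elements `slope`, `intercept`, `r_squared`, `levels`,
#'   `replicates`, `s_a`, `s_b`, `t_tab`, `f_tab`, `intraday_cv`,
#'   `interday_cv`, `rt_rsd`, `area_rsd`, `lod`, `loq`, `purities`.
#' @export
reference_calibration <- function() {
  list(
    slope = 2333.5, intercept = 2956.2, r_squared = 0.998,
    levels = c(1, 5, 10, 20, 40, 60, 80, 100), replicates = 3,
    s_a = 15.79, s_b = 830.91, t_tab = 2.009, f_tab = 1.576,
    intraday_cv = 0.20, interday_cv = 0.29,
    rt_rsd = 0.45, area_rsd = 0.30,
    lod = 0.18, loq = 0.85,
    purities = c(`AnAc 15:3` = 0.9917, `AnAc 15:2` = 0.9819,
                 `AnAc 15:1` = 0.9940))
}

#' Reference per-extraction amounts for five cashew clones
#'
#' Published quantification of the three anacardic acids over five sequential
#' extractions of cashew peduncle powder from five clones (CCP 09, CCP 76,
#' BRS 265, BRS 275, Embrapa 51), in mg per 100 g dry weight. `NA` marks
#' extractions below the limit of quantification (<LOQ), which contribute
#' nothing to totals; `total` is the published total amount for the row.
#'
#' @return data.frame with columns `sample`, `analyte`, `e1`..`e5`, `total`.
#' @export
reference_extraction_amounts <- function() {
  rows <- list(
    list("CCP 09",     "AnAc 15:3",  22.07,  2.32,    NA,   NA, NA,  24.40),
    list("CCP 09",     "AnAc 15:2",  16.66,  1.81,    NA,   NA, NA,  18.47),
    list("CCP 09",     "AnAc 15:1", 109.88, 14.63,  2.39, 0.81, NA, 127.72),
    list("CCP 76",     "AnAc 15:3",  23.16,  6.34,  1.65,   NA, NA,  31.16),
    list("CCP 76",     "AnAc 15:2",  41.22, 12.01,  3.62,   NA, NA,  56.87),
    list("CCP 76",     "AnAc 15:1",  79.98, 24.07,  7.74, 0.16, NA, 111.96),
    list("BRS 265",    "AnAc 15:3",  39.88,  4.64,  0.23,   NA, NA,  44.76),
    list("BRS 265",    "AnAc 15:2",  33.29,  3.99,  0.10,   NA, NA,  37.38),
    list("BRS 265",    "AnAc 15:1", 115.26, 16.14,  2.33, 1.12, NA, 134.86),
    list("BRS 275",    "AnAc 15:3",  26.88,  2.95,    NA,   NA, NA,  29.83),
    list("BRS 275",    "AnAc 15:2",  17.51,  1.64,    NA,   NA, NA,  19.15),
    list("BRS 275",    "AnAc 15:1",  81.26, 10.45,  1.42, 0.49, NA,  93.63),
    list("Embrapa 51", "AnAc 15:3",  16.56,  3.05,    NA,   NA, NA,  19.62),
    list("Embrapa 51", "AnAc 15:2",  11.66,  2.05,    NA,   NA, NA,  13.71),
    list("Embrapa 51", "AnAc 15:1",  75.95, 16.56,  2.09, 0.40, NA,  95.02))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], analyte = r[[2]], e1 = r[[3]], e2 = r[[4]],
               e3 = r[[5]], e4 = r[[6]], e5 = r[[7]], total = r[[8]],
               stringsAsFactors = FALSE)))
  out
}

#' Reference per-extraction recovery percentages for five cashew clones
#'
#' Published recovery percentages (share of the total summed peak area) of the
#' three anacardic acids over five sequential extractions, per clone. Each row
#' sums to 100 within rounding of the two-decimal entries. These rows feed
#' [recovery_from_percent()] for cumulative-recovery and
#' extraction-exhaustion calculations.
#'
#' @return data.frame with columns `sample`, `analyte`, `r1`..`r5` (percent).
#' @export
reference_recovery <- function() {
  rows <- list(
    list("CCP 09",     "AnAc 15:3", 85.35, 11.42, 2.18, 0.93, 0.11),
    list("CCP 09",     "AnAc 15:2", 83.88, 12.27, 2.56, 1.14, 0.13),
    list("CCP 09",     "AnAc 15:1", 84.51, 11.73, 2.18, 1.17, 0.19),
    list("CCP 76",     "AnAc 15:3", 71.17, 21.05, 7.06, 0.66, 0.03),
    list("CCP 76",     "AnAc 15:2", 70.48, 21.42, 7.30, 0.78, 0.02),
    list("CCP 76",     "AnAc 15:1", 70.25, 21.58, 7.36, 0.77, 0.02),
    list("BRS 265",    "AnAc 15:3", 85.33, 11.26, 2.00, 1.33, 0.05),
    list("BRS 265",    "AnAc 15:2", 84.97, 11.76, 2.03, 1.16, 0.06),
    list("BRS 265",    "AnAc 15:1", 84.15, 12.23, 2.21, 1.33, 0.06),
    list("BRS 275",    "AnAc 15:3", 84.56, 11.33, 2.34, 1.54, 0.22),
    list("BRS 275",    "AnAc 15:2", 84.41, 11.19, 1.90, 1.31, 0.18),
    list("BRS 275",    "AnAc 15:1", 84.73, 11.58, 2.24, 1.29, 0.15),
    list("Embrapa 51", "AnAc 15:3", 78.67, 17.24, 2.74, 1.17, 0.17),
    list("Embrapa 51", "AnAc 15:2", 78.24, 17.56, 2.73, 1.17, 0.28),
    list("Embrapa 51", "AnAc 15:1", 78.13, 17.62, 2.88, 1.15, 0.20))
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], analyte = r[[2]], r1 = r[[3]], r2 = r[[4]],
               r3 = r[[5]], r4 = r[[6]], r5 = r[[7]],
               stringsAsFactors = FALSE)))
}

#' Reference quantified records in long form
#'
#' [reference_extraction_amounts()] reshaped to one record per extraction with
#' an explicit `censored` flag (TRUE for <LOQ cells), ready for
#' [clone_totals()].
#'
#' @return data.frame with columns `sample`, `analyte`, `extraction`, `amount`,
#'   `censored`.
#' @export
reference_extraction_records <- function() {
  wide <- reference_extraction_amounts()
  out <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
    a <- as.numeric(wide[i, paste0("e", 1:5)])
    data.frame(sample = wide$sample[i], analyte = wide$analyte[i],
               extraction = 1:5,
               amount = ifelse(is.na(a), 0, a),
               censored = is.na(a), stringsAsFactors = FALSE)
  }))
  out
}
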
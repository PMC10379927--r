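#' Write a chromatogram to CSV
#'
#' Column layout: `time_min` followed by one column per wavelength named
#' `wl_<nm>` (e.g. `wl_200` .. `wl_400`). Comma separated, period decimal,
#' UTF-8, header required.
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  # 17 significant digits so absorbance values round-trip exactly
  mat <- cbind(chrom$times, chrom$absorbance)
  body <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  header <- paste(c("time_min",
                    sprintf("wl_%d", as.integer(chrom$wavelengths))),
                  collapse = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a chromatogram from CSV
#'
#' Expects the layout written by [write_chromatogram_csv()]: a `time_min`
#' column followed by `wl_<nm>` wavelength columns. Validation is strict —
#' ragged or non-numeric rows, non-monotone or duplicated time stamps and
#' missing wavelength columns are rejected with the offending line where
#' determinable. Locale guessing is deliberately not attempted: a
#' comma-decimal cell is a validation error, not a dialect.
#'
#' @param path CSV file path.
#' @param metadata Optional metadata list to attach (see [chromatogram()]).
#' @return A [chromatogram()].
#' @export
read_chromatogram_csv <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "time_min")
    stop("first column must be 'time_min'")
  wl_cols <- grep("^wl_\\d+$", names(df)[-1], value = TRUE)
  if (length(wl_cols) != ncol(df) - 1L)
    stop("all columns after time_min must be named wl_<nm>")
  if (length(wl_cols) == 0L) stop("no wavelength columns found")
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1]
    stop(sprintf("non-numeric value at data line %d", bad))
  }
  times <- num[, 1]
  d <- diff(times)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1L
    stop(sprintf("time stamps not strictly increasing at data line %d", bad))
  }
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  if (any(diff(wl) <= 0)) stop("wavelength columns must be strictly increasing")
  if (is.null(metadata))
    metadata <- list(sample = basename(path), injection_volume_ul = 20,
                     monitor_wavelength = 280)
  chromatogram(times, wl, num[, -1, drop = FALSE], metadata = metadata)
}

#' Write / read a peak table CSV
#'
#' Columns: `sample`, `analyte`, `apex_rt_min`, `start_min`, `end_min`,
#' `height_mau`, `area_mau_min`, `purity`.
#'
#' @param peaks Peak table as produced by [process_chromatogram()].
#' @param path File path.
#' @return `path` (write) or the peak data.frame (read).
#' @export
write_peak_table_csv <- function(peaks, path) {
  out <- data.frame(sample = peaks$sample, analyte = peaks$analyte,
                    apex_rt_min = peaks$apex_time, start_min = peaks$start_time,
                    end_min = peaks$end_time, height_mau = peaks$height,
                    area_mau_min = peaks$area, purity = peaks$purity)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table_csv
#' @export
read_peak_table_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sample", "analyte", "apex_rt_min", "start_min", "end_min",
            "height_mau", "area_mau_min", "purity")
  if (!all(need %in% names(df)))
    stop("peak table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  data.frame(sample = df$sample, analyte = df$analyte,
             apex_time = df$apex_rt_min, start_time = df$start_min,
             end_time = df$end_min, height = df$height_mau,
             area = df$area_mau_min, purity = df$purity)
}

#' Write / read a calibration CSV
#'
#' Columns: `concentration_ug_ml`, `replicate`, `area` (plus optional `day`).
#'
#' @param series Calibration data.frame with `level`, `replicate`, `area`.
#' @param path File path.
#' @return `path` (write) or a data.frame with `level`, `replicate`, `area`
#'   (and `day` if present) on read.
#' @export
write_calibration_csv <- function(series, path) {
  out <- data.frame(concentration_ug_ml = series$level,
                    replicate = series$replicate, area = series$area)
  if ("day" %in% names(series)) out$day <- series$day
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("concentration_ug_ml", "area") %in% names(df)))
    stop("calibration CSV needs columns concentration_ug_ml and area")
  out <- data.frame(level = df$concentration_ug_ml,
                    replicate = if ("replicate" %in% names(df)) df$replicate
                    else seq_len(nrow(df)),
                    area = df$area)
  if ("day" %in% names(df)) out$day <- df$day
  out
}

#' Write / read an extraction-series CSV
#'
#' Columns: `sample`, `analyte`, `extraction_index`, `area`. One file may hold
#' many sample x analyte series; [read_extraction_csv()] splits them into
#' [extraction_series()] objects.
#'
#' @param series_list List of [extraction_series()] (or one of them).
#' @param path File path.
#' @param volume,mass Unit-chain constants applied to every series on read.
#' @return `path` (write) or a named list of [extraction_series()] on read.
#' @export
write_extraction_csv <- function(series_list, path) {
  if (inherits(series_list, "extraction_series")) series_list <- list(series_list)
  recs <- do.call(rbind, lapply(series_list, function(s) s$records))
  out <- data.frame(sample = recs$sample, analyte = recs$analyte,
                    extraction_index = recs$extraction, area = recs$area)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_extraction_csv
#' @export
read_extraction_csv <- function(path, volume = 3, mass = 0.5) {
  df <- utils::read.csv(path)
  need <- c("sample", "analyte", "extraction_index", "area")
  if (!all(need %in% names(df)))
    stop("extraction CSV needs columns: ", paste(need, collapse = ", "))
  keys <- interaction(df$sample, df$analyte, drop = TRUE)
  out <- lapply(split(df, keys), function(g)
    extraction_series(data.frame(sample = g$sample, analyte = g$analyte,
                                 extraction = g$extraction_index,
                                 area = g$area, stringsAsFactors = FALSE),
                      volume = volume, mass = mass))
  out
}

#' Study configuration
#'
#' One object holding the tunables of a whole study: analyte catalog,
#' calibration levels, the unit chain, decision thresholds, the LOD/LOQ
#' method and the master seed. Serializes to YAML and back losslessly (the
#' catalog is rebuilt from its numeric fields).
#'
#' @param catalog List of [analyte_def()]s.
#' @param calibration_levels Concentration levels, ug/mL.
#' @param volume,mass Unit chain: reconstitution volume (mL), powder mass (g).
#' @param purity_threshold Selectivity threshold (default 0.95).
#' @param suitability_rsd System-suitability RSD threshold, percent.
#' @param recovery_threshold Extraction-exhaustion threshold, percent.
#' @param confidence Confidence level for calibration tests.
#' @param lod_method `"signal-to-noise"` or `"residual-sd"`.
#' @param seed Master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(catalog = anac_catalog(),
                         calibration_levels = c(1, 5, 10, 20, 40, 60, 80, 100),
                         volume = 3, mass = 0.5,
                         purity_threshold = 0.95, suitability_rsd = 2,
                         recovery_threshold = 90, confidence = 0.95,
                         lod_method = "signal-to-noise", seed = 1L) {
  stopifnot(purity_threshold > 0, purity_threshold <= 1,
            suitability_rsd > 0, recovery_threshold > 0,
            recovery_threshold <= 100, confidence > 0, confidence < 1,
            volume > 0, mass > 0)
  lod_method <- match.arg(lod_method, c("signal-to-noise", "residual-sd"))
  structure(list(catalog = catalog, calibration_levels = calibration_levels,
                 volume = volume, mass = mass,
                 purity_threshold = purity_threshold,
                 suitability_rsd = suitability_rsd,
                 recovery_threshold = recovery_threshold,
                 confidence = confidence, lod_method = lod_method,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `path` (write) or a [study_config()] on read.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  lst <- unclass(config)
  lst$catalog <- lapply(config$catalog, function(a)
    list(name = a$name, retention_time = a$retention_time,
         molecular_weight = a$molecular_weight, expected_mz = a$expected_mz,
         uv_wavelengths = a$uv_profile$wavelengths,
         uv_values = a$uv_profile$values))
  # 17 significant digits so numeric fields round-trip exactly
  yaml::write_yaml(lst, path, precision = 17)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  catalog <- lapply(lst$catalog, function(a)
    analyte_def(a$name, a$retention_time, a$molecular_weight, a$expected_mz,
                uv_spectrum(a$uv_wavelengths, a$uv_values)))
  names(catalog) <- vapply(catalog, `[[`, character(1), "name")
  study_config(catalog = catalog,
               calibration_levels = unlist(lst$calibration_levels),
               volume = lst$volume, mass = lst$mass,
               purity_threshold = lst$purity_threshold,
               suitability_rsd = lst$suitability_rsd,
               recovery_threshold = lst$recovery_threshold,
               confidence = lst$confidence, lod_method = lst$lod_method,
               seed = lst$seed)
}

#' Digest of a study configuration
#'
#' MD5 of the canonical JSON serialization, with numerics rounded to 10
#' significant digits so a round trip through the YAML representation leaves
#' the digest unchanged; semantically identical configs produce identical
#' digests. Emitted artifacts can reference it to tie a result to the
#' configuration that produced it.
#'
#' @param config A [study_config()].
#' @return A 32-character hex string.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "study_config"))
  canon <- rapply(unclass(config),
                  function(v) if (is.double(v)) signif(v, 10) else v,
                  how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  f <- file(tmp, "wb")
  writeLines(jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  close(f)
  unname(tools::md5sum(tmp))
}

#' Run log
#'
#' Minimal provenance record: timestamped stage events, the config digest and
#' the package version. Appended to by pipeline stages; serialized with the
#' report JSON.
#'
#' @param config A [study_config()].
#' @return An environment of class `run_log` with `log_event(log, stage, msg)`
#'   entries under `$events`.
#' @export
run_log <- function(config) {
  e <- new.env(parent = emptyenv())
  e$config_digest <- config_digest(config)
  e$version <- as.character(utils::packageVersion("anacardiq"))
  e$events <- list()
  class(e) <- "run_log"
  e
}

#' @rdname run_log
#' @param log A `run_log`.
#' @param stage Stage name.
#' @param msg Event message.
#' @export
log_event <- function(log, stage, msg) {
  stopifnot(inherits(log, "run_log"))
  log$events[[length(log$events) + 1L]] <-
    list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage,
         message = msg)
  invisible(log)
}

#' Write a validation or quantification report as JSON
#'
#' @param record A plain list (see [report_record()],
#'   [calibration_fit_record()]) or any JSON-representable structure.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
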
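#' DAD chromatogram container
#'
#' A diode-array chromatogram: absorbance sampled on a strictly increasing time
#' grid (minutes) by a strictly increasing wavelength grid (nm), with
#' acquisition metadata. The monitor wavelength (default 280 nm) is the channel
#' used for quantitative peak processing.
#'
#' @param times Strictly increasing time points in minutes.
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param absorbance Numeric matrix, `length(times)` rows by
#'   `length(wavelengths)` columns, in mAU; no missing values.
#' @param metadata List: `sample`, `injection_volume_ul`,
#'   `monitor_wavelength` (nm).
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(times, wavelengths, absorbance,
                         metadata = list(sample = NA_character_,
                                         injection_volume_ul = 20,
                                         monitor_wavelength = 280)) {
  times <- as.numeric(times); wavelengths <- as.numeric(wavelengths)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(times) || ncol(absorbance) != length(wavelengths))
    stop("absorbance matrix dimensions must match the time and wavelength axes")
  if (anyNA(absorbance)) stop("absorbance must not contain missing values")
  if (is.null(metadata$monitor_wavelength)) metadata$monitor_wavelength <- 280
  structure(list(times = times, wavelengths = wavelengths,
                 absorbance = absorbance, metadata = metadata),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d x %d (%.2f-%.2f min, %g-%g nm), monitor %g nm\n",
              ifelse(is.na(x$metadata$sample), "?", x$metadata$sample),
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$times), max(x$times),
              min(x$wavelengths), max(x$wavelengths),
              x$metadata$monitor_wavelength))
  invisible(x)
}

#' Plot the monitor-wavelength trace of a chromatogram
#'
#' @param x A [chromatogram()].
#' @param wavelength Channel to plot, nm; defaults to the monitor wavelength.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.chromatogram <- function(x, wavelength = x$metadata$monitor_wavelength, ...) {
  plot(x$times, monitor_trace(x, wavelength), type = "l",
       xlab = "time (min)", ylab = sprintf("absorbance at %g nm (mAU)", wavelength),
       ...)
  invisible(x)
}

#' Extract one wavelength channel as a time series
#'
#' @param chrom A [chromatogram()].
#' @param wavelength Channel in nm; must be on the grid (nearest used if not).
#' @return Numeric vector of absorbance over `chrom$times`.
#' @export
monitor_trace <- function(chrom, wavelength = chrom$metadata$monitor_wavelength) {
  stopifnot(inherits(chrom, "chromatogram"))
  j <- which.min(abs(chrom$wavelengths - wavelength))
  chrom$absorbance[, j]
}

#' Estimate the chromatographic baseline of a single-wavelength trace
#'
#' Morphological opening (rolling minimum then rolling maximum over the same
#' window) followed by rolling-mean smoothing. The opening flattens features
#' narrower than the window (peaks) while preserving constant and linear
#' baselines; edges are handled by linearly extrapolating the trace before
#' applying the windows. The window must be wider than the peaks.
#'
#' @param trace Numeric absorbance trace, mAU.
#' @param times Matching strictly increasing time vector, minutes.
#' @param window Structuring window width in minutes (default 2); must exceed
#'   the widest peak and be shorter than the run.
#' @return Numeric baseline vector of the same length.
#' @export
estimate_baseline <- function(trace, times, window = 2) {
  stopifnot(length(trace) == length(times), all(is.finite(trace)))
  span <- diff(range(times))
  if (window >= span) stop("baseline window must be shorter than the run")
  if (window <= 0) stop("baseline window must be positive")
  dt <- mean(diff(times))
  k <- max(3L, 2L * floor(window / (2 * dt)) + 1L)  # odd window in points
  h <- (k - 1L) %/% 2L
  sm_k <- max(3L, 2L * floor(h / 2L) + 1L)
  sm_h <- (sm_k - 1L) %/% 2L
  p <- 2L * h + sm_h + 2L  # pad width covering erosion + dilation + smoothing
  n <- length(trace)
  # pad by linear extrapolation of the outer window at each end
  m <- min(n, k)
  fit_lo <- stats::lm.fit(cbind(1, seq_len(m)), trace[seq_len(m)])$coefficients
  fit_hi <- stats::lm.fit(cbind(1, seq_len(m)), trace[(n - m + 1):n])$coefficients
  pad_lo <- fit_lo[1] + fit_lo[2] * (1 - p):0
  pad_hi <- fit_hi[1] + fit_hi[2] * (m + 1):(m + p)
  x <- c(pad_lo, trace, pad_hi)
  opened <- zoo::rollapply(zoo::rollapply(x, k, min, align = "center", fill = NA),
                           k, max, align = "center", fill = NA)
  out <- zoo::rollapply(opened, sm_k, mean, align = "center", fill = NA)
  as.numeric(out[(p + 1):(p + n)])
}

#' Detect peaks on a baseline-corrected trace
#'
#' Apexes are local maxima whose baseline-corrected height is at least
#' `min_snr` times the noise SD (estimated robustly from first differences
#' unless supplied). Apex location uses a lightly smoothed copy of the trace
#' (5-point rolling mean) so sampling noise cannot split or displace maxima.
#' Peak boundaries are walked outward from each apex to the nearer of the
#' baseline re-crossing (signal falling below 3 noise SD) or a local minimum
#' (valley between fused peaks); peaks are reported sorted by apex time.
#'
#' @param trace Baseline-corrected absorbance trace, mAU.
#' @param times Matching time vector, minutes.
#' @param min_snr Minimum apex signal-to-noise ratio (default 10).
#' @param min_width Minimum peak width in minutes (default 0.02).
#' @param noise_sd Optional known noise SD; estimated if `NULL`.
#' @return data.frame with columns `apex_time`, `start_time`, `end_time`,
#'   `height` (one row per peak; zero rows if nothing qualifies).
#' @export
detect_peaks <- function(trace, times, min_snr = 10, min_width = 0.02,
                         noise_sd = NULL) {
  stopifnot(length(trace) == length(times))
  if (is.null(noise_sd))
    noise_sd <- stats::mad(diff(trace)) / sqrt(2)
  floor_sd <- max(noise_sd, 1e-12)
  threshold <- min_snr * floor_sd
  dt <- mean(diff(times))
  min_pts <- max(3L, ceiling(min_width / dt))
  empty <- data.frame(apex_time = numeric(0), start_time = numeric(0),
                      end_time = numeric(0), height = numeric(0))
  n <- length(trace)
  sm <- if (n >= 5L) zoo::rollmean(trace, 5L, fill = "extend") else trace
  if (all(sm <= threshold)) return(empty)
  pk <- pracma::findpeaks(sm, minpeakheight = threshold,
                          minpeakdistance = min_pts, zero = "+")
  if (is.null(pk)) return(empty)
  pk <- matrix(pk, ncol = 4)
  walk <- function(apex, dir) {
    i <- apex
    minval <- sm[apex]; minidx <- apex
    repeat {
      nxt <- i + dir
      if (nxt < 1L || nxt > n) return(i)
      v <- sm[nxt]
      if (v < 3 * floor_sd) return(nxt)
      if (v < minval) { minval <- v; minidx <- nxt }
      else if (v > minval + 5 * floor_sd) return(minidx)
      i <- nxt
    }
  }
  out <- lapply(seq_len(nrow(pk)), function(r) {
    apex <- pk[r, 2]
    lo <- walk(apex, -1L)
    hi <- walk(apex, +1L)
    data.frame(apex_time = times[apex], start_time = times[lo],
               end_time = times[hi], height = sm[apex])
  })
  res <- do.call(rbind, out)
  res <- res[res$end_time - res$start_time >= min_width, , drop = FALSE]
  res[order(res$apex_time), , drop = FALSE]
}

#' Integrate a peak by the trapezoidal rule
#'
#' Trapezoidal integral of the baseline-corrected trace between `start` and
#' `end` (inclusive of grid samples within the bounds), with negative
#' corrected values clipped to zero. Units mAU * min.
#'
#' @param trace Raw absorbance trace, mAU.
#' @param baseline Baseline of the same length (0 for already-corrected data).
#' @param times Time vector, minutes.
#' @param start,end Integration bounds in minutes, `start < end`, inside the run.
#' @return Peak area in mAU * min (0 for a degenerate interval).
#' @export
integrate_peak <- function(trace, baseline, times, start, end) {
  stopifnot(length(trace) == length(times))
  if (length(baseline) == 1L) baseline <- rep(baseline, length(trace))
  stopifnot(length(baseline) == length(trace))
  if (start > end) stop("integration bounds are reversed")
  if (start < min(times) || end > max(times))
    stop("integration bounds lie outside the time range")
  idx <- which(times >= start & times <= end)
  if (length(idx) < 2L) return(0)
  y <- pmax(trace[idx] - baseline[idx], 0)
  pracma::trapz(times[idx], y)
}

#' Match detected peaks to the analyte catalog by retention time
#'
#' Each peak is assigned to the catalog analyte whose retention time is nearest
#' and within `rt_tolerance`; peaks with no analyte in tolerance stay
#' unassigned. An analyte claims at most one peak: the nearest by absolute
#' retention-time difference wins, with ties broken in favour of the larger
#' area; losing peaks are left unassigned and flagged `ambiguous`.
#'
#' @param peaks data.frame with at least `apex_time` and `area` columns.
#' @param catalog List of [analyte_def()] objects whose retention times are
#'   pairwise separated by more than `2 * rt_tolerance`.
#' @param rt_tolerance Matching half-window in minutes (default 0.2).
#' @return `peaks` with added columns `analyte` (character, `NA` if unassigned)
#'   and `ambiguous` (logical).
#' @export
match_peaks <- function(peaks, catalog, rt_tolerance = 0.2) {
  rts <- vapply(catalog, `[[`, numeric(1), "retention_time")
  names(rts) <- vapply(catalog, `[[`, character(1), "name")
  if (length(rts) > 1 && min(diff(sort(rts))) <= 2 * rt_tolerance)
    stop("catalog retention times must be separated by more than 2 * rt_tolerance")
  peaks$analyte <- NA_character_
  peaks$ambiguous <- FALSE
  if (nrow(peaks) == 0L) return(peaks)
  for (a in names(rts)) {
    d <- abs(peaks$apex_time - rts[[a]])
    cand <- which(d <= rt_tolerance & is.na(peaks$analyte))
    if (length(cand) == 0L) next
    best <- cand[order(d[cand], -peaks$area[cand])][1]
    peaks$analyte[best] <- a
    losers <- setdiff(cand, best)
    peaks$ambiguous[losers] <- TRUE
  }
  peaks
}

#' Extract the UV spectrum at a time point
#'
#' Returns the absorbance-matrix row at the sample nearest to `time`
#' (nearest-sample convention, no interpolation), optionally corrected by
#' subtracting the mean of the rows at `baseline_times` (typically the peak
#' start and end, giving a local per-wavelength baseline).
#'
#' @param chrom A [chromatogram()].
#' @param time Time in minutes, within the run.
#' @param baseline_times Optional times whose mean spectrum is subtracted.
#' @return A [uv_spectrum].
#' @export
extract_spectrum <- function(chrom, time, baseline_times = NULL) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (time < min(chrom$times) || time > max(chrom$times))
    stop("time lies outside the run")
  row_at <- function(t) chrom$absorbance[which.min(abs(chrom$times - t)), ]
  v <- row_at(time)
  if (!is.null(baseline_times)) {
    bl <- rowMeans(vapply(baseline_times, row_at,
                          numeric(length(chrom$wavelengths))))
    v <- v - bl
  }
  uv_spectrum(chrom$wavelengths, v)
}

#' Three-point UV peak purity
#'
#' Selectivity evidence that a peak contains a single compound: the spectrum at
#' the apex and at the two half-height crossings (up-slope and down-slope) is
#' compared to a reference spectrum by cosine similarity over 220--400 nm after
#' local baseline correction (subtracting the mean spectrum at the peak
#' bounds). The reported purity is the minimum of the three similarities,
#' clipped to `[0, 1]`. Values of 0.95 and above are conventionally taken as
#' pure.
#'
#' @param chrom A [chromatogram()].
#' @param peak One-row data.frame (or list) with `apex_time`, `start_time`,
#'   `end_time`.
#' @param reference Reference [uv_spectrum] on the chromatogram's grid.
#' @param range Wavelength window for the comparison, default `c(220, 400)`.
#' @return Purity fraction in `[0, 1]`, with attribute `points` giving the
#'   three similarities and attribute `fallback` TRUE when a half-height
#'   crossing was not found inside the bounds (bound used instead).
#' @export
peak_purity <- function(chrom, peak, reference, range = c(220, 400)) {
  stopifnot(inherits(chrom, "chromatogram"))
  apex <- peak$apex_time; lo <- peak$start_time; hi <- peak$end_time
  if (lo >= apex || apex >= hi) stop("peak bounds must bracket the apex")
  trace <- monitor_trace(chrom)
  idx <- which(chrom$times >= lo & chrom$times <= hi)
  seg_t <- chrom$times[idx]; seg_y <- trace[idx]
  base_level <- mean(c(seg_y[1], seg_y[length(seg_y)]))
  apex_i <- which.min(abs(seg_t - apex))
  half <- base_level + (seg_y[apex_i] - base_level) / 2
  fallback <- FALSE
  up <- which(seg_t < apex & seg_y <= half)
  t_up <- if (length(up)) seg_t[max(up)] else { fallback <- TRUE; lo }
  dn <- which(seg_t > apex & seg_y <= half)
  t_dn <- if (length(dn)) seg_t[min(dn)] else { fallback <- TRUE; hi }
  bt <- c(lo, hi)
  sims <- vapply(c(apex, t_up, t_dn), function(t) {
    s <- extract_spectrum(chrom, t, baseline_times = bt)
    cosine_similarity(s, reference, range = range)
  }, numeric(1))
  purity <- min(pmax(pmin(sims, 1), 0))
  structure(purity, points = stats::setNames(sims, c("apex", "up", "down")),
            fallback = fallback)
}

#' Full chromatogram-to-peak-table pipeline
#'
#' Convenience wrapper: estimates the baseline at the monitor wavelength,
#' detects peaks, integrates each, matches them to the analyte catalog, and
#' scores three-point purity against each assigned analyte's reference profile.
#'
#' @param chrom A [chromatogram()].
#' @param catalog List of [analyte_def()]s (default [anac_catalog()]).
#' @param min_snr,min_width,window,rt_tolerance Tuning passed to the stages.
#' @return A peak-table data.frame: `sample`, `analyte`, `apex_time`,
#'   `start_time`, `end_time`, `height`, `area`, `purity`, `ambiguous`.
#' @export
process_chromatogram <- function(chrom, catalog = anac_catalog(),
                                 min_snr = 10, min_width = 0.02,
                                 window = 2, rt_tolerance = 0.2) {
  trace <- monitor_trace(chrom)
  bl <- estimate_baseline(trace, chrom$times, window = window)
  corrected <- trace - bl
  peaks <- detect_peaks(corrected, chrom$times, min_snr = min_snr,
                        min_width = min_width)
  if (nrow(peaks) == 0L) {
    return(data.frame(sample = character(0), analyte = character(0),
                      apex_time = numeric(0), start_time = numeric(0),
                      end_time = numeric(0), height = numeric(0),
                      area = numeric(0), purity = numeric(0),
                      ambiguous = logical(0)))
  }
  peaks$area <- vapply(seq_len(nrow(peaks)), function(i)
    integrate_peak(trace, bl, chrom$times, peaks$start_time[i],
                   peaks$end_time[i]), numeric(1))
  peaks <- match_peaks(peaks, catalog, rt_tolerance = rt_tolerance)
  peaks$purity <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    if (is.na(peaks$analyte[i])) next
    ref <- catalog[[peaks$analyte[i]]]$uv_profile
    peaks$purity[i] <- as.numeric(peak_purity(chrom, peaks[i, ], ref))
  }
  cbind(sample = chrom$metadata$sample %||% NA_character_, peaks,
        stringsAsFactors = FALSE)[, c("sample", "analyte", "apex_time",
                                      "start_time", "end_time", "height",
                                      "area", "purity", "ambiguous")]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
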
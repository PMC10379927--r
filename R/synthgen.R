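#' Recipe for a synthetic DAD chromatogram
#'
#' Bundles everything needed to simulate one injection: the analyte catalog,
#' per-analyte concentrations, the detector response line at 280 nm, peak shape,
#' baseline, noise and the acquisition grid. The signal model is a sum of
#' (exponentially modified) Gaussian peaks in time, each scaled across
#' wavelength by its analyte's UV profile, on a linear baseline with additive
#' i.i.d. Gaussian noise.
#'
#' The default response line (2333.5 area units per ug/mL, intercept 2956.2)
#' and 30-min run reflect an isocratic C18 anacardic-acid separation monitored
#' at 280 nm. Peak area at 280 nm for concentration x is
#' `response_slope * x + response_intercept` (zero concentration produces no
#' peak), and the peak amplitude is `area / (sigma * sqrt(2*pi))`.
#'
#' @param analytes List of [analyte_def()] objects.
#' @param concentrations Numeric vector of concentrations (ug/mL), one per
#'   analyte; 0 suppresses the peak.
#' @param response_slope Detector response slope, area units per ug/mL.
#' @param response_intercept Detector response intercept, area units.
#' @param peak_sigma Gaussian SD of peaks in minutes (scalar or per analyte).
#' @param tailing_tau Exponential tailing constant in minutes; 0 = pure
#'   Gaussian.
#' @param noise_sd SD of additive detector noise, mAU.
#' @param baseline_offset Constant baseline, mAU.
#' @param baseline_drift Linear baseline drift, mAU per minute.
#' @param rt_jitter_sd Per-injection retention-time jitter SD, minutes.
#' @param sampling_rate Acquisition rate, points per minute.
#' @param run_length Run length, minutes; must cover the last peak + 3 sigma.
#' @param seed Integer seed for reproducible simulation.
#' @return An object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(analytes = anac_catalog(),
                              concentrations = c(40, 40, 40),
                              response_slope = 2333.5,
                              response_intercept = 2956.2,
                              peak_sigma = 0.1,
                              tailing_tau = 0,
                              noise_sd = 0.2,
                              baseline_offset = 2,
                              baseline_drift = 0,
                              rt_jitter_sd = 0.02,
                              sampling_rate = 100,
                              run_length = 30,
                              seed = 1L) {
  stopifnot(length(analytes) >= 1L,
            all(vapply(analytes, inherits, logical(1), "analyte_def")),
            length(concentrations) == length(analytes),
            all(concentrations >= 0))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (rt_jitter_sd < 0) stop("rt_jitter_sd must be >= 0")
  sig <- rep_len(peak_sigma, length(analytes))
  tau <- rep_len(tailing_tau, length(analytes))
  if (any(sig <= 0)) stop("peak_sigma must be positive")
  if (any(tau < 0)) stop("tailing_tau must be >= 0")
  rts <- vapply(analytes, `[[`, numeric(1), "retention_time")
  if (run_length < max(rts) + 3 * max(sig))
    stop("run_length must cover the last retention time plus 3 peak widths")
  structure(
    list(analytes = analytes, concentrations = as.numeric(concentrations),
         response_slope = response_slope,
         response_intercept = response_intercept,
         peak_sigma = sig, tailing_tau = tau, noise_sd = noise_sd,
         baseline_offset = baseline_offset, baseline_drift = baseline_drift,
         rt_jitter_sd = rt_jitter_sd, sampling_rate = sampling_rate,
         run_length = run_length, seed = as.integer(seed)),
    class = "simulation_recipe")
}

# Peak profile with unit Gaussian amplitude: pure Gaussian for tau = 0, else
# exponentially modified Gaussian (area A*sigma*sqrt(2*pi) in both cases).
emg_profile <- function(t, mu, sigma, tau) {
  if (tau <= 0) return(exp(-0.5 * ((t - mu) / sigma)^2))
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  sigma / tau * sqrt(pi / 2) *
    exp(0.5 * (sigma / tau)^2 - (t - mu) / tau) * pracma::erfc(z)
}

#' Simulate a DAD chromatogram with known ground truth
#'
#' Generates a time-by-wavelength absorbance matrix following the recipe's
#' signal model, together with a truth manifest listing, per analyte, the exact
#' (jittered) retention time, the analytic peak area at the monitor wavelength
#' (`amplitude * sigma * sqrt(2*pi)`), the amplitude and shape parameters, and
#' whether the peak overlaps a neighbour (apex spacing below 2 sigma).
#' The same recipe and seed reproduce the output exactly.
#'
#' @param recipe A [simulation_recipe()].
#' @param seed Optional override of `recipe$seed`.
#' @return A list with elements `chromatogram` (a [chromatogram()]) and `truth`
#'   (a data.frame with columns `analyte`, `true_rt`, `true_area`, `amplitude`,
#'   `width_sigma`, `tailing_tau`, `overlap`).
#' @export
simulate_chromatogram <- function(recipe, seed = NULL) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(if (is.null(seed)) recipe$seed else as.integer(seed))
  times <- seq(0, recipe$run_length, by = 1 / recipe$sampling_rate)
  wl <- 200:400
  nt <- length(times); nw <- length(wl)
  absorb <- matrix(recipe$baseline_offset + recipe$baseline_drift * times,
                   nrow = nt, ncol = nw)
  k <- length(recipe$analytes)
  truth <- data.frame(analyte = character(k), true_rt = numeric(k),
                      true_area = numeric(k), amplitude = numeric(k),
                      width_sigma = recipe$peak_sigma,
                      tailing_tau = recipe$tailing_tau,
                      overlap = logical(k), stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    an <- recipe$analytes[[i]]
    conc <- recipe$concentrations[i]
    mu <- an$retention_time +
      if (recipe$rt_jitter_sd > 0) stats::rnorm(1, 0, recipe$rt_jitter_sd) else 0
    area <- if (conc > 0)
      recipe$response_slope * conc + recipe$response_intercept else 0
    amp <- area / (recipe$peak_sigma[i] * sqrt(2 * pi))
    truth$analyte[i] <- an$name
    truth$true_rt[i] <- mu
    truth$true_area[i] <- area
    truth$amplitude[i] <- amp
    if (amp > 0) {
      shape <- emg_profile(times, mu, recipe$peak_sigma[i], recipe$tailing_tau[i])
      # scale UV profile so the 280 nm channel carries the stated amplitude
      prof <- an$uv_profile
      stopifnot(identical(prof$wavelengths, as.numeric(wl)) ||
                  all(prof$wavelengths == wl))
      ref280 <- prof$values[match(280, prof$wavelengths)]
      if (is.na(ref280) || ref280 <= 0)
        stop("analyte UV profile must be positive at the 280 nm monitor wavelength")
      absorb <- absorb + amp * outer(shape, prof$values / ref280)
    }
  }
  rts <- truth$true_rt[truth$true_area > 0]
  if (length(rts) > 1) {
    spacing <- diff(sort(rts))
    close_pairs <- any(spacing < 2 * max(recipe$peak_sigma))
    if (close_pairs) {
      ord <- order(truth$true_rt)
      gap_lo <- c(Inf, diff(truth$true_rt[ord]))
      gap_hi <- c(diff(truth$true_rt[ord]), Inf)
      truth$overlap[ord] <- pmin(gap_lo, gap_hi) < 2 * max(recipe$peak_sigma) &
        truth$true_area[ord] > 0
    }
  }
  if (recipe$noise_sd > 0)
    absorb <- absorb + matrix(stats::rnorm(nt * nw, 0, recipe$noise_sd), nt, nw)
  chrom <- chromatogram(times, wl, absorb,
                        metadata = list(sample = "synthetic",
                                        injection_volume_ul = 20,
                                        monitor_wavelength = 280))
  list(chromatogram = chrom, truth = truth)
}

#' Simulate an external-standard calibration series
#'
#' Produces replicate peak areas at each concentration level following a linear
#' detector response with multiplicative Gaussian noise of relative SD
#' `cv_target`. The defaults reproduce the study design: eight levels
#' (1--100 ug/mL) in triplicate on a line with slope 2333.5 and intercept
#' 2956.2, replicate scatter giving sub-1% coefficients of variation.
#'
#' @param levels Concentration levels in ug/mL (positive, distinct).
#' @param replicates Injections per level (>= 1).
#' @param slope,intercept True response line (area units per ug/mL; area units).
#' @param cv_target Relative SD of replicate areas (>= 0).
#' @param seed Integer seed.
#' @param day Optional day label attached to every row (for interday designs).
#' @return A data.frame with columns `level`, `replicate`, `area` (and `day` if
#'   given), carrying the true line as attributes `slope` and `intercept`.
#' @export
simulate_calibration_series <- function(levels = c(1, 5, 10, 20, 40, 60, 80, 100),
                                        replicates = 3, slope = 2333.5,
                                        intercept = 2956.2, cv_target = 0.002,
                                        seed = 1L, day = NULL) {
  if (any(levels <= 0) || anyDuplicated(levels))
    stop("levels must be positive and distinct")
  if (replicates < 1) stop("replicates must be >= 1")
  if (cv_target < 0) stop("cv_target must be >= 0")
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(replicates), level = levels)
  mu <- slope * grid$level + intercept
  area <- mu * (1 + stats::rnorm(nrow(grid), 0, cv_target))
  out <- data.frame(level = grid$level, replicate = grid$replicate, area = area)
  if (!is.null(day)) out$day <- day
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  out
}

#' Sequential-extraction depletion profile
#'
#' Describes how an analyte depletes over sequential extractions of one sample:
#' a total extractable amount and, for each step, the fraction of the analyte
#' *remaining* at that point that the step removes. Step efficiencies applied
#' to the remaining pool (rather than a fixed geometric ratio) reproduce the
#' non-geometric depletion patterns seen in real exhaustive extractions.
#'
#' @param total_amount Total extractable amount, mg per 100 g dry weight.
#' @param step_efficiencies Fractions in `[0, 1]`, one per extraction step.
#' @return An object of class `depletion_profile`.
#' @seealso [depletion_from_fractions()] to recover efficiencies from observed
#'   per-step shares; [step_amounts()] for the implied per-step amounts.
#' @export
depletion_profile <- function(total_amount, step_efficiencies) {
  if (total_amount <= 0) stop("total_amount must be positive")
  if (any(step_efficiencies < 0 | step_efficiencies > 1))
    stop("step efficiencies must lie in [0, 1]")
  structure(list(total_amount = total_amount,
                 step_efficiencies = as.numeric(step_efficiencies)),
            class = "depletion_profile")
}

#' Per-step amounts implied by a depletion profile
#'
#' Step k removes `e_k` of the pool remaining after steps 1..k-1, so its amount
#' is `total * e_k * prod(1 - e_j, j < k)`. The amounts sum to the total exactly
#' when the last efficiency is 1 and never exceed it otherwise.
#'
#' @param profile A [depletion_profile()].
#' @return Numeric vector of per-step amounts (same units as `total_amount`).
#' @export
step_amounts <- function(profile) {
  stopifnot(inherits(profile, "depletion_profile"))
  e <- profile$step_efficiencies
  remaining <- cumprod(c(1, 1 - e))[seq_along(e)]
  profile$total_amount * e * remaining
}

#' Solve step efficiencies from observed per-step shares
#'
#' Inverts the depletion model: given the fraction of the total recovered at
#' each step (e.g. a row of reported per-extraction recovery percentages
#' divided by 100), returns the per-step efficiencies by sequential division of
#' each share by the pool remaining before that step.
#'
#' @param fractions Per-step shares of the total, summing to <= 1 (small
#'   rounding excess is tolerated and rescaled).
#' @param total_amount Total amount for the resulting profile.
#' @return A [depletion_profile()] whose [step_amounts()] reproduce
#'   `fractions * total_amount`.
#' @export
depletion_from_fractions <- function(fractions, total_amount = 1) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  s <- sum(fractions)
  if (s > 1 + 1e-6) {
    if (s > 1.01) stop("fractions must sum to <= 1")
    fractions <- fractions / s
  }
  e <- numeric(length(fractions))
  remaining <- 1
  for (k in seq_along(fractions)) {
    e[k] <- if (remaining > 0) min(1, fractions[k] / remaining) else 0
    remaining <- remaining - fractions[k]
  }
  depletion_profile(total_amount, e)
}

#' Simulate a sequential-extraction series
#'
#' Converts a depletion profile into per-extraction peak areas through a
#' calibration line: each step's true amount (mg/100 g) becomes a vial
#' concentration via the reconstitution volume and sample mass, then a peak
#' area via the line, with optional multiplicative noise. Ground truth (per-step
#' amounts and concentrations) is attached for recovery round-trip tests.
#'
#' @param profile A [depletion_profile()].
#' @param fit A [calibration_fit] (or any list with elements `a` and `b`)
#'   giving the response line `area = a * conc + b`.
#' @param volume Reconstitution volume, mL (default 3).
#' @param mass Extracted powder mass, g (default 0.5).
#' @param cv Relative SD of area noise (default 0 = noiseless).
#' @param seed Integer seed.
#' @param sample,analyte Labels for the resulting series.
#' @return An [extraction_series()] whose records carry simulated areas; the
#'   truth is attached as attributes `true_amounts` and `true_concentrations`.
#' @export
simulate_extraction_series <- function(profile, fit, volume = 3, mass = 0.5,
                                       cv = 0, seed = 1L,
                                       sample = "synthetic", analyte = "AnAc 15:3") {
  stopifnot(inherits(profile, "depletion_profile"))
  if (volume <= 0 || mass <= 0) stop("volume and mass must be positive")
  if (cv < 0) stop("cv must be >= 0")
  coefs <- line_coefficients(fit)
  set.seed(as.integer(seed))
  amounts <- step_amounts(profile)
  # invert the unit chain: amount [mg/100 g] -> vial concentration [ug/mL]
  conc <- amounts * mass / (volume * 0.1)
  area <- coefs$a * conc + coefs$b
  if (cv > 0) area <- area * (1 + stats::rnorm(length(area), 0, cv))
  series <- extraction_series(
    data.frame(sample = sample, analyte = analyte,
               extraction = seq_along(area), area = area,
               stringsAsFactors = FALSE),
    volume = volume, mass = mass)
  attr(series, "true_amounts") <- amounts
  attr(series, "true_concentrations") <- conc
  series
}

# accept either a calibration_fit or a bare list(a=, b=)
line_coefficients <- function(fit) {
  if (inherits(fit, "calibration_fit")) return(list(a = fit$a, b = fit$b))
  if (is.list(fit) && all(c("a", "b") %in% names(fit)))
    return(list(a = fit$a, b = fit$b))
  stop("fit must be a calibration_fit or a list with elements a and b")
}
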
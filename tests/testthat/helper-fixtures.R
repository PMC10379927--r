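# Shared fixtures: all built in code, no files.

ref <- reference_calibration()

# noiseless triplicate calibration exactly on the reference line
exact_calibration_points <- function() {
  data.frame(level = rep(ref$levels, each = 3),
             area = rep(ref$slope * ref$levels + ref$intercept, each = 3))
}

exact_fit <- function() fit_line(exact_calibration_points())

# a fit whose dispersions are overridden with the published ones, so the
# significance machinery can be exercised on the printed inputs
published_dispersion_fit <- function() {
  fit <- exact_fit()
  fit$s_y <- 1  # placeholder; only s_a / s_b feed the t statistics
  fit$s_a <- ref$s_a
  fit$s_b <- ref$s_b
  fit
}

# 4-point toy calibration with hand-computed normal-equation solution:
# n = 4, Sx = 10, Sy = 56, Sxx = 30, Sxy = 155, D = 20
# a = 3, b = 6.5, residuals (0.5, -0.5, -0.5, 0.5), SSres = 1,
# s_y = sqrt(1/2), s_a = sqrt(0.5 * 4 / 20), s_b = sqrt(0.5 * 30 / 20)
toy_points <- function() data.frame(level = 1:4, area = c(10, 12, 15, 19))
toy_expect <- list(a = 3, b = 6.5, s_y = sqrt(0.5),
                   s_a = sqrt(0.1), s_b = sqrt(0.75))

# independent matrix-form OLS oracle: (X'X)^{-1} X'y and classical SEs
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  n <- length(y)
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(XtX)))
  list(a = unname(beta[2]), b = unname(beta[1]), s_y = sqrt(s2),
       s_b = unname(se[1]), s_a = unname(se[2]))
}

# single-analyte noiseless recipe used by several integration oracles
single_peak_recipe <- function(conc = 40, sigma = 0.1, tau = 0, noise = 0,
                               drift = 0, seed = 1) {
  simulation_recipe(analytes = anac_catalog()[1], concentrations = conc,
                    peak_sigma = sigma, tailing_tau = tau, noise_sd = noise,
                    baseline_drift = drift, rt_jitter_sd = 0, seed = seed)
}
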
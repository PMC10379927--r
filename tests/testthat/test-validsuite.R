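test_that("precision reproduces hand-computed SD and CV", {
  p0 <- precision(data.frame(level = 40, area = c(40, 40, 40)), "intraday")
  expect_equal(p0$sd, 0)
  expect_equal(p0$cv, 0)

  p1 <- precision(data.frame(level = 40, area = c(39.9, 40.0, 40.1)), "intraday")
  expect_equal(p1$sd, 0.1, tolerance = 1e-12)
  expect_equal(p1$cv, 0.25, tolerance = 1e-12)
  expect_equal(p1$n, 3)
})

test_that("sample SD agrees with the two-pass textbook computation", {
  set.seed(3)
  for (i in 1:1000) {
    v <- rnorm(sample(3:12, 1), runif(1, 10, 1000), runif(1, 0.1, 50))
    p <- precision(data.frame(level = 1, area = v), "intraday")
    m <- sum(v) / length(v)
    s2 <- sum((v - m)^2) / (length(v) - 1)
    expect_equal(p$sd, sqrt(s2), tolerance = 1e-12)
    expect_equal(p$cv, 100 * sqrt(s2) / m, tolerance = 1e-12)
  }
})

test_that("CV is invariant under positive rescaling", {
  v <- c(39.9, 40.0, 40.1)
  p1 <- precision(data.frame(level = 1, area = v), "intraday")
  p2 <- precision(data.frame(level = 1, area = 1000 * v), "intraday")
  expect_equal(p1$cv, p2$cv, tolerance = 1e-12)
})

test_that("interday precision pools day means per level", {
  df <- data.frame(level = rep(c(10, 40), each = 6),
                   day = rep(rep(1:3, each = 2), 2),
                   area = c(100, 102, 110, 112, 120, 122,
                            400, 400, 410, 410, 420, 420))
  p <- precision(df, "interday")
  # day means for level 10: 101, 111, 121 -> sd 10, mean 111
  expect_equal(p$sd[p$level == 10], 10, tolerance = 1e-12)
  expect_equal(p$cv[p$level == 10], 100 * 10 / 111, tolerance = 1e-12)
  expect_equal(attr(p, "mode"), "interday")
  expect_error(precision(df[df$day == 1, ], "interday"), "2 distinct days")
})

test_that("simulated replicate noise produces sub-percent intraday CVs", {
  cvs <- vapply(1:100, function(s) {
    ser <- simulate_calibration_series(replicates = 6, cv_target = 0.002,
                                       seed = s)
    attr(precision(ser, "intraday"), "summary_cv")
  }, numeric(1))
  expect_gt(mean(cvs), 0.1)
  expect_lt(mean(cvs), 0.3)
})

test_that("system suitability computes RSDs and enforces the injection count", {
  same <- data.frame(rt = rep(7.9, 10), area = rep(96000, 10))
  s <- system_suitability(same)
  expect_equal(s$rt_rsd, 0)
  expect_equal(s$area_rsd, 0)
  expect_true(s$pass && s$pass_strict)

  expect_error(system_suitability(same[1:4, ]), "at least 6")

  # published-scale RSDs (0.45% rt, 0.30% area) pass even the strict 1% profile
  set.seed(5)
  inj <- data.frame(rt = 7.9 * (1 + rnorm(10, 0, 0.0045)),
                    area = 96000 * (1 + rnorm(10, 0, 0.0030)))
  s2 <- system_suitability(inj, rsd_threshold = 1)
  expect_true(s2$pass)
})

test_that("retention-time jitter propagates to the expected RT RSD", {
  rsds <- vapply(1:200, function(s) {
    set.seed(s)
    inj <- data.frame(rt = 7.9 * (1 + rnorm(10, 0, 0.005)),
                      area = rep(96000, 10))
    system_suitability(inj)$rt_rsd
  }, numeric(1))
  expect_lt(abs(mean(rsds) - 0.5), 0.15)
})

test_that("detection limits follow the two numeric estimators exactly", {
  fit <- regression_dispersions(fit_line(toy_points()))

  # signal-to-noise: LOQ/LOD = 10/3 by construction
  noise <- 0.18 * fit$a / 3  # noise chosen so LOD = 0.18
  dl <- detection_limits(fit, noise_sd = noise)
  expect_equal(dl$lod, 0.18, tolerance = 1e-12)
  expect_equal(dl$loq, 0.60, tolerance = 1e-12)
  expect_equal(dl$loq / dl$lod, 10 / 3, tolerance = 1e-12)

  # residual-SD: LOQ/LOD = 10/3.3; inverting LOD = 0.18 on the reference slope
  # implies s_y ~ 127.3
  s_y_needed <- 0.18 * 2333.5 / 3.3
  expect_equal(s_y_needed, 127.28, tolerance = 1e-3)
  rl <- detection_limits(fit, method = "residual-sd")
  expect_equal(rl$lod, 3.3 * fit$s_y / fit$a, tolerance = 1e-12)
  expect_equal(rl$loq / rl$lod, 10 / 3.3, tolerance = 1e-12)

  expect_error(detection_limits(fit, noise_sd = NULL), "noise_sd")
})

test_that("a validated method's LOD sits below the lowest calibration level", {
  # replicate scatter at the study's scale: residual-based limits must
  # land under the 1 ug/mL bottom level for the report to validate
  ser <- simulate_calibration_series(cv_target = 0.002, seed = 42)
  fit <- regression_dispersions(fit_line(ser))
  dl <- detection_limits(fit, method = "residual-sd")
  expect_lt(dl$lod, 1)
})

test_that("selectivity verdicts use an inclusive 95% boundary", {
  out <- selectivity_report(c(a = 0.9917, b = 0.95, c = 0.80))
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  expect_error(selectivity_report(c(1.2)), "0, 1")
})

test_that("validation reports assemble, render and round-trip through JSON", {
  ser <- simulate_calibration_series(cv_target = 0.002, seed = 1)
  fit <- calibrate(ser)
  prec <- list(precision(ser, "intraday"))
  set.seed(1)
  inj <- data.frame(rt = 7.9 * (1 + rnorm(10, 0, 0.0045)),
                    area = 96000 * (1 + rnorm(10, 0, 0.003)))
  suit <- system_suitability(inj)
  dl <- detection_limits(fit, method = "residual-sd")
  sel <- selectivity_report(c(`AnAc 15:3` = 0.9917, `AnAc 15:2` = 0.9819,
                              `AnAc 15:1` = 0.9940))
  rep <- build_report(fit, prec, suit, dl, sel)

  md <- report_markdown(rep)
  expect_match(md, "Analytical curve")
  expect_match(md, "Selectivity \\(AnAc 15:3\\)")

  path <- tempfile(fileext = ".json")
  write_report_json(report_record(rep), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$fit$slope, fit$a, tolerance = 1e-12)
  expect_equal(back$fit$t_intercept, fit$t_b, tolerance = 1e-12)
  expect_equal(back$limits$lod, dl$lod, tolerance = 1e-12)
  expect_equal(back$suitability$rt_rsd, suit$rt_rsd, tolerance = 1e-12)
  expect_equal(unlist(back$precision$summary_cv),
               attr(prec[[1]], "summary_cv"), tolerance = 1e-12)

  expect_error(build_report(NULL, prec, suit, dl, sel), "missing component: fit")
})
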
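test_that("baseline estimation recovers constant and linear baselines", {
  times <- seq(0, 30, by = 0.01)
  # flat baseline
  flat <- rep(5, length(times))
  expect_lt(max(abs(estimate_baseline(flat, times) - 5)), 1e-9)

  # linear drift 0 -> 30 mAU with no peaks: recovered within 1% of range
  drift <- times  # 1 mAU/min over 30 min
  bl <- estimate_baseline(drift, times)
  expect_lt(max(abs(bl - drift)), 0.01 * 30)

  expect_error(estimate_baseline(flat, times, window = 40), "shorter than the run")
})

test_that("baseline-corrected integration on a drifting chromatogram hits the truth", {
  sim <- simulate_chromatogram(single_peak_recipe(drift = 1, noise = 0.2, seed = 21))
  trace <- monitor_trace(sim$chromatogram)
  t <- sim$chromatogram$times
  bl <- estimate_baseline(trace, t)
  tr <- sim$truth
  area <- integrate_peak(trace, bl, t, tr$true_rt - 0.5, tr$true_rt + 0.5)
  expect_lt(abs(area / tr$true_area - 1), 0.02)
})

test_that("peak detection finds exactly the true peaks at high SNR", {
  # three disjoint peaks, SNR ~ 100 at the apex
  # concentration 0.2 -> area ~ 3423 -> amplitude ~ 13655; noise for SNR ~ 100
  amp <- (2333.5 * 0.2 + 2956.2) / (0.1 * sqrt(2 * pi))
  rec <- simulation_recipe(concentrations = rep(0.2, 3), noise_sd = amp / 100,
                           rt_jitter_sd = 0, seed = 8)
  sim <- simulate_chromatogram(rec)
  t <- sim$chromatogram$times
  trace <- monitor_trace(sim$chromatogram)
  corrected <- trace - estimate_baseline(trace, t)
  pk <- detect_peaks(corrected, t, min_snr = 10)
  expect_equal(nrow(pk), 3)
  dt <- mean(diff(t))
  expect_true(all(abs(sort(pk$apex_time) - sort(sim$truth$true_rt)) <= dt + 1e-9))

  # all-zero trace: empty table, not an error
  expect_equal(nrow(detect_peaks(rep(0, 100), seq_len(100) / 100)), 0)

  # a peak below the SNR threshold is not reported
  quiet <- detect_peaks(corrected, t, min_snr = 1e6)
  expect_equal(nrow(quiet), 0)
})

test_that("pure noise yields essentially no false positives", {
  fp <- vapply(1:200, function(s) {
    set.seed(s)
    nrow(detect_peaks(rnorm(3001), seq(0, 30, by = 0.01), min_snr = 5))
  }, numeric(1))
  expect_lt(mean(fp), 0.1)
})

test_that("trapezoidal integration matches the Gaussian closed form", {
  sigma <- 0.1
  times <- seq(0, 4, by = 0.01)
  g <- 1000 * exp(-0.5 * ((times - 2) / sigma)^2)
  area <- integrate_peak(g, 0, times, 2 - 5 * sigma, 2 + 5 * sigma)
  expect_equal(area, 1000 * sigma * sqrt(2 * pi), tolerance = 1e-3)

  # degenerate interval
  expect_equal(integrate_peak(g, 0, times, 2, 2), 0)
  expect_error(integrate_peak(g, 0, times, 3, 1), "reversed")
})

test_that("pipeline areas agree with the truth manifest on a triplet chromatogram", {
  sim <- simulate_chromatogram(simulation_recipe(seed = 4))
  pk <- process_chromatogram(sim$chromatogram)
  expect_equal(nrow(pk), 3)
  m <- merge(pk, sim$truth, by = "analyte")
  expect_true(all(abs(m$area / m$true_area - 1) < 0.01))
})

test_that("integration is linear in concentration", {
  a1 <- process_chromatogram(simulate_chromatogram(
    simulation_recipe(concentrations = c(20, 20, 20), noise_sd = 0,
                      rt_jitter_sd = 0, response_intercept = 0))$chromatogram)
  a2 <- process_chromatogram(simulate_chromatogram(
    simulation_recipe(concentrations = c(40, 40, 40), noise_sd = 0,
                      rt_jitter_sd = 0, response_intercept = 0))$chromatogram)
  expect_true(all(abs(a2$area / a1$area - 2) < 0.002))
})

test_that("detection and integration track the truth across seeded chromatograms", {
  errs <- vapply(1:50, function(s) {
    sim <- simulate_chromatogram(simulation_recipe(seed = s))
    pk <- process_chromatogram(sim$chromatogram)
    if (nrow(pk) != 3 || anyNA(pk$analyte)) return(NA_real_)
    m <- merge(pk, sim$truth, by = "analyte")
    max(abs(m$area / m$true_area - 1))
  }, numeric(1))
  expect_false(anyNA(errs))           # no missed peaks
  expect_lt(median(errs), 0.01)       # median area error < 1%
})

test_that("retention-time matching assigns uniquely within tolerance", {
  catalog <- anac_catalog()
  mk <- function(rt, area = 100)
    data.frame(apex_time = rt, start_time = rt - 0.3, end_time = rt + 0.3,
               height = 10, area = area)
  # exact hit
  p <- match_peaks(mk(7.9), catalog)
  expect_equal(p$analyte, "AnAc 15:3")
  # 1.5x tolerance away: unassigned
  p <- match_peaks(mk(7.9 + 0.3), catalog, rt_tolerance = 0.2)
  expect_true(is.na(p$analyte))
  # two candidates inside tolerance: nearest wins regardless of row order,
  # the loser is flagged ambiguous
  two <- rbind(mk(7.95, area = 50), mk(7.80, area = 500))
  for (ord in list(1:2, 2:1)) {
    p <- match_peaks(two[ord, ], catalog, rt_tolerance = 0.2)
    expect_equal(p$analyte[p$apex_time == 7.95], "AnAc 15:3")
    expect_true(is.na(p$analyte[p$apex_time == 7.80]))
    expect_true(p$ambiguous[p$apex_time == 7.80])
  }
  # equidistant candidates: larger area breaks the tie
  tie <- rbind(mk(7.8, area = 10), mk(8.0, area = 20))
  p <- match_peaks(tie, catalog, rt_tolerance = 0.2)
  expect_equal(p$analyte[p$apex_time == 8.0], "AnAc 15:3")
  # catalog too crowded for the tolerance
  crowded <- list(analyte_def("x", 5, 300), analyte_def("y", 5.1, 300))
  expect_error(match_peaks(mk(5), crowded, rt_tolerance = 0.2), "separated")
})

test_that("spectrum extraction uses the nearest sample and respects bounds", {
  sim <- simulate_chromatogram(single_peak_recipe())
  ch <- sim$chromatogram
  # between-sample times resolve to the nearest row
  s1 <- extract_spectrum(ch, 7.901)
  s2 <- extract_spectrum(ch, 7.90)
  expect_identical(s1$values, s2$values)
  expect_error(extract_spectrum(ch, 31), "outside")

  # peakless region of a noisy run: near-zero after local baseline correction
  simn <- simulate_chromatogram(single_peak_recipe(noise = 0.5, seed = 9))
  sp <- extract_spectrum(simn$chromatogram, 25, baseline_times = c(24, 26))
  expect_lt(sqrt(sum(sp$values^2)),
            3 * 0.5 * sqrt(length(sp$values)))
})

test_that("three-point purity separates pure from contaminated peaks", {
  sim <- simulate_chromatogram(single_peak_recipe(noise = 0.2, seed = 2))
  pk <- process_chromatogram(sim$chromatogram)
  ref_profile <- anac_catalog()[[1]]$uv_profile
  pur <- peak_purity(sim$chromatogram, pk[1, ], ref_profile)
  expect_gt(as.numeric(pur), 0.99)

  # the apex point against its own spectrum is exactly 1
  apex_sp <- extract_spectrum(sim$chromatogram, pk$apex_time[1],
                              baseline_times = c(pk$start_time[1], pk$end_time[1]))
  pur_self <- peak_purity(sim$chromatogram, pk[1, ], apex_sp)
  expect_equal(unname(attr(pur_self, "points")["apex"]), 1, tolerance = 1e-12)
})

test_that("a co-eluting contaminant with a shifted UV band breaks purity", {
  contam_profile <- make_uv_spectrum(c(297, 360), c(16, 28), c(1, 0.45))
  main <- anac_catalog()[[1]]
  contam <- analyte_def("contaminant", main$retention_time + 0.3 * 0.1,
                        molecular_weight = 300, uv_profile = contam_profile)
  rec <- simulation_recipe(analytes = list(main, contam),
                           concentrations = c(40, 40), noise_sd = 0,
                           rt_jitter_sd = 0)
  sim <- simulate_chromatogram(rec)
  expect_true(all(sim$truth$overlap))  # flagged as fused in the manifest
  t <- sim$chromatogram$times
  trace <- monitor_trace(sim$chromatogram)
  corrected <- trace - estimate_baseline(trace, t)
  pk <- detect_peaks(corrected, t)
  pur <- peak_purity(sim$chromatogram, pk[1, ], main$uv_profile)
  expect_lt(as.numeric(pur), 0.95)
})

test_that("purity is non-increasing in the contaminant's relative amplitude", {
  main <- anac_catalog()[[1]]
  contam_profile <- make_uv_spectrum(c(297, 360), c(16, 28), c(1, 0.45))
  contam <- analyte_def("contaminant", main$retention_time + 0.05,
                        molecular_weight = 300, uv_profile = contam_profile)
  purity_at <- function(conc) {
    rec <- simulation_recipe(analytes = list(main, contam),
                             concentrations = c(40, conc), noise_sd = 0,
                             rt_jitter_sd = 0, response_intercept = 0)
    sim <- simulate_chromatogram(rec)
    t <- sim$chromatogram$times
    trace <- monitor_trace(sim$chromatogram)
    corrected <- trace - estimate_baseline(trace, t)
    pk <- detect_peaks(corrected, t)
    as.numeric(peak_purity(sim$chromatogram, pk[1, ], main$uv_profile))
  }
  purities <- vapply(seq(0, 36, length.out = 10), purity_at, numeric(1))
  expect_true(all(diff(purities) <= 1e-9))
})
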
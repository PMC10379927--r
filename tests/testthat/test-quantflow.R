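test_that("the area-to-amount unit chain is correct and linear", {
  fit <- exact_fit()
  q <- amount_from_area(2333.5 * 36.783 + 2956.2, fit)
  expect_equal(q$concentration, 36.783, tolerance = 1e-9)
  expect_equal(q$amount, 22.0698, tolerance = 1e-9)

  # zero concentration -> zero amount
  q0 <- amount_from_area(2956.2, fit)
  expect_equal(q0$amount, 0, tolerance = 1e-9)

  # doubling the reconstitution volume doubles the amount
  q2 <- amount_from_area(2333.5 * 36.783 + 2956.2, fit, volume = 6)
  expect_equal(q2$amount, 2 * q$amount, tolerance = 1e-12)

  # a sub-intercept area flags a negative concentration and reports 0
  qn <- amount_from_area(1000, fit)
  expect_true(qn$negative)
  expect_equal(qn$amount, 0)
})

test_that("censoring is inclusive at the LOQ and keeps raw areas", {
  fit <- exact_fit()
  limits <- list(loq = 0.85)
  concs <- c(36.783, 3.867, 0.85, 0.5)
  ser <- extraction_series(
    data.frame(sample = "s", analyte = "AnAc 15:3", extraction = 1:4,
               area = 2333.5 * concs + 2956.2))
  ser <- censor(quantify_series(ser, fit), limits)
  expect_equal(ser$records$censored, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(ser$records$area, 2333.5 * concs + 2956.2)  # raw areas retained
})

test_that("the published censoring pattern totals from quantified records only", {
  # extraction-1/2 quantified, 3-5 censored: total from two records
  fit <- exact_fit()
  concs <- c(36.783, 3.867, 0.6, 0.3, 0.1)
  ser <- extraction_series(
    data.frame(sample = "CCP 09", analyte = "AnAc 15:3", extraction = 1:5,
               area = 2333.5 * concs + 2956.2))
  ser <- censor(quantify_series(ser, fit), list(loq = 0.85))
  expect_equal(ser$records$censored, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  rep <- clone_totals(list(ser))
  expect_equal(rep$analyte_totals$total,
               sum(ser$records$amount[1:2]), tolerance = 1e-12)
})

test_that("recovery percentages normalize, accumulate and ignore record order", {
  one <- extraction_series(data.frame(sample = "s", analyte = "a",
                                      extraction = 1, area = 123))
  expect_equal(recovery_matrix(one)$recovery, 100)

  ser <- extraction_series(data.frame(sample = "s", analyte = "a",
                                      extraction = 1:5,
                                      area = c(8535, 1142, 218, 93, 11)))
  rm <- recovery_matrix(ser)
  expect_equal(sum(rm$recovery), 100, tolerance = 1e-9)
  expect_true(all(diff(rm$cumulative) >= 0))
  expect_equal(rm$cumulative[5], 100, tolerance = 1e-9)

  shuffled <- extraction_series(
    data.frame(sample = "s", analyte = "a", extraction = c(3, 1, 5, 2, 4),
               area = c(218, 8535, 11, 1142, 93)))
  expect_equal(recovery_matrix(shuffled), rm)

  zero <- extraction_series(data.frame(sample = "s", analyte = "a",
                                       extraction = 1:2, area = c(0, 0)))
  expect_error(recovery_matrix(zero), "zero")
})

test_that("reported recovery rows are taken as-is with prefix-sum cumulatives", {
  rm <- recovery_from_percent(c(85.35, 11.42, 2.18, 0.93, 0.11))
  expect_equal(rm$recovery[1], 85.35)
  expect_equal(rm$cumulative[2], 96.77, tolerance = 1e-12)
  expect_error(recovery_from_percent(c(50, 30)), "sum to 100")
})

test_that("extraction count to reach a recovery threshold is minimal and monotone", {
  ccp09 <- recovery_from_percent(c(85.35, 11.42, 2.18, 0.93, 0.11))
  expect_equal(extractions_needed(ccp09, 90), 2L)
  expect_equal(extractions_needed(ccp09, 85), 1L)
  # threshold 100 needs every extraction (area-derived matrix sums exactly)
  exact <- recovery_matrix(extraction_series(
    data.frame(sample = "s", analyte = "a", extraction = 1:5,
               area = c(8535, 1142, 218, 93, 11))))
  expect_equal(extractions_needed(exact, 100), 5L)
  # reported rounded rows may top out just short of 100
  expect_error(extractions_needed(ccp09, 100), "never reaches")

  ccp76 <- recovery_from_percent(c(71.17, 21.05, 7.06, 0.66, 0.03))
  expect_equal(extractions_needed(ccp76, 90), 2L)

  # non-increasing as the threshold loosens
  thresholds <- c(99.9, 99, 95, 90, 80, 50)
  needed <- vapply(thresholds, function(th)
    extractions_needed(ccp09, th), integer(1))
  expect_true(all(diff(needed) <= 0))
})

test_that("clone totals respect censoring and report the clone range", {
  rep <- clone_totals(reference_extraction_records(),
                      expected_analytes = names(anac_catalog()))
  at <- rep$analyte_totals
  expect_equal(at$total[at$sample == "BRS 275" & at$analyte == "AnAc 15:3"],
               29.83, tolerance = 1e-12)
  expect_false(any(rep$clone_totals$incomplete))

  # a clone missing an analyte is flagged but still totalled
  sub <- reference_extraction_records()
  sub <- sub[!(sub$sample == "CCP 09" & sub$analyte == "AnAc 15:1"), ]
  rep2 <- clone_totals(sub, expected_analytes = names(anac_catalog()))
  expect_true(rep2$clone_totals$incomplete[rep2$clone_totals$sample == "CCP 09"])
})

test_that("noiseless and low-noise series round-trip through the full pipeline", {
  shares <- c(85.35, 11.42, 2.18, 0.93, 0.11) / 100
  prof <- depletion_from_fractions(shares, total_amount = 24.40)

  # zero-intercept line: raw-area recovery equals the depletion fractions
  fit0 <- fit_line(data.frame(level = c(1, 5, 10, 20, 40, 60, 80, 100),
                              area = 2333.5 * c(1, 5, 10, 20, 40, 60, 80, 100)))
  ser0 <- simulate_extraction_series(prof, fit0, cv = 0, seed = 2)
  expect_equal(recovery_matrix(ser0)$recovery, 100 * shares / sum(shares),
               tolerance = 1e-9)

  # reference line with replicate noise: per-step shares (percent) recovered
  # within 2 percentage points on every step
  fit <- exact_fit()
  worst <- vapply(1:50, function(s) {
    ser <- simulate_extraction_series(prof, fit, cv = 0.005, seed = s)
    amt <- quantify_series(ser, fit)$records$amount
    max(abs(100 * amt / sum(amt) - 100 * shares))
  }, numeric(1))
  expect_lt(max(worst), 2)
})
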
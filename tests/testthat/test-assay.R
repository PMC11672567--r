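test_that("noiseless 4PL curves are recovered to 0.1%", {
  fx <- make_assay_fixtures("binding", dir = tempfile(), noise = 0,
                            ec50 = 200, hill = 1, bottom = 0.05, top = 2.0)
  d <- read.csv(fx$files[["csv"]])
  f <- fit_4pl(d$concentration_pM, d$response)
  expect_true(f$converged)
  expect_equal(f$ec50, 200, tolerance = 1e-3)
  expect_equal(f$hill, 1, tolerance = 1e-3)
  expect_equal(f$bottom, 0.05, tolerance = 1e-3)
  expect_equal(f$top, 2.0, tolerance = 1e-3)
  # descending curves work too
  fx2 <- make_assay_fixtures("binding", dir = tempfile(), noise = 0,
                             ec50 = 350, hill = -1.2, bottom = 0.1,
                             top = 1.8)
  d2 <- read.csv(fx2$files[["csv"]])
  f2 <- fit_4pl(d2$concentration_pM, d2$response)
  expect_true(f2$converged)
  expect_equal(f2$ec50, 350, tolerance = 1e-3)
})

test_that("EC50 recovery stays within 5% median error at 2% noise", {
  errs <- vapply(1:20, function(seed) {
    fx <- make_assay_fixtures("binding", dir = tempfile(), noise = 0.02,
                              ec50 = 200, seed = seed)
    d <- read.csv(fx$files[["csv"]])
    f <- fit_4pl(d$concentration_pM, d$response)
    abs(f$ec50 - 200) / 200
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("degenerate binding data is flagged, not silently fitted", {
  f <- fit_4pl(10^(0:5), rep(1.0, 6))
  expect_false(f$converged)
  expect_error(fit_4pl(c(-1, 1, 10, 100, 1000), 1:5), "positive")
  expect_error(fit_4pl(c(1, 10, 100, 1000), 1:4), "5 distinct")
})

test_that("relative potency follows the log10 ratio convention", {
  expect_equal(relative_potency(200, 200), 100)
  expect_equal(relative_potency(148, 518), 79.96, tolerance = 1e-2)
  # antisymmetry: the two directed potencies multiply to 100^2
  expect_equal(relative_potency(148, 518) * relative_potency(518, 148),
               100^2, tolerance = 1e-9)
  # sub-pM values are refused (log sign flip makes the ratio meaningless)
  expect_error(relative_potency(148, 0.5), "unit-ambiguous")
  expect_error(relative_potency(0.5, 148), "unit-ambiguous")
})

test_that("AC-SINS quadratic vertex is exact on noiseless spectra", {
  fx <- make_assay_fixtures("acsins", dir = tempfile(), lambda_max = 530,
                            a = -0.001, noise = 0)
  d <- read.csv(fx$files[["csv"]])
  q <- acsins_lambda_max(d$wavelength_nm, d$absorbance)
  expect_true(q$valid)
  expect_equal(q$lambda_max, 530, tolerance = 1e-9)
  expect_equal(q$a, -0.001, tolerance = 1e-12)
  # vertex formula instance: a=-1, b=1060 -> 530
  expect_equal(-1060 / (2 * -1), 530)
  # a shifted vertex is found wherever it lies inside the window
  fx2 <- make_assay_fixtures("acsins", dir = tempfile(),
                             lambda_max = 541.3, a = -0.0008, noise = 0)
  d2 <- read.csv(fx2$files[["csv"]])
  expect_equal(acsins_lambda_max(d2$wavelength_nm,
                                 d2$absorbance)$lambda_max,
               541.3, tolerance = 1e-9)
})

test_that("AC-SINS vertex recovery tolerates stated noise", {
  devs <- vapply(1:100, function(seed) {
    fx <- make_assay_fixtures("acsins", dir = tempfile(), lambda_max = 530,
                              a = -0.001, peak = 0.5, noise = 0.005,
                              seed = seed)
    d <- read.csv(fx$files[["csv"]])
    abs(acsins_lambda_max(d$wavelength_nm, d$absorbance)$lambda_max - 530)
  }, numeric(1))
  expect_gte(mean(devs <= 0.2), 0.95)
})

test_that("invalid peaks are flagged and guarded", {
  wl <- seq(480, 580, 2)
  rising <- 0.001 * (wl - 530)^2 + 0.1       # convex: no peak
  q <- acsins_lambda_max(wl, rising)
  expect_false(q$valid)
  expect_true(is.na(q$lambda_max))
  expect_error(acsins_lambda_max(wl[1:4], rising[1:4]), ">= 5 points")
  expect_error(acsins_shift(q, q), "invalid")
})

test_that("plasmon shifts subtract control from sample and rank constructs", {
  mk <- function(lam) {
    fx <- make_assay_fixtures("acsins", dir = tempfile(), lambda_max = lam,
                              noise = 0)
    d <- read.csv(fx$files[["csv"]])
    acsins_lambda_max(d$wavelength_nm, d$absorbance)
  }
  ctrl <- mk(530)
  expect_equal(acsins_shift(mk(532.4), ctrl), 2.4, tolerance = 1e-9)
  expect_equal(acsins_shift(mk(530), ctrl), 0, tolerance = 1e-9)
  # planted shift ordering is recovered exactly in the noiseless case
  shifts <- vapply(c(530.97, 530.83, 530.61), function(l)
    acsins_shift(mk(l), ctrl), numeric(1))
  expect_equal(order(shifts), c(3, 2, 1))
})

test_that("SEC calibration interpolates exactly through two standards", {
  cal <- sec_calibration(c(670, 44), c(8, 12))
  expect_equal(sec_mw_estimate(10, cal), 171.7, tolerance = 1e-3)
  expect_equal(sec_mw_estimate(8, cal), 670)
  expect_equal(sec_mw_estimate(12, cal), 44)
  expect_error(sec_calibration(670, 8), ">= 2")
  expect_error(sec_calibration(c(44, 670), c(8, 12)), "negative")
  expect_warning(sec_mw_estimate(20, cal), "extrapolating")
})

test_that("SEC fixtures round-trip through calibration and estimation", {
  fx <- make_assay_fixtures("sec", dir = tempfile())
  d <- read.csv(fx$files[["csv"]])
  cal <- sec_calibration(d$mw_kda, d$retention_ml)
  expect_equal(cal$slope, fx$truth$slope, tolerance = 1e-9)
  expect_equal(cal$intercept, fx$truth$intercept, tolerance = 1e-9)
  # a ~144 kDa IgG elutes where the truth line says it should
  v_igg <- (log10(144) - fx$truth$intercept) / fx$truth$slope
  expect_equal(sec_mw_estimate(v_igg, cal), 144, tolerance = 1e-9)
})
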
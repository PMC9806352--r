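test_that("TRU activity prorates 50% turbidity reduction per mg per minute", {
  expect_equal(turbidity_reduction_units(1.0, 0.5, 1, 1)$activity, 1.0)
  expect_equal(turbidity_reduction_units(1.0, 1.0, 1, 1)$activity, 0)
  # 2.5 ug venom, 20 min incubation at 50% reduction
  expect_equal(turbidity_reduction_units(1.0, 0.5, 0.0025, 20)$activity, 20)

  expect_warning(turbidity_reduction_units(1.0, 1.2, 1, 1), "negative")
  neg <- suppressWarnings(turbidity_reduction_units(1.0, 1.2, 1, 1))
  expect_equal(neg$activity, 0)
  expect_true(neg$negative_reduction)
})

test_that("TRU activity scales exactly inversely with mass and time", {
  base <- turbidity_reduction_units(0.8, 0.3, 0.001, 10)$activity
  expect_equal(turbidity_reduction_units(0.8, 0.3, 0.002, 10)$activity,
               base / 2, tolerance = 1e-12)
  expect_equal(turbidity_reduction_units(0.8, 0.3, 0.001, 30)$activity,
               base / 3, tolerance = 1e-12)
})

test_that("standard-curve specific activity inverts the fitted line", {
  curve <- fit_standard_curve(c(0, 10), c(0, 1))
  expect_equal(curve$slope, 0.1)
  expect_equal(curve$intercept, 0)

  res <- specific_activity_from_curve(curve, 0.5, 0.005, 40)
  expect_equal(res$nmol, 5)
  expect_equal(res$activity, 25)
  expect_false(res$negative)

  at_intercept <- specific_activity_from_curve(curve, 0, 1, 1)
  expect_equal(at_intercept$activity, 0)

  out <- specific_activity_from_curve(curve, 1.5, 1, 1)
  expect_true(out$extrapolated)

  expect_error(fit_standard_curve(c(5, 5), c(0, 1)),
               class = "venomcomp_validation_error")
  expect_error(fit_standard_curve(c(0, 1, 2), c(3, 3, 3)),
               class = "venomcomp_curve_error")
})

test_that("noise-free synthetic curves recover planted activity exactly", {
  slope <- 0.04; intercept <- 0.12
  amounts <- seq(0, 50, by = 5)
  curve <- fit_standard_curve(amounts, intercept + slope * amounts)
  expect_equal(curve$slope, slope, tolerance = 1e-12)
  planted_nmol <- 37.5
  res <- specific_activity_from_curve(curve, intercept + slope * planted_nmol,
                                      0.005, 40)
  expect_equal(res$nmol, planted_nmol, tolerance = 1e-9)
})

test_that("relative haemolysis treats the positive control as 100% and is affine-invariant", {
  expect_equal(relative_haemolysis(1.2, 0.05, 1.2), 100)
  expect_equal(relative_haemolysis(0.05, 0.05, 1.2), 0)
  expect_equal(relative_haemolysis((1.2 + 0.05) / 2, 0.05, 1.2), 50)

  base <- relative_haemolysis(0.61, 0.08, 1.14)
  shift <- relative_haemolysis(0.61 + 0.3, 0.08 + 0.3, 1.14 + 0.3)
  expect_equal(shift, base, tolerance = 1e-12)

  expect_error(relative_haemolysis(0.5, 1.0, 0.9),
               class = "venomcomp_validation_error")
  # uncorrected mode ignores the blank
  expect_equal(relative_haemolysis(0.6, 0.1, 1.2, blank_correct = FALSE), 50)
})

test_that("clotting delays report absolute and fold changes, with censoring as a lower bound", {
  r <- clotting_delay(32, 235)
  expect_equal(r$delay_s, 203)
  expect_equal(r$fold, 235 / 32)
  expect_equal(round(r$fold, 2), 7.34)
  expect_false(r$fold_is_lower_bound)

  same <- clotting_delay(40, 40)
  expect_equal(same$fold, 1)
  expect_equal(same$delay_s, 0)

  cens <- clotting_delay(32, 1800, censored = TRUE)
  expect_equal(cens$fold, 56.25)
  expect_true(cens$fold_is_lower_bound)

  expect_error(clotting_delay(0, 100), class = "venomcomp_validation_error")
})
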
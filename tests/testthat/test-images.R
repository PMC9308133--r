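# darkfield/flatfield correction, calibration, concentration inversion

test_that("correction model takes the mean dark and median flat projection", {
  darks <- image_stack(replicate(3, matrix(100, 4, 4), simplify = FALSE))
  flats <- image_stack(replicate(3, matrix(300, 4, 4), simplify = FALSE))
  cm <- build_correction(darks, flats)
  expect_equal(cm$darkfield, matrix(100, 4, 4))
  expect_equal(cm$flat_minus_dark, matrix(200, 4, 4))
  expect_true(all(cm$valid))

  # median (not mean) across flatfield frames
  flats2 <- image_stack(list(matrix(280, 2, 2), matrix(300, 2, 2),
                             matrix(320, 2, 2)))
  darks2 <- image_stack(replicate(3, matrix(100, 2, 2), simplify = FALSE))
  cm2 <- build_correction(darks2, flats2)
  expect_equal(cm2$flat_minus_dark, matrix(200, 2, 2))

  # a pixel whose flatfield does not exceed the darkfield is masked
  flat_bad <- matrix(300, 2, 2); flat_bad[1, 1] <- 90
  cm3 <- build_correction(darks2,
                          image_stack(replicate(3, flat_bad,
                                                simplify = FALSE)))
  expect_false(cm3$valid[1, 1])
  expect_true(all(cm3$valid[-1]))

  expect_error(build_correction(darks, flats2), "differ")
})

test_that("correction is affine-exact and propagates the invalid mask", {
  set.seed(4)
  dark <- matrix(runif(64, 90, 110), 8, 8)
  fmd <- matrix(runif(64, 150, 250), 8, 8)
  cm <- structure(list(darkfield = dark, flat_minus_dark = fmd,
                       valid = matrix(TRUE, 8, 8)),
                  class = "correction_model")
  for (k in c(0, 0.5, 1, 3.7)) {
    expect_equal(correct_image(dark + k * fmd, cm),
                 matrix(k, 8, 8), tolerance = 1e-12)
  }
  cm$valid[2, 3] <- FALSE
  out <- correct_image(dark, cm)
  expect_true(is.na(out[2, 3]))
  expect_error(correct_image(matrix(0, 4, 4), cm), "shape mismatch")
})

test_that("roi median uses mean-of-middle-two and resists outliers", {
  img <- matrix(7, 120, 120)
  expect_equal(roi_median(img, roi(1, 1, 100, 100)), 7)

  half <- matrix(c(0, 1), 10, 10)          # even count, half 0 / half 1
  expect_equal(roi_median(half, roi(1, 1, 10, 10)), 0.5)

  spiked <- matrix(5, 50, 50); spiked[1, 1] <- 1e6
  expect_equal(roi_median(spiked, roi(1, 1, 50, 50)), 5)

  expect_error(roi_median(img, roi(50, 50, 100, 100)), "fit inside")
  masked <- matrix(NA_real_, 10, 10)
  expect_error(roi_median(masked, roi(1, 1, 10, 10)), "fully masked")
})

test_that("reference normalization is a guarded ratio", {
  expect_equal(normalize_to_reference(0.5, 0.5), 1.0)
  expect_equal(normalize_to_reference(7.5, 0.5), 15.0)
  expect_equal(normalize_to_reference(0, 3), 0)
  expect_error(normalize_to_reference(1, 0), "positive")
})

test_that("calibration fits recover lines and invert correctly", {
  cal <- fit_calibration(c(0, 2.5, 5, 7.5), c(0, 0.25, 0.5, 0.75))
  expect_equal(cal$slope, 0.1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$residual_se, 0, tolerance = 1e-12)
  expect_equal(as.numeric(to_concentration(0.5, cal)), 5, tolerance = 1e-9)
  expect_equal(as.numeric(to_concentration(cal$intercept, cal)), 0)

  # round trip on the fitted line
  for (C in c(0.5, 3.2, 7.5)) {
    I <- cal$intercept + cal$slope * C
    expect_equal(as.numeric(to_concentration(I, cal)), C, tolerance = 1e-9)
  }

  # noisy line: estimates within 3 standard errors of the truth
  set.seed(31)
  a <- 1.8; b <- 0.4
  C <- rep(c(0, 0.5, 1.5, 2.5, 5, 7.5), length.out = 20)
  I <- b + a * C + rnorm(20, 0, 0.1)
  cal2 <- fit_calibration(C, I)
  ses <- summary(cal2$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(cal2$slope - a), 3 * ses[["concentration"]])
  expect_lt(abs(cal2$intercept - b), 3 * ses[["(Intercept)"]])

  # two points: exact interpolation, SE flagged undefined
  cal3 <- fit_calibration(c(0, 7.5), c(0.1, 1.6))
  expect_false(cal3$se_defined)
  expect_equal(cal3$residual_se, 0)
  expect_equal(cal3$slope, 1.5 / 7.5, tolerance = 1e-12)

  expect_error(fit_calibration(c(1, 1), c(0, 1)), "distinct")
  # below-zero inversions are returned as-is but flagged
  low <- to_concentration(-0.05, cal)
  expect_lt(as.numeric(low), 0)
  expect_true(attr(low, "below_zero"))
  flat <- structure(list(slope = 0, intercept = 1), class = "calibration_curve")
  expect_error(to_concentration(1, flat), "slope")
})

test_that("pipeline linearity: doubling the tracer doubles the estimate", {
  rs <- make_reference_stacks(shape = c(40, 40), vignette = 0.15,
                              noise_sd = 1, n = 50, seed = 8)
  cm <- build_correction(rs$darkfields, rs$flatfields)
  ds <- make_dilution_series(concentrations = c(0, 0.5, 1.5, 3, 6),
                             slope = 2, intercept = 0, noise_sd = 1,
                             shape = c(40, 40), seed = 9, reference = rs)
  region <- roi(1, 1, 40, 40)
  ints <- vapply(seq_along(ds$concentrations), function(i) {
    roi_median(correct_image(ds$frames$frames[, , i], cm), region)
  }, 0)
  cal <- fit_calibration(ds$concentrations, ints)
  est <- as.numeric(to_concentration(ints, cal))
  expect_equal(est[[5]] / est[[4]], 2, tolerance = 0.02)
})

test_that("time courses carry frame-interval timestamps and recover levels", {
  rs <- make_reference_stacks(shape = c(30, 30), noise_sd = 0, seed = 2)
  cm <- build_correction(rs$darkfields, rs$flatfields)
  p <- rs$truth$params
  # constant stack at the reference level
  ref_signal <- 1.0
  frames <- replicate(4, p$dark_level + ref_signal * p$flat_level *
                        p$vignette_field, simplify = FALSE)
  stack <- image_stack(frames, frame_interval_s = 0.5)
  cal <- fit_calibration(c(0, 0.5, 7.5), c(0, 1, 15))  # normalized units
  ts <- quantify_timeseries(stack, cm, roi(1, 1, 30, 30), cal,
                            reference_intensity = ref_signal)
  expect_equal(ts$time_s, c(0, 0.5, 1.0, 1.5))
  expect_equal(ts$concentration, rep(0.5, 4), tolerance = 1e-9)
})

test_that("stacks and correction models survive TIFF round trips", {
  skip_if_not_installed("tiff")
  dir <- withr::local_tempdir()
  set.seed(12)
  # integer 14-bit counts survive the 16-bit storage exactly
  stack <- image_stack(replicate(3, matrix(sample(0:16383, 64), 8, 8),
                                 simplify = FALSE),
                       frame_interval_s = 0.5)
  p_tif <- file.path(dir, "stack.tif")
  write_image_stack(stack, p_tif)
  back <- read_image_stack(p_tif, frame_interval_s = 0.5)
  expect_equal(back$frames, stack$frames)

  rs <- make_reference_stacks(shape = c(8, 8), noise_sd = 0.5, n = 10,
                              seed = 5)
  cm <- build_correction(rs$darkfields, rs$flatfields)
  write_correction(cm, file.path(dir, "corr.tif"),
                   file.path(dir, "corr.json"))
  cm2 <- read_correction(file.path(dir, "corr.tif"),
                         file.path(dir, "corr.json"))
  expect_equal(cm2$darkfield, cm$darkfield, tolerance = 1e-4)
  expect_equal(cm2$valid, cm$valid)
})
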
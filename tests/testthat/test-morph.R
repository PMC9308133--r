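# segmentation, elongation, axial profiling, condition statistics

test_that("maximum-entropy threshold equals the brute-force Kapur optimum", {
  set.seed(17)
  imgs <- list(
    matrix(sample(c(rnorm(300, 60, 4), rnorm(100, 180, 8))), 20, 20),
    matrix(runif(400, 0, 255), 20, 20),
    matrix(c(rep(50, 350), rep(200, 50)) + rnorm(400, 0, 2), 20, 20))
  for (img in imgs) {
    expect_equal(max_entropy_threshold(img)$threshold,
                 kapur_bruteforce(img), tolerance = 1e-12)
  }
})

test_that("bimodal images split between the modes; polarity can invert", {
  img <- matrix(50, 30, 30)
  img[10:20, 10:20] <- 200
  res <- max_entropy_threshold(img)
  expect_gt(res$threshold, 50)
  expect_lt(res$threshold, 200)
  expect_equal(unname(res$mask$mask), unname(img == 200))

  inv <- max_entropy_threshold(max(img) - img, invert = TRUE)
  expect_equal(unname(inv$mask$mask), unname(img == 200))

  expect_error(max_entropy_threshold(matrix(5, 4, 4)), "constant")
})

test_that("noisy flat objects segment at >= 99% pixel accuracy", {
  set.seed(3)
  truth <- disk_mask(60, pad = 40)
  img <- matrix(rnorm(length(truth), 50, 5), nrow(truth))
  img[truth] <- rnorm(sum(truth), 200, 5)
  res <- max_entropy_threshold(img)
  expect_gte(mean(res$mask$mask == truth), 0.99)
})

test_that("elongation index matches analytic shapes within 2%", {
  expect_equal(elongation_index(disk_mask(80)), 1.0, tolerance = 0.02)
  expect_equal(elongation_index(stadium_mask(300, 100)), 3.0,
               tolerance = 0.02)
  # square: maximum Feret diameter is the diagonal, inscribed circle the side
  expect_equal(elongation_index(square_mask(100)), sqrt(2),
               tolerance = 0.02)
  expect_error(elongation_index(matrix(FALSE, 5, 5)), "empty")
})

test_that("elongation index is rotation- and translation-invariant to 2%", {
  base <- elongation_index(stadium_mask(240, 80, angle_deg = 0))
  for (ang in c(30, 45, 77)) {
    rot <- elongation_index(stadium_mask(240, 80, angle_deg = ang))
    expect_equal(rot, base, tolerance = 0.02)
  }
  shifted <- matrix(FALSE, 300, 330)
  sm <- stadium_mask(240, 80)
  shifted[20 + seq_len(nrow(sm)), 45 + seq_len(ncol(sm))] <- sm
  expect_equal(elongation_index(shifted), base, tolerance = 1e-12)
  expect_gte(base, 1 - 0.02)
})

test_that("axial profiles partition the band and locate gradients", {
  # uniform band: equal sums, normalized profile of ones, tied peak
  img <- matrix(1, 100, 210)
  ax <- axis_polyline(rbind(c(50, 6), c(50, 205)))
  pr <- axial_profile(img, ax, band_width_px = 80)
  expect_equal(pr$intensities, rep(1, 10), tolerance = 1e-12)
  pk <- peak_position(pr)
  expect_true(attr(pk, "tie"))
  expect_equal(as.numeric(pk), 0.05)

  # linear gradient decreasing away from the posterior pole
  grad <- matrix(rep(seq(1, 0.05, length.out = 210), each = 100), 100, 210)
  pr2 <- axial_profile(grad, ax, band_width_px = 80)
  pk2 <- peak_position(pr2)
  expect_equal(as.numeric(pk2), 0.05)
  expect_false(attr(pk2, "tie"))
  expect_true(all(diff(pr2$intensities) < 0))

  # no pixel is counted twice and nothing beyond the image is summed
  expect_lte(sum(pr2$raw_sums), sum(grad))

  # programmed peaks recovered within one segment
  for (p_true in c(0.15, 0.55, 0.95)) {
    ph <- make_gastruloid_phantom(200, 60, p_true, noise_sd = 3, seed = 77)
    pk3 <- as.numeric(peak_position(axial_profile(ph$image, ph$axis)))
    expect_lte(abs(pk3 - p_true), 0.10)
  }
})

test_that("profile normalization is scale-invariant with unit maximum", {
  pr <- normalize_profile((1:10) / 10, axis_length_px = 200)
  expect_equal(max(pr$intensities), 1)
  expect_equal(pr$positions[which.max(pr$intensities)], 0.95)
  expect_equal(pr$positions, seq(0.05, 0.95, by = 0.1))

  const <- normalize_profile(rep(4, 10), 100)
  expect_equal(const$intensities, rep(1, 10))

  scaled <- normalize_profile(7.3 * (1:10) / 10, 200)
  expect_equal(scaled$intensities, pr$intensities, tolerance = 1e-12)

  expect_error(normalize_profile(rep(0, 10), 100), "all-zero")
})

test_that("peak position reads the raw maximum with a smallest-tie rule", {
  pr <- normalize_profile(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 100)
  expect_equal(as.numeric(peak_position(pr)), 0.95)
  pr2 <- normalize_profile(c(10, 2, 3, 4, 5, 6, 7, 8, 9, 1), 100)
  expect_equal(as.numeric(peak_position(pr2)), 0.05)
  pr3 <- normalize_profile(c(5, 9, 9, 1, 1, 1, 1, 1, 1, 1), 100)
  pk <- peak_position(pr3)
  expect_equal(as.numeric(pk), 0.15)
  expect_true(attr(pk, "tie"))

  # invariance under monotone intensity rescaling
  img <- make_gastruloid_phantom(200, 60, 0.35, noise_sd = 0, seed = 1)$image
  ax <- make_gastruloid_phantom(200, 60, 0.35, noise_sd = 0, seed = 1)$axis
  p1 <- as.numeric(peak_position(axial_profile(img, ax)))
  p2 <- as.numeric(peak_position(axial_profile(3 * img + 17, ax)))
  expect_equal(p1, p2)
})

test_that("condition fits recover known polynomials", {
  coefs <- c(0.2, 1.1, -3.0, 2.4, 0.6)   # ascending powers, quartic
  xs <- seq(0.05, 0.95, by = 0.1)
  truth_y <- drop(outer(xs, 0:4, `^`) %*% coefs)
  mk_profile <- function(y) {
    structure(list(positions = xs, intensities = y, raw_sums = y,
                   axis_length_px = 100, id = NA_character_),
              class = "axial_profile")
  }
  fit0 <- fit_condition(list(mk_profile(truth_y)), degree = 4)
  expect_equal(fit0$coefficients, coefs, tolerance = 1e-9)
  expect_equal(max(abs(fit0$residuals)), 0, tolerance = 1e-9)

  set.seed(19)
  profs <- lapply(1:7, function(i) mk_profile(truth_y + rnorm(10, 0, 0.05)))
  fit1 <- fit_condition(profs, degree = 4)
  expect_lt(max(abs(predict(fit1, xs) - truth_y)), 0.1)
  expect_equal(fit1$n_gastruloids, 7L)
  expect_equal(length(fit1$residuals), 70L)

  fit2 <- fit_condition(list(mk_profile(truth_y)), degree = 0)
  expect_equal(fit2$coefficients, mean(truth_y), tolerance = 1e-12)

  expect_error(fit_condition(list(mk_profile(truth_y)), degree = 10),
               "degree")
})

test_that("condition peak summaries average per-gastruloid peaks", {
  s <- condition_peak_summary(c(0.85, 0.95, 0.95))
  expect_equal(s$mean, 0.9166667, tolerance = 1e-6)
  expect_equal(s$se, 0.03333333, tolerance = 1e-6)
  expect_equal(s$n, 3L)

  s1 <- condition_peak_summary(0.75)
  expect_equal(s1$mean, 0.75)
  expect_equal(s1$se, 0)
  expect_false(s1$se_defined)

  expect_equal(condition_peak_summary(rep(0.85, 4))$se, 0)
})

test_that("the one-tailed Welch test matches its closed forms", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- welch_one_tailed(b, a, "greater")
  oracle <- welch_closed_form(b, a, "greater")
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$t, 3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p, 0.01065582, tolerance = 1e-6)

  same <- welch_one_tailed(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)

  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = 2)
    pg <- welch_one_tailed(x, y, "greater")$p
    pl <- welch_one_tailed(x, y, "less")$p
    expect_equal(pg + pl, 1, tolerance = 1e-12)
  }

  expect_error(welch_one_tailed(1, c(1, 2)), "length")
  expect_error(welch_one_tailed(c(1, 1), c(2, 2)), "zero variance")
})

test_that("montage axes load from CSV and morphometry tables assemble", {
  dir <- withr::local_tempdir()
  ph1 <- make_gastruloid_phantom(160, 50, 0.25, noise_sd = 2, seed = 41)
  ph2 <- make_gastruloid_phantom(200, 50, 0.85, noise_sd = 2, seed = 42)
  axes_df <- rbind(
    data.frame(id = "g1", row = ph1$axis$vertices[, 1],
               col = ph1$axis$vertices[, 2]),
    data.frame(id = "g2", row = ph2$axis$vertices[, 1],
               col = ph2$axis$vertices[, 2]))
  path <- file.path(dir, "axes.csv")
  write.csv(axes_df, path, row.names = FALSE)
  axes <- read_axes_csv(path)
  expect_named(axes, c("g1", "g2"))
  expect_s3_class(axes$g1, "axis_polyline")

  results <- list(
    g1 = list(elongation = elongation_index(ph1$mask),
              profile = axial_profile(ph1$image, axes$g1, id = "g1")),
    g2 = list(elongation = elongation_index(ph2$mask),
              profile = axial_profile(ph2$image, axes$g2, id = "g2")))
  tab <- morphometry_table(results)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("id", "elongation_index", "peak_position",
                      sprintf("seg%02d", 1:10)))
  expect_lte(abs(tab$peak_position[1] - 0.25), 0.10)
  expect_lte(abs(tab$peak_position[2] - 0.85), 0.10)
})
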
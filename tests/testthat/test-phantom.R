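test_that("phantom specs are validated", {
  expect_error(phantom_spec(cornea_radius_px = -5), "positive")
  expect_error(phantom_spec(pupil_radius_px = 300, cornea_radius_px = 100),
               "smaller")
  expect_error(phantom_spec(pupil_offset_px = c(150, 0)), "inside")
  expect_error(phantom_spec(invasion_distance_px = -1), "non-negative")
})

test_that("masks use exactly the declared class codes, one per pixel", {
  ph <- clean_phantom(128, d_frac = 0.6)
  expect_true(is.matrix(ph$mask))
  expect_true(all(ph$mask %in% ptery_classes()))
  # jittered phantoms too
  ph2 <- generate_phantom(phantom_spec(128, 128,
                                       invasion_distance_px = 30,
                                       boundary_jitter_sd_px = 2))
  expect_true(all(ph2$mask %in% ptery_classes()))
})

test_that("zero-height cap: d = R gives no invasion", {
  ph <- clean_phantom(256, d_frac = 1)
  codes <- ptery_classes()
  X <- matrix(rep(seq_len(256) - 1, each = 256), 256)
  Y <- t(X)
  inside <- (X - ph$truth$cornea_center[1])^2 +
    (Y - ph$truth$cornea_center[2])^2 <= ph$truth$cornea_radius_px^2
  expect_equal(sum(ph$mask == codes[["pterygium"]] & inside), 0)
  expect_equal(ph$truth$alpha_cornea_analytic, 0)
  expect_equal(ph$truth$beta_true, 0)
})

test_that("half-disc cap: d = 0 gives alpha = beta = 0.5", {
  ph <- clean_phantom(256, d_frac = 0)
  expect_equal(ph$truth$alpha_cornea_analytic, 0.5)
  expect_equal(ph$truth$beta_true, 0.5)
  # pixel counting agrees
  codes <- ptery_classes()
  X <- matrix(rep(seq_len(256) - 1, each = 256), 256)
  Y <- t(X)
  inside <- (X - ph$truth$cornea_center[1])^2 +
    (Y - ph$truth$cornea_center[2])^2 <= ph$truth$cornea_radius_px^2
  frac <- sum(ph$mask == codes[["pterygium"]] & inside) / sum(inside)
  expect_lt(abs(frac - 0.5), 0.01)
})

test_that("pixel-counted cap fraction matches the closed form (R=200, d=150)", {
  ph <- generate_phantom(phantom_spec(512, 512, cornea_radius_px = 200,
                                      invasion_distance_px = 150,
                                      boundary_jitter_sd_px = 0))
  alpha_ref <- (200^2 * acos(0.75) - 150 * sqrt(200^2 - 150^2)) /
    (pi * 200^2)
  expect_equal(ph$truth$alpha_cornea_analytic, alpha_ref, tolerance = 1e-12)
  codes <- ptery_classes()
  X <- matrix(rep(seq_len(512) - 1, each = 512), 512)
  Y <- t(X)
  inside <- (X - ph$truth$cornea_center[1])^2 +
    (Y - ph$truth$cornea_center[2])^2 <= 200^2
  frac <- sum(ph$mask == codes[["pterygium"]] & inside) / sum(inside)
  expect_lt(abs(frac - alpha_ref), 0.01)
})

test_that("pixel counting converges to the analytic fraction with resolution", {
  err_at <- function(size) {
    ph <- clean_phantom(size, d_frac = 0.6)
    codes <- ptery_classes()
    X <- matrix(rep(seq_len(size) - 1, each = size), size)
    Y <- t(X)
    inside <- (X - ph$truth$cornea_center[1])^2 +
      (Y - ph$truth$cornea_center[2])^2 <= ph$truth$cornea_radius_px^2
    abs(sum(ph$mask == codes[["pterygium"]] & inside) / sum(inside) -
          ph$truth$alpha_cornea_analytic)
  }
  expect_lt(err_at(1024), err_at(256))
})

test_that("true grade flips from 1 to 2 when depth crosses 3 mm at 11.5 mm", {
  # beta * 11.5 = 3  <=>  beta = 0.26087  <=>  d/R = 1 - 2 * beta
  R <- 100
  just_below <- clean_phantom(300, d_frac = 1 - 2 * (2.9 / 11.5), R = R)
  just_above <- clean_phantom(300, d_frac = 1 - 2 * (3.1 / 11.5), R = R)
  expect_equal(phantom_grade(just_below$truth, 11.5), 1L)
  expect_equal(phantom_grade(just_above$truth, 11.5), 2L)
})

test_that("pupil-covering caps are graded 3", {
  ph <- clean_phantom(256, d_frac = 0.05)
  expect_true(ph$truth$pupil_covered_true)
  expect_equal(phantom_grade(ph$truth, 11.5), 3L)
})

test_that("perturb_mask is an identity at zero strength and seed-deterministic", {
  ph <- clean_phantom(128, d_frac = 0.5)
  expect_identical(perturb_mask(ph$mask, 0, 0L, seed = 3), ph$mask)
  p1 <- perturb_mask(ph$mask, 0.05, 1L, seed = 7)
  p2 <- perturb_mask(ph$mask, 0.05, 1L, seed = 7)
  expect_identical(p1, p2)
  p3 <- perturb_mask(ph$mask, 0.05, 1L, seed = 8)
  expect_false(identical(p1, p3))
  expect_error(perturb_mask(ph$mask, 1), "flip_fraction")
})

test_that("5% label flips keep per-class Dice between 0.8 and 1", {
  ph <- clean_phantom(512, d_frac = 0.5)
  pert <- perturb_mask(ph$mask, 0.05, 0L, seed = 11)
  expect_true(all(pert %in% ptery_classes()))
  for (cl in ptery_classes()) {
    d <- per_class_metrics(pert, ph$mask, cl)$dice
    expect_lt(d, 1)
    expect_gt(d, 0.8)
  }
})

test_that("erosion and dilation move the pterygium boundary", {
  ph <- clean_phantom(128, d_frac = 0.5)
  codes <- ptery_classes()
  n0 <- sum(ph$mask == codes[["pterygium"]])
  grown <- perturb_mask(ph$mask, 0, 2L, seed = 1)
  shrunk <- perturb_mask(ph$mask, 0, -2L, seed = 1)
  expect_gt(sum(grown == codes[["pterygium"]]), n0)
  expect_lt(sum(shrunk == codes[["pterygium"]]), n0)
  expect_true(all(shrunk %in% codes))
})

test_that("rendered phantoms are valid RGB arrays", {
  ph <- clean_phantom(64, d_frac = 0.5)
  img <- render_phantom_rgb(ph$mask, noise_sd = 0.05, seed = 2)
  expect_equal(dim(img), c(64L, 64L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img, render_phantom_rgb(ph$mask, noise_sd = 0.05,
                                           seed = 2))
})
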
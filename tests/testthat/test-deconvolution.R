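test_that("stain vectors normalize to unit length", {
  expect_equal(normalize_stain_vector(c(1, 0, 0))$od, c(1, 0, 0))
  expect_equal(normalize_stain_vector(c(0.3, 0.4, 0))$od, c(0.6, 0.8, 0))
  expect_error(normalize_stain_vector(c(0, 0, 0)), "zero")
  expect_error(normalize_stain_vector(c(-1, 1, 0)), "non-negative")
  for (v in stain_presets())
    expect_equal(sqrt(sum(v$od^2)), 1, tolerance = 1e-9)
})

test_that("basis completion yields an orthogonal residual and a true inverse", {
  b <- axis_basis()
  expect_equal(b$v3$od, c(0, 0, 1))
  expect_equal(b$unmix, solve(b$matrix))
  expect_equal(unname(b$unmix %*% b$matrix), diag(3), tolerance = 1e-9)

  v1 <- normalize_stain_vector(c(0.6, 0.8, 0))
  v2 <- normalize_stain_vector(c(0, 0, 1))
  b2 <- complete_stain_basis(v1, v2)
  expect_equal(b2$v3$od, c(0.8, -0.6, 0))  # sum positive: no flip
  expect_lt(abs(sum(b2$v3$od * v1$od)), 1e-12)
  expect_lt(abs(sum(b2$v3$od * v2$od)), 1e-12)

  expect_error(complete_stain_basis(v1, v1), "collinear")

  # residual orthogonality for an arbitrary realistic pair
  b3 <- default_basis()
  expect_lt(abs(sum(b3$v3$od * b3$v1$od)), 1e-9)
  expect_lt(abs(sum(b3$v3$od * b3$v2$od)), 1e-9)
  expect_equal(unname(b3$unmix %*% b3$matrix), diag(3), tolerance = 1e-9)
})

test_that("optical density transform follows -log10 with a 1/255 floor", {
  img <- rgb_image(array(1, c(2, 2, 3)), mode = "real")
  expect_true(all(rgb_to_od(img) == 0))

  img2 <- rgb_image(array(0.1, c(2, 2, 3)), mode = "real")
  expect_equal(as.numeric(rgb_to_od(img2)), rep(1, 12))

  img3 <- rgb_image(array(0, c(2, 2, 3)), mode = "real")
  od3 <- rgb_to_od(img3)
  expect_equal(as.numeric(od3), rep(log10(255), 12))
  expect_equal(attr(od3, "od_floor_count"), 12L)

  # 8-bit input must go through correction (or an explicit rescale) first
  expect_error(rgb_to_od(flat_image(128)), "correct_illumination")
})

test_that("unmixing inverts the stain mixture and is linear before flooring", {
  b <- default_basis()
  mk <- function(co) array(rep(co, each = 4), c(2, 2, 3))
  pure <- unmix_image(mk(b$v1$od), b)
  expect_equal(as.numeric(pure$c1), rep(1, 4), tolerance = 1e-9)
  expect_equal(as.numeric(pure$c2), rep(0, 4), tolerance = 1e-9)

  mix <- unmix_image(mk(0.7 * b$v1$od + 0.2 * b$v2$od), b)
  expect_equal(as.numeric(mix$c1), rep(0.7, 4), tolerance = 1e-9)
  expect_equal(as.numeric(mix$c2), rep(0.2, 4), tolerance = 1e-9)
  expect_equal(as.numeric(mix$c3), rep(0, 4), tolerance = 1e-9)

  blank <- unmix_image(array(0, c(2, 2, 3)), b)
  expect_true(all(blank$c1 == 0) && all(blank$c2 == 0))

  # linearity over random OD fields (flooring cannot trigger on positives)
  set.seed(11)
  od1 <- array(runif(27, 0, 0.5), c(3, 3, 3))
  od2 <- array(runif(27, 0, 0.5), c(3, 3, 3))
  f <- function(od) {
    flat <- matrix(od, ncol = 3) %*% b$unmix
    flat  # pre-floor concentrations
  }
  expect_equal(f(0.3 * od1 + 1.7 * od2), 0.3 * f(od1) + 1.7 * f(od2),
               tolerance = 1e-9)

  # swapping the stain order swaps the channels exactly
  bs <- complete_stain_basis(b$v2, b$v1)
  a1 <- unmix_image(od1, b); a2 <- unmix_image(od1, bs)
  expect_equal(a1$c1, a2$c2)
  expect_equal(a1$c2, a2$c1)
})

test_that("8-bit conversion is transmittance-coded with half-away-from-zero rounding", {
  expect_equal(as.integer(concentration_to_channel(matrix(0))), 255L)
  expect_equal(as.integer(concentration_to_channel(matrix(1))), 26L)  # round(25.5)
  expect_equal(as.integer(concentration_to_channel(matrix(10))), 0L)
  expect_error(concentration_to_channel(matrix(-0.1)), "non-negative")
})

test_that("stain vectors are recoverable from stained ROIs", {
  b <- default_basis()
  v <- b$v1$od
  # noiseless: constant concentration along v
  pix <- matrix(rep(10^(-0.6 * v), each = 50), ncol = 3)
  est <- estimate_stain_vector(pix)
  expect_equal(est$od, v, tolerance = 1e-6)

  # Gaussian intensity noise sigma = 0.01, 500 pixels: within 1 degree
  set.seed(21)
  noisy <- pix[rep(1:50, 10), ] + rnorm(1500, 0, 0.01)
  noisy <- pmin(pmax(noisy, 0), 1)
  est2 <- estimate_stain_vector(noisy)
  angle <- acos(min(1, sum(est2$od * v))) * 180 / pi
  expect_lt(angle, 1)

  expect_error(estimate_stain_vector(matrix(1, 100, 3)), "no stain")
  expect_error(estimate_stain_vector(pix[1:5, ]), "at least 10")
})

test_that("render-unmix round trip recovers concentrations to quantization accuracy", {
  b <- default_basis()
  sc <- two_disk_scene(96)
  r <- render_stained_image(sc, b)
  corr <- correct_illumination(r$image, make_calibration_pair(sc))
  maps <- unmix_image(rgb_to_od(corr), b)
  expect_lte(sqrt(mean((maps$c1 - r$truth$c1)^2)), 0.01)
  expect_lte(sqrt(mean((maps$c2 - r$truth$c2)^2)), 0.01)
})
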
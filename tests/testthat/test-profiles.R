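test_that("extract_profile averages the orthogonal band correctly", {
  # constant image -> flat profile
  img <- matrix(7, 10, 12)
  pr <- extract_profile(img, "horizontal", 5, 4)
  expect_equal(pr$intensities, rep(7, 12))

  # one bright row, vertical profile width 1 -> single-sample spike
  img2 <- matrix(0, 10, 10); img2[4, ] <- 50
  pr2 <- extract_profile(img2, "vertical", 6, 1)
  expect_equal(which(pr2$intensities > 0), 4L)

  # width-10 band over a linear horizontal gradient: hand-averaged oracle
  img3 <- matrix(rep(1:20, each = 16), nrow = 16) +
    matrix(rep(seq(0, 1.5, by = 0.1), 20), nrow = 16)
  centre <- 9L
  band <- (centre - 5L):(centre + 4L)
  oracle <- apply(img3[band, ], 2, mean)
  pr3 <- extract_profile(img3, "horizontal", centre, 10)
  expect_equal(pr3$intensities, unname(oracle))

  expect_error(extract_profile(img2, "vertical", 5, 11), "exceeds")
})

test_that("averaging_width = 1 equals the raw line read-out exactly", {
  set.seed(42)
  for (rep in 1:5) {
    img <- matrix(runif(30 * 40, 0, 1000), 30, 40)
    r <- sample(30, 1); cc <- sample(40, 1)
    expect_identical(extract_profile(img, "horizontal", r, 1)$intensities,
                     unname(img[r, ]))
    expect_identical(extract_profile(img, "vertical", cc, 1)$intensities,
                     unname(img[, cc]))
  }
})

test_that("peak_and_fwhm matches hand-interpolated crossings", {
  pr <- intensity_profile(0:6, c(0, 1, 2, 4, 2, 1, 0))
  ps <- peak_and_fwhm(pr)
  expect_false(ps$no_peak)
  expect_equal(ps$peak_position, 3)
  expect_equal(ps$half_max_crossings, c(2, 4))   # half level 2, hand-derived
  expect_equal(ps$fwhm, 2.0)

  # sampled Gaussian sigma 2 um, spacing 0.05 um: closed form 4.70964 um
  ps2 <- peak_and_fwhm(gaussian_profile(2.0, 0.05))
  expect_equal(ps2$fwhm, FWHM_K * 2.0, tolerance = 0.05 / (FWHM_K * 2))

  # strictly increasing ramp -> flagged, not an error
  ps3 <- peak_and_fwhm(intensity_profile(1:10, 1:10))
  expect_true(ps3$no_peak)
})

test_that("peak_and_fwhm is invariant under affine intensity rescaling", {
  set.seed(7)
  for (i in 1:10) {
    sigma <- runif(1, 0.5, 3)
    pr <- gaussian_profile(sigma, 0.1, amp = runif(1, 10, 500),
                           baseline = runif(1, 0, 50))
    a <- runif(1, 0.1, 9); b <- runif(1, 0, 100)
    scaled <- intensity_profile(pr$positions, a * pr$intensities + b,
                                unit = pr$unit)
    p1 <- peak_and_fwhm(pr); p2 <- peak_and_fwhm(scaled)
    expect_equal(p1$peak_position, p2$peak_position)
    expect_equal(p1$fwhm, p2$fwhm, tolerance = 1e-12)
  }
})

test_that("profile FWHM converges to the closed form as spacing shrinks", {
  sigma <- 0.8
  errs <- vapply(c(0.2, 0.1, 0.05), function(sp) {
    abs(peak_and_fwhm(gaussian_profile(sigma, sp))$fwhm - FWHM_K * sigma)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))       # monotone decreasing error
  expect_lt(errs[3], 0.05 / 2)
})

test_that("fit_gaussian recovers noiseless parameters to 1e-6 relative", {
  x <- seq(0, 10, by = 0.1)
  pr <- intensity_profile(x, 100 * exp(-(x - 5)^2 / 2) + 10, unit = "um")
  fit <- fit_gaussian(pr)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$mean, 5, tolerance = 1e-6)
  expect_equal(fit$sigma, 1, tolerance = 1e-6)
  expect_equal(fit$baseline, 10, tolerance = 1e-6)
  expect_equal(fit$fwhm / fit$sigma, FWHM_K)     # definition, to machine eps
})

test_that("fit_gaussian mean is unbiased under noise (Monte Carlo)", {
  x <- seq(0, 10, by = 0.1)
  clean <- 100 * exp(-(x - 5)^2 / 2) + 10
  means <- vapply(1:100, function(s) {
    set.seed(s)
    y <- pmax(clean + rnorm(length(x), 0, 2), 0)
    fit_gaussian(intensity_profile(x, y, unit = "um"))$mean
  }, numeric(1))
  expect_lt(abs(mean(means) - 5), 0.05)
})

test_that("fit_gaussian flags failure on a flat profile", {
  fit <- fit_gaussian(intensity_profile(1:20, rep(3, 20)))
  expect_false(fit$converged)
})
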
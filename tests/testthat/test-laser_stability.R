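constant_series <- function(values, ny = 8L, nx = 8L, dt = 20) {
  Tn <- length(values)
  px <- array(0, dim = c(Tn, 1, 1, ny, nx))
  for (t in seq_len(Tn)) px[t, 1, 1, , ] <- values[t]
  image_stack(px, frame_interval = dt)
}

test_that("frame_statistics matches hand-computed drift numbers", {
  fs <- frame_statistics(constant_series(rep(100, 10)))
  expect_equal(fs$mean_intensity, rep(100, 10))
  expect_equal(fs$sd_intensity, rep(0, 10))
  expect_equal(fs$max_percent_change, 0)

  # two frames, means 100 and 110: (110 - 100) / 105 * 100
  fs2 <- frame_statistics(constant_series(c(100, 110)))
  expect_equal(fs2$max_percent_change, 10 / 105 * 100, tolerance = 1e-12)

  expect_error(frame_statistics(constant_series(100)), "at least 2")
})

test_that("sinusoidal drift yields max change ~ 2 * amplitude / mean", {
  fx <- generate_fixture("laser",
                         list(n_frames = 120L, drift = "sine",
                              drift_amplitude = 20, drift_period_s = 480,
                              noise_sd = 0, frame_noise_sd = 0), seed = 3)
  fs <- frame_statistics(fx$stack)
  expect_equal(fs$max_percent_change, 2 * 20 / 1000 * 100, tolerance = 0.02)
})

test_that("linear drift slope is recovered by least squares within 1%", {
  fx <- generate_fixture("laser",
                         list(n_frames = 100L, drift = "linear",
                              drift_slope = 0.05, noise_sd = 2), seed = 4)
  fs <- frame_statistics(fx$stack)
  slope <- coef(lm(fs$mean_intensity ~ fs$times))[[2]]
  expect_equal(slope, 0.05, tolerance = 0.01)
})

test_that("linescan_noise matches the population-SD hand computation", {
  img <- matrix(c(90, 100, 110), nrow = 1)
  ln <- linescan_noise(img, 1)
  expect_equal(ln$mean, 100)
  expect_equal(ln$sd, sqrt(200 / 3), tolerance = 1e-12)   # 8.16497
  expect_equal(ln$cv, sqrt(200 / 3) / 100, tolerance = 1e-12)

  expect_equal(linescan_noise(matrix(5, 3, 7), 2)$cv, 0)
  expect_true(linescan_noise(matrix(0, 3, 7), 2)$cv_undefined)
})

test_that("linescan cv estimates multiplicative noise at 512 px", {
  fx <- generate_fixture("laser", list(n_frames = 2L, nx = 512L, ny = 4L,
                                       noise_sd = 0, mult_cv = 0.05),
                         seed = 9)
  ln <- linescan_noise(frame_yx(fx$stack, t = 1))
  expect_equal(ln$cv, 0.05, tolerance = 0.2 * 0.05 / 0.05)  # within 20%
  expect_lt(abs(ln$cv - 0.05) / 0.05, 0.2)
})

test_that("multiscale histograms conserve mass and localise known noise", {
  # constant stack: every scale is a single spike in the bin containing 0
  hs0 <- multiscale_histograms(constant_series(rep(100, 120)))
  for (h in hs0) {
    expect_equal(sum(h$frequencies), 1, tolerance = 1e-9)
    expect_equal(max(h$frequencies), 1)
  }

  # alternating means 100/102 at 20 s: differences +-2 counts = +-1.980%
  hsa <- multiscale_histograms(constant_series(rep(c(100, 102), 60)))
  h20 <- hsa[["20s"]]
  mids <- (h20$edges[-1] + head(h20$edges, -1)) / 2
  hot <- which(h20$frequencies > 0)
  expect_length(hot, 2L)
  expect_equal(sort(mids[hot]), c(-1.75, 1.75))   # bins holding +-1.980
  expect_equal(sum(h20$frequencies[hot]), 1, tolerance = 1e-9)
  expect_equal(h20$frequencies[hot][1], 0.5, tolerance = 0.01)

  # white frame-to-frame noise sd s: sd of adjacent differences = s * sqrt(2)
  s <- 30
  fx <- generate_fixture("laser", list(n_frames = 400L, nx = 32L, ny = 32L,
                                       noise_sd = 0, frame_noise_sd = s),
                         seed = 11)
  h <- multiscale_histograms(fx$stack)[["20s"]]
  mids <- (h$edges[-1] + head(h$edges, -1)) / 2
  mids[1] <- -10.25; mids[length(mids)] <- 10.25
  est_sd <- sqrt(sum(h$frequencies * mids^2) -
                   sum(h$frequencies * mids)^2)
  expect_equal(est_sd, s * sqrt(2) / 1000 * 100, tolerance = 0.15)
})

test_that("fewer than 100 frames skips the us/ms scales with a warning", {
  expect_warning(hs <- multiscale_histograms(constant_series(rep(10, 20))),
                 "us/ms")
  expect_false(any(c("us", "ms") %in% names(hs)))
})

test_that("frame means are invariant under within-frame pixel shuffling", {
  fx <- generate_fixture("laser", list(n_frames = 6L, nx = 16L, ny = 16L),
                         seed = 2)
  st <- fx$stack
  set.seed(1)
  shuffled <- st
  for (t in 1:6) {
    f <- frame_yx(st, t = t)
    shuffled$pixels[t, 1, 1, , ] <- matrix(sample(f), nrow(f), ncol(f))
  }
  expect_equal(frame_statistics(shuffled)$mean_intensity,
               frame_statistics(st)$mean_intensity)
})
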
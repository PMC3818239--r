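test_that("a static noiseless bead tracks to identical centroids", {
  fx <- generate_fixture("stage", list(n_frames = 12L, jitter_sd_um = 0,
                                       noise_sd = 0), seed = 1)
  tr <- track_bead(fx$stack)
  expect_false(any(tr$missing))
  expect_equal(diff(range(tr$centroids[, "x"])), 0)
  expect_equal(diff(range(tr$centroids[, "y"])), 0)
  # symmetric bead: centroid at its geometric centre within 0.1 px
  p <- fx$truth$parameters
  expect_lt(abs(tr$centroids[1, "x"] - (p$nx - 1) / 2 * p$pixel_size_um),
            0.1 * p$pixel_size_um)
})

test_that("a stepped bead is measured at the commanded step size", {
  fx <- generate_fixture("stageacc", list(commanded_step_um = c(1, 0),
                                          n_moves = 8L, noise_sd = 0),
                         seed = 2)
  tr <- track_bead(fx$stack)
  steps <- -diff(tr$centroids[, "x"])      # stage +x moves bead -x in image
  expect_true(all(abs(steps - 1.0) < 0.02))
})

test_that("photobleaching decay is recovered from the intensity trace", {
  tau <- 300
  fx <- generate_fixture("stage", list(bleach_tau_s = tau, jitter_sd_um = 0,
                                       noise_sd = 0), seed = 3)
  tr <- track_bead(fx$stack)
  fit <- lm(log(tr$mean_intensity) ~ tr$times)
  expect_equal(-1 / coef(fit)[[2]], tau, tolerance = 0.05)
})

test_that("repeatability statistics match their sampling distribution", {
  fx <- generate_fixture("stage", list(jitter_sd_um = 0, noise_sd = 0),
                         seed = 4)
  rs0 <- repeatability_stats(track_bead(fx$stack))
  expect_equal(unname(rs0$sd), c(0, 0))

  fx1 <- generate_fixture("stage", seed = 5)   # jitter sd 0.3 um, n = 100
  rs <- repeatability_stats(track_bead(fx1$stack))
  expect_true(all(rs$sd > 0.25 & rs$sd < 0.35))
  expect_error(repeatability_stats(
    track_bead(generate_fixture("stage", list(n_frames = 5L),
                                seed = 1)$stack)), ">= 10")
})

test_that("repeatability sd is invariant under a global position offset", {
  fx <- generate_fixture("stage", list(n_frames = 20L), seed = 6)
  tr <- track_bead(fx$stack)
  tr2 <- tr
  tr2$centroids <- tr2$centroids + 13.7
  expect_equal(repeatability_stats(tr)$sd, repeatability_stats(tr2)$sd)
})

test_that("a two-cluster trace shows the separation as max excursion", {
  cent <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
                matrix(rep(c(2, 0), 10), ncol = 2, byrow = TRUE))
  colnames(cent) <- c("x", "y")
  tr <- structure(list(times = seq_len(20), centroids = cent,
                       mean_intensity = rep(1, 20), missing = rep(FALSE, 20),
                       position_label = "stage1", pixel_size_xy = 0.1,
                       stage_positions = NULL, axes_sign = c(1, 1)),
                  class = "StageTrace")
  rs <- repeatability_stats(tr)
  expect_equal(rs$max_excursion, 1)          # half the 2 um separation
  expect_equal(unname(rs$mean_position), c(1, 0))
})

test_that("accuracy residuals are zero when metadata matches motion", {
  fx <- generate_fixture("stageacc", list(noise_sd = 0), seed = 7)
  ac <- accuracy_stats(track_bead(fx$stack))
  expect_true(all(abs(ac$residuals) < 0.01))
  expect_true(all(abs(ac$scalar_residuals) < 0.01))
})

test_that("a short-falling stage leaves the commanded-minus-measured gap", {
  fx <- generate_fixture("stageacc",
                         list(commanded_step_um = c(10, 0), exec_scale = 0.98,
                              n_moves = 3L, nx = 420L, noise_sd = 0),
                         seed = 8)
  ac <- accuracy_stats(track_bead(fx$stack))
  expect_equal(unname(ac$residuals[, "x"]), rep(0.2, 3), tolerance = 1e-3)
  expect_equal(unname(ac$residuals[, "y"]), rep(0, 3), tolerance = 1e-6)
})

test_that("axis-inverted metadata is detectable as ~2x-commanded residuals", {
  fx <- generate_fixture("stageacc",
                         list(commanded_step_um = c(2, 0), noise_sd = 0,
                              invert_metadata = TRUE), seed = 9)
  ac <- accuracy_stats(track_bead(fx$stack))
  expect_equal(unname(ac$residuals[, "x"]),
               2 * unname(ac$commanded_moves[, "x"]), tolerance = 0.01)
})

test_that("accuracy requires stage positions in the metadata", {
  fx <- generate_fixture("stage", list(n_frames = 12L), seed = 10)
  tr <- track_bead(fx$stack)
  tr$stage_positions <- NULL
  expect_error(accuracy_stats(tr), "stage_positions_um")
})

test_that("grid pass-through preserves shape and degenerate frames", {
  fx <- generate_fixture("grid", seed = 11)
  g <- grid_passthrough(fx$stack)
  expect_equal(dim(g), c(256L, 256L))
  flat <- matrix(42, 32, 32)
  expect_equal(grid_passthrough(flat), flat)   # degenerate range guard
})
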
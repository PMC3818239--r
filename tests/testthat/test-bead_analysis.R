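test_that("identical channels co-register exactly", {
  fx <- generate_fixture("bead", list(noise_sd = 0), seed = 1)
  cr <- bead_centroids(fx$stack)
  expect_true(all(cr$xy_distance == 0))
  expect_true(all(cr$z_distance == 0))
  expect_equal(cr$xy_distance, t(cr$xy_distance))   # symmetric
})

test_that("sub-voxel channel offsets are recovered within half a voxel", {
  off <- rbind(c(0, 0, 0), c(0.20, -0.10, 0.45), c(0, 0, 0), c(0, 0, 0))
  # noiseless: zero-offset channels must then co-register exactly
  fx <- generate_fixture("bead", list(offsets_um = off, noise_sd = 0),
                         seed = 2)
  cr <- bead_centroids(fx$stack)
  p <- fx$truth$parameters
  # Euclidean XY distance by hand: sqrt(0.2^2 + 0.1^2) = 0.2236 um
  expect_equal(cr$xy_distance[1, 2], sqrt(0.05), tolerance = 1,
               ignore_attr = TRUE)
  expect_lt(abs(cr$xy_distance[1, 2] - sqrt(0.05)), p$pixel_size_um / 2)
  expect_lt(abs(cr$z_distance[1, 2] - 0.45), p$z_step_um / 2)
  # channels generated identically report 0 exactly
  expect_equal(cr$xy_distance[1, 3], 0)
  expect_equal(cr$z_distance[3, 4], 0)
})

test_that("a second bead in the stack is rejected by the component rule", {
  fx <- generate_fixture("bead", list(n_beads = 2L, nx = 80L, ny = 80L),
                         seed = 3)
  expect_error(bead_centroids(fx$stack), "only one bead.*2 objects")
})

test_that("centroids shift exactly with integer-voxel translations", {
  p0 <- list(noise_sd = 0)
  fx0 <- generate_fixture("bead", p0, seed = 4)
  c0 <- bead_centroids(fx0$stack)$records[[1]]$centroid
  pitch <- c(fx0$truth$parameters$pixel_size_um,
             fx0$truth$parameters$pixel_size_um,
             fx0$truth$parameters$z_step_um)
  shift_vox <- c(3, -2, 1)
  off <- matrix(rep(shift_vox * pitch, each = 4), nrow = 4)
  fx1 <- generate_fixture("bead", c(p0, list(offsets_um = off)), seed = 4)
  c1 <- bead_centroids(fx1$stack)$records[[1]]$centroid
  expect_equal(c1 - c0, setNames(shift_vox * pitch, c("x", "y", "z")),
               tolerance = 1e-9)
})

test_that("distances are consistent under channel relabelling", {
  off <- rbind(c(0, 0, 0), c(0.2, 0, 0.3), c(-0.1, 0.15, 0), c(0, -0.2, 0.1))
  fx <- generate_fixture("bead", list(offsets_um = off), seed = 5)
  cr <- bead_centroids(fx$stack)
  perm <- c(3, 1, 4, 2)
  st2 <- fx$stack
  st2$pixels <- st2$pixels[, perm, , , , drop = FALSE]
  st2$channel_wavelengths <- st2$channel_wavelengths[perm]
  cr2 <- bead_centroids(st2)
  expect_equal(unname(cr2$xy_distance), unname(cr$xy_distance[perm, perm]),
               tolerance = 1e-12)
})

test_that("halving z_step changes z distances by less than one old step", {
  off <- rbind(c(0, 0, 0), c(0, 0, 0.3), c(0, 0, 0), c(0, 0, 0))
  coarse <- generate_fixture("bead", list(offsets_um = off, noise_sd = 0),
                             seed = 6)
  fine <- generate_fixture("bead",
                           list(offsets_um = off, noise_sd = 0,
                                z_step_um = 0.125, nz = 49L), seed = 6)
  z1 <- bead_centroids(coarse$stack)$z_distance[1, 2]
  z2 <- bead_centroids(fine$stack)$z_distance[1, 2]
  expect_lt(abs(z1 - z2), coarse$truth$parameters$z_step_um)
})

test_that("psf_metrics recovers noiseless FWHMs within 2%", {
  fx <- generate_fixture("psf", seed = 7)     # sigma (0.1, 0.1, 0.3) um
  ps <- psf_metrics(fx$stack)
  expect_equal(ps$lateral_fwhm_x, FWHM_K * 0.1, tolerance = 0.02)
  expect_equal(ps$lateral_fwhm_y, FWHM_K * 0.1, tolerance = 0.02)
  expect_equal(ps$axial_fwhm, FWHM_K * 0.3, tolerance = 0.02)
  # isotropic in XY by construction: the two lateral widths agree
  expect_equal(ps$lateral_fwhm_x, ps$lateral_fwhm_y, tolerance = 0.01)
})

test_that("psf FWHM bias stays below 5% under shot-like noise", {
  fw <- vapply(1:20, function(s) {
    fx <- generate_fixture("psf", list(shot_scale = 1, noise_sd = 3),
                           seed = 100 + s)
    ps <- psf_metrics(fx$stack)
    c(ps$lateral_fwhm_x, ps$axial_fwhm)
  }, numeric(2))
  expect_lt(abs(mean(fw[1, ]) - FWHM_K * 0.1) / (FWHM_K * 0.1), 0.05)
  expect_lt(abs(mean(fw[2, ]) - FWHM_K * 0.3) / (FWHM_K * 0.3), 0.05)
})
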
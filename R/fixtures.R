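#' @name fixtures
#' @title Seeded synthetic recordings with known ground truth
#'
#' @description
#' Every assay input can be generated synthetically: mirror-reflection XZ
#' bands, flat-field vignettes, multi-channel and sub-resolution bead
#' stacks, transmitted-light time series, lambda scans, calibration grids
#' and stage time series. Each generator returns the stack together with
#' the exact generating parameters (`FixtureTruth`), so analysis results
#' can be checked against truth rather than against recorded data. Noise
#' is Gaussian read noise plus an optional signal-scaled (shot-like)
#' component; pixel values are rounded to integers and clamped to the bit
#' depth, exactly as written to TIFF.
NULL

fixture_defaults <- list(
  laser = list(nx = 128L, ny = 128L, n_frames = 120L, frame_interval_s = 20,
               mean_intensity = 1000, noise_sd = 3, mult_cv = 0,
               frame_noise_sd = 0, drift = "none", drift_slope = 0,
               drift_amplitude = 0, drift_period_s = 1200, bit_depth = 16L),
  axial = list(wavelengths = c(458, 488, 561), offsets_um = c(0, 0.20, 0.35),
               z0_um = 1.2, sigma_z_um = 0.25, nx = 64L, nz = 121L,
               z_step_um = 0.03, pixel_size_um = 0.1, amplitude = 3000,
               baseline = 50, noise_sd = 5, bit_depth = 16L),
  field = list(nx = 256L, ny = 256L, wavelength = 488, peak = 3000,
               vignette_sigma_px = 150, baseline = 0, noise_sd = 3,
               pixel_size_um = 0.3, bit_depth = 16L),
  bead = list(wavelengths = c(405, 488, 561, 633),
              offsets_um = NULL,           # C x 3 matrix (x, y, z); default 0
              nx = 48L, ny = 48L, nz = 25L, pixel_size_um = 0.08,
              z_step_um = 0.25, sigma_xy_um = 0.35, sigma_z_um = 0.5,
              amplitude = 3000, baseline = 20, noise_sd = 3, n_beads = 1L,
              second_bead_offset_um = c(2.5, 2.5, 0), bit_depth = 16L),
  psf = list(wavelength = 488, sigma_um = c(0.1, 0.1, 0.3),
             voxel_um = c(0.03, 0.03, 0.15), nx = 49L, ny = 49L, nz = 41L,
             amplitude = 2000, baseline = 10, noise_sd = 0,
             shot_scale = 0, bit_depth = 16L),
  lambda = list(lambda_start_nm = 420, lambda_step_nm = 2, n_steps = 141L,
                peak_nm = c(488, 561, 633), peak_sigma_nm = 5,
                peak_amplitude = c(3000, 2500, 2000), baseline = 30,
                nx = 32L, ny = 32L, noise_sd = 2, bit_depth = 16L),
  grid = list(nx = 256L, ny = 256L, spacing_px = 32L, line_value = 3000,
              background = 100, noise_sd = 5, pixel_size_um = 0.3,
              bit_depth = 16L),
  stage = list(n_frames = 100L, nx = 96L, ny = 96L, pixel_size_um = 0.1,
               frame_interval_s = 5, sigma_um = 0.5, amplitude = 3000,
               baseline = 10, jitter_sd_um = 0.3, bleach_tau_s = Inf,
               noise_sd = 2, bit_depth = 16L),
  stageacc = list(n_moves = 5L, commanded_step_um = c(2, 0),
                  exec_scale = 1.0, nx = 160L, ny = 64L,
                  pixel_size_um = 0.1, frame_interval_s = 10,
                  sigma_um = 0.5, amplitude = 3000, baseline = 10,
                  noise_sd = 2, invert_metadata = FALSE, bit_depth = 16L),
  zgalvo = list(n_frames = 60L, frame_interval_s = 2, nx = 64L, nz = 121L,
                z_step_um = 0.03, z0_um = 0.5, sigma_z_um = 0.25,
                drift_um_per_frame = 0, width_jitter_sd_um = 0,
                amplitude = 3000, baseline = 50, noise_sd = 5,
                bit_depth = 16L))

quantise <- function(px, bit_depth) {
  px <- round(px)
  px[px < 0] <- 0
  px[px > 2^bit_depth - 1] <- 2^bit_depth - 1
  px
}

# 2-D Gaussian bead evaluated at pixel centres; positions in um
bead_frame <- function(nx, ny, pixel_size, cx, cy, sigma, amplitude,
                       baseline) {
  x <- (seq_len(nx) - 1) * pixel_size
  y <- (seq_len(ny) - 1) * pixel_size
  baseline + amplitude * outer(exp(-(y - cy)^2 / (2 * sigma^2)),
                               exp(-(x - cx)^2 / (2 * sigma^2)))
}

#' Generate one synthetic recording
#'
#' @param kind one of `"laser"`, `"axial"`, `"field"`, `"bead"`, `"psf"`,
#'   `"lambda"`, `"grid"`, `"stage"`, `"stageacc"`, `"zgalvo"`.
#' @param parameters named list overriding that kind's defaults (see
#'   `scopeqc:::fixture_defaults`).
#' @param seed integer seed; identical `(kind, parameters, seed)` yields a
#'   bit-identical stack.
#' @return list with `stack` (an [image_stack()]) and `truth` (a
#'   `FixtureTruth`: `kind`, resolved `parameters`, `seed`).
#' @export
generate_fixture <- function(kind, parameters = list(), seed = 1L) {
  if (!kind %in% names(fixture_defaults))
    stop("unknown fixture kind ", sQuote(kind), "; valid kinds: ",
         paste(names(fixture_defaults), collapse = ", "))
  unknown <- setdiff(names(parameters), names(fixture_defaults[[kind]]))
  if (length(unknown))
    stop("unknown parameter(s) for kind ", sQuote(kind), ": ",
         paste(unknown, collapse = ", "))
  p <- utils::modifyList(fixture_defaults[[kind]], parameters)
  set.seed(seed)
  stack <- switch(kind,
    laser = fixture_laser(p), axial = fixture_axial(p),
    field = fixture_field(p), bead = fixture_bead(p),
    psf = fixture_psf(p), lambda = fixture_lambda(p),
    grid = fixture_grid(p), stage = fixture_stage(p),
    stageacc = fixture_stageacc(p), zgalvo = fixture_zgalvo(p))
  list(stack = stack,
       truth = structure(list(kind = kind, parameters = p, seed = seed),
                         class = "FixtureTruth"))
}

fixture_laser <- function(p) {
  Tn <- p$n_frames
  px <- array(0, dim = c(Tn, 1, 1, p$ny, p$nx))
  tt <- (seq_len(Tn) - 1) * p$frame_interval_s
  level <- rep(p$mean_intensity, Tn)
  if (p$drift == "linear") level <- level + p$drift_slope * tt
  if (p$drift == "sine")
    level <- level + p$drift_amplitude * sin(2 * pi * tt / p$drift_period_s)
  level <- level + stats::rnorm(Tn, 0, p$frame_noise_sd)
  for (t in seq_len(Tn)) {
    f <- matrix(level[t], p$ny, p$nx)
    if (p$noise_sd > 0) f <- f + stats::rnorm(p$ny * p$nx, 0, p$noise_sd)
    if (p$mult_cv > 0) f <- f * (1 + stats::rnorm(p$ny * p$nx, 0, p$mult_cv))
    px[t, 1, 1, , ] <- f
  }
  image_stack(quantise(px, p$bit_depth), pixel_size_xy = 1,
              frame_interval = p$frame_interval_s, bit_depth = p$bit_depth)
}

reflection_band <- function(nz, nx, z_step, z0, sigma, amplitude, baseline,
                            noise_sd) {
  z <- (seq_len(nz) - 1) * z_step
  img <- matrix(rep(baseline + amplitude * exp(-(z - z0)^2 / (2 * sigma^2)),
                    nx), nrow = nz)
  if (noise_sd > 0) img <- img + stats::rnorm(nz * nx, 0, noise_sd)
  img
}

fixture_axial <- function(p) {
  C <- length(p$wavelengths)
  stopifnot(length(p$offsets_um) == C)
  px <- array(0, dim = c(1, C, p$nz, 1, p$nx))
  for (cc in seq_len(C))
    px[1, cc, , 1, ] <- reflection_band(p$nz, p$nx, p$z_step_um,
                                        p$z0_um + p$offsets_um[cc],
                                        p$sigma_z_um, p$amplitude,
                                        p$baseline, p$noise_sd)
  image_stack(quantise(px, p$bit_depth), pixel_size_um_or_1(p),
              z_step = p$z_step_um, channel_wavelengths = p$wavelengths,
              bit_depth = p$bit_depth)
}

pixel_size_um_or_1 <- function(p) p$pixel_size_um %||% 1

fixture_field <- function(p) {
  cx <- centre_index(p$nx); cy <- centre_index(p$ny)
  img <- p$baseline +
    p$peak * outer(exp(-((seq_len(p$ny) - cy)^2) / (2 * p$vignette_sigma_px^2)),
                   exp(-((seq_len(p$nx) - cx)^2) / (2 * p$vignette_sigma_px^2)))
  if (p$noise_sd > 0) img <- img + stats::rnorm(p$ny * p$nx, 0, p$noise_sd)
  image_stack(quantise(array(img, dim = c(1, 1, 1, p$ny, p$nx)), p$bit_depth),
              pixel_size_xy = p$pixel_size_um,
              channel_wavelengths = p$wavelength, bit_depth = p$bit_depth)
}

gaussian_blob_3d <- function(nz, ny, nx, z_step, pixel_size, centre_um,
                             sigma_um, amplitude) {
  x <- (seq_len(nx) - 1) * pixel_size
  y <- (seq_len(ny) - 1) * pixel_size
  z <- (seq_len(nz) - 1) * z_step
  gx <- exp(-(x - centre_um[1])^2 / (2 * sigma_um[1]^2))
  gy <- exp(-(y - centre_um[2])^2 / (2 * sigma_um[2]^2))
  gz <- exp(-(z - centre_um[3])^2 / (2 * sigma_um[3]^2))
  amplitude * (gz %o% gy %o% gx)                  # [z, y, x]
}

fixture_bead <- function(p) {
  C <- length(p$wavelengths)
  off <- p$offsets_um
  if (is.null(off)) off <- matrix(0, nrow = C, ncol = 3)
  off <- matrix(off, ncol = 3)
  stopifnot(nrow(off) == C)
  centre <- c((p$nx - 1) / 2 * p$pixel_size_um,
              (p$ny - 1) / 2 * p$pixel_size_um,
              (p$nz - 1) / 2 * p$z_step_um)
  px <- array(0, dim = c(1, C, p$nz, p$ny, p$nx))
  for (cc in seq_len(C)) {
    vol <- p$baseline +
      gaussian_blob_3d(p$nz, p$ny, p$nx, p$z_step_um, p$pixel_size_um,
                       centre + off[cc, ],
                       c(p$sigma_xy_um, p$sigma_xy_um, p$sigma_z_um),
                       p$amplitude)
    if (p$n_beads > 1L)
      vol <- vol + gaussian_blob_3d(p$nz, p$ny, p$nx, p$z_step_um,
                                    p$pixel_size_um,
                                    centre + off[cc, ] + p$second_bead_offset_um,
                                    c(p$sigma_xy_um, p$sigma_xy_um, p$sigma_z_um),
                                    p$amplitude)
    if (p$noise_sd > 0) vol <- vol + stats::rnorm(length(vol), 0, p$noise_sd)
    px[1, cc, , , ] <- vol
  }
  image_stack(quantise(px, p$bit_depth), pixel_size_xy = p$pixel_size_um,
              z_step = p$z_step_um, channel_wavelengths = p$wavelengths,
              bit_depth = p$bit_depth)
}

fixture_psf <- function(p) {
  centre <- c((p$nx - 1) / 2 * p$voxel_um[1],
              (p$ny - 1) / 2 * p$voxel_um[2],
              (p$nz - 1) / 2 * p$voxel_um[3])
  vol <- p$baseline +
    gaussian_blob_3d(p$nz, p$ny, p$nx, p$voxel_um[3], p$voxel_um[1],
                     centre, p$sigma_um, p$amplitude)
  if (p$shot_scale > 0)
    vol <- vol + stats::rnorm(length(vol), 0, p$shot_scale * sqrt(pmax(vol, 0)))
  if (p$noise_sd > 0) vol <- vol + stats::rnorm(length(vol), 0, p$noise_sd)
  px <- array(0, dim = c(1, 1, p$nz, p$ny, p$nx))
  px[1, 1, , , ] <- vol
  image_stack(quantise(px, p$bit_depth), pixel_size_xy = p$voxel_um[1],
              z_step = p$voxel_um[3], channel_wavelengths = p$wavelength,
              bit_depth = p$bit_depth)
}

fixture_lambda <- function(p) {
  wl <- p$lambda_start_nm + (seq_len(p$n_steps) - 1) * p$lambda_step_nm
  level <- rep(p$baseline, p$n_steps)
  for (k in seq_along(p$peak_nm))
    level <- level + p$peak_amplitude[k] *
      exp(-(wl - p$peak_nm[k])^2 / (2 * p$peak_sigma_nm^2))
  px <- array(0, dim = c(p$n_steps, 1, 1, p$ny, p$nx))
  for (t in seq_len(p$n_steps)) {
    f <- matrix(level[t], p$ny, p$nx)
    if (p$noise_sd > 0) f <- f + stats::rnorm(p$ny * p$nx, 0, p$noise_sd)
    px[t, 1, 1, , ] <- f
  }
  image_stack(quantise(px, p$bit_depth), wavelength_axis = wl,
              bit_depth = p$bit_depth)
}

fixture_grid <- function(p) {
  img <- matrix(p$background, p$ny, p$nx)
  img[seq(p$spacing_px %/% 2L, p$ny, by = p$spacing_px), ] <- p$line_value
  img[, seq(p$spacing_px %/% 2L, p$nx, by = p$spacing_px)] <- p$line_value
  if (p$noise_sd > 0) img <- img + stats::rnorm(p$ny * p$nx, 0, p$noise_sd)
  image_stack(quantise(array(img, dim = c(1, 1, 1, p$ny, p$nx)), p$bit_depth),
              pixel_size_xy = p$pixel_size_um, bit_depth = p$bit_depth)
}

fixture_stage <- function(p) {
  Tn <- p$n_frames
  centre <- c((p$nx - 1) / 2, (p$ny - 1) / 2) * p$pixel_size_um
  jit <- matrix(stats::rnorm(2 * Tn, 0, p$jitter_sd_um), ncol = 2)
  tt <- (seq_len(Tn) - 1) * p$frame_interval_s
  amp <- p$amplitude * exp(-tt / p$bleach_tau_s)
  px <- array(0, dim = c(Tn, 1, 1, p$ny, p$nx))
  for (t in seq_len(Tn)) {
    f <- bead_frame(p$nx, p$ny, p$pixel_size_um,
                    centre[1] + jit[t, 1], centre[2] + jit[t, 2],
                    p$sigma_um, amp[t], p$baseline)
    if (p$noise_sd > 0) f <- f + stats::rnorm(p$ny * p$nx, 0, p$noise_sd)
    px[t, 1, 1, , ] <- f
  }
  image_stack(quantise(px, p$bit_depth), pixel_size_xy = p$pixel_size_um,
              frame_interval = p$frame_interval_s,
              stage_positions = matrix(rep(centre, each = Tn), ncol = 2),
              bit_depth = p$bit_depth)
}

fixture_stageacc <- function(p) {
  Tn <- p$n_moves + 1L
  step <- p$commanded_step_um
  travel <- p$n_moves * abs(step)
  # commanded +X moves the bead -X in the image; start so it stays in frame
  start_img <- c(if (step[1] >= 0) (p$nx - 1) * p$pixel_size_um * 0.85
                 else (p$nx - 1) * p$pixel_size_um * 0.15,
                 (p$ny - 1) / 2 * p$pixel_size_um)
  commanded_pos <- cbind(10 + step[1] * (seq_len(Tn) - 1L),
                         10 + step[2] * (seq_len(Tn) - 1L))
  executed_delta <- (seq_len(Tn) - 1L) %o% (step * p$exec_scale)
  img_pos <- sweep(-executed_delta, 2, start_img, `+`)
  px <- array(0, dim = c(Tn, 1, 1, p$ny, p$nx))
  for (t in seq_len(Tn)) {
    f <- bead_frame(p$nx, p$ny, p$pixel_size_um, img_pos[t, 1], img_pos[t, 2],
                    p$sigma_um, p$amplitude, p$baseline)
    if (p$noise_sd > 0) f <- f + stats::rnorm(p$ny * p$nx, 0, p$noise_sd)
    px[t, 1, 1, , ] <- f
  }
  meta_pos <- if (p$invert_metadata) -commanded_pos else commanded_pos
  image_stack(quantise(px, p$bit_depth), pixel_size_xy = p$pixel_size_um,
              frame_interval = p$frame_interval_s,
              stage_positions = meta_pos, bit_depth = p$bit_depth)
}

fixture_zgalvo <- function(p) {
  Tn <- p$n_frames
  px <- array(0, dim = c(Tn, 1, p$nz, 1, p$nx))
  for (t in seq_len(Tn)) {
    sigma_t <- p$sigma_z_um
    if (p$width_jitter_sd_um > 0)
      sigma_t <- max(p$sigma_z_um +
                       stats::rnorm(1, 0, p$width_jitter_sd_um), 0.02)
    px[t, 1, , 1, ] <- reflection_band(p$nz, p$nx, p$z_step_um,
                                       p$z0_um + p$drift_um_per_frame * (t - 1),
                                       sigma_t, p$amplitude, p$baseline,
                                       p$noise_sd)
  }
  image_stack(quantise(px, p$bit_depth), pixel_size_xy = 0.1,
              z_step = p$z_step_um, frame_interval = p$frame_interval_s,
              bit_depth = p$bit_depth)
}

#' Write a complete synthetic QC dataset
#'
#' Emits every assay's keyword-named recording (TIFF + sidecar) into one
#' directory, so a full [run_suite()] can be demonstrated with no
#' microscope. Per-recording seeds are derived deterministically from
#' `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @param parameters optional named list `kind -> parameter overrides`.
#' @return named character vector of the TIFF paths, invisibly.
#' @export
generate_demo_dataset <- function(dir, seed = 1L, parameters = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plan <- list(
    laser = "laser.tif",
    axial = "axial488.tif",
    field = "field488.tif",
    bead = "bead.tif",
    psf = "psf.tif",
    lambda = "scanpmt1.tif",
    grid = "grid.tif",
    stage = c("stage1.tif", "stage2.tif", "stage3.tif"),
    stageacc = c("stageacc1.tif", "stageacc2.tif", "stageacc3.tif"),
    zgalvo = "zgalvo.tif")
  out <- character(0)
  k <- 0L
  for (kind in names(plan)) for (fn in plan[[kind]]) {
    k <- k + 1L
    fx <- generate_fixture(kind, parameters[[kind]] %||% list(),
                           seed = (seed * 1000L + k) %% .Machine$integer.max)
    path <- file.path(dir, fn)
    write_stack(fx$stack, path)
    out[fn] <- path
  }
  invisible(out)
}
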
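#' Label connected components of a binary mask
#'
#' Full-neighbourhood connectivity (8-connected in 2-D, 26-connected in
#' 3-D), flood-fill labelling. Used to enforce the one-bead-per-stack
#' acquisition rule.
#'
#' @param mask logical matrix `[y, x]` or 3-D logical array `[z, y, x]`.
#' @return integer array of the same shape; 0 is background, components
#'   are numbered from 1.
#' @export
label_components <- function(mask) {
  was_2d <- is.matrix(mask)
  if (was_2d) mask <- array(mask, dim = c(1L, dim(mask)))
  d <- dim(mask)
  labels <- array(0L, dim = d)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  todo <- which(mask)
  next_label <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    queue <- seed
    labels[seed] <- next_label
    while (length(queue)) {
      coords <- arrayInd(queue, d)
      queue <- integer(0)
      for (k in seq_len(nrow(off))) {
        nb <- coords
        nb[, 1] <- nb[, 1] + off[k, 1]
        nb[, 2] <- nb[, 2] + off[k, 2]
        nb[, 3] <- nb[, 3] + off[k, 3]
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] +
          nb[ok, 1]
        lin <- lin[mask[lin] & labels[lin] == 0L]
        if (length(lin)) {
          labels[lin] <- next_label
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  if (was_2d) labels <- matrix(labels, nrow = d[2], ncol = d[3])
  labels
}

# reject stacks violating the one-bead acquisition rule: more than one
# 26-connected component of at least min_voxels above threshold
assert_single_bead <- function(mask, min_voxels = 5L, what = "stack") {
  labs <- label_components(mask)
  sizes <- tabulate(labs[labs > 0L])
  n_big <- sum(sizes >= min_voxels)
  if (n_big > 1L)
    stop("only one bead per ", what, " is permitted; found ", n_big,
         " objects above the ", min_voxels, "-voxel minimum")
  invisible(n_big)
}

# [z, y, x] numeric array view of one channel
channel_zyx <- function(stack, cc) {
  array(stack$pixels[1, cc, , , ], dim = c(n_z(stack), n_y(stack), n_x(stack)))
}

bead_channel_mask <- function(vol, median_radius = 7L) {
  filtered <- vol
  for (z in seq_len(dim(vol)[1]))
    filtered[z, , ] <- median_filter_disc(matrix(vol[z, , ], nrow = dim(vol)[2]),
                                          radius = median_radius)
  thr <- max(filtered) / 2        # channel-specific half-maximum threshold
  list(mask = filtered >= thr, threshold = thr, filtered = filtered)
}

mask_centroid_um <- function(mask, vol, stack) {
  idx <- which(mask)
  coords <- arrayInd(idx, dim(mask))               # [z, y, x]
  w <- vol[idx]
  list(
    centroid = c(x = (mean(coords[, 3]) - 1) * stack$pixel_size_xy,
                 y = (mean(coords[, 2]) - 1) * stack$pixel_size_xy,
                 z = (mean(coords[, 1]) - 1) * stack$z_step),
    centroid_weighted = c(
      x = (sum(w * coords[, 3]) / sum(w) - 1) * stack$pixel_size_xy,
      y = (sum(w * coords[, 2]) / sum(w) - 1) * stack$pixel_size_xy,
      z = (sum(w * coords[, 1]) / sum(w) - 1) * stack$z_step),
    voxel_count = length(idx))
}

#' Multi-channel bead co-registration
#'
#' Measures how well the colour channels of a multi-fluorescent bead
#' (e.g. a 1 um Tetraspeck) are co-registered in 3-D. Per channel: every
#' slice is median filtered (radius 7 pixels), the global maximum of the
#' filtered stack sets a channel-specific half-maximum threshold, the whole
#' stack is binarised at that threshold, and the unweighted 3-D centroid of
#' the above-threshold voxels is computed in micrometres (the
#' intensity-weighted centroid is reported alongside for comparison).
#' Pairwise XY (Euclidean) and Z (absolute) centroid distances between all
#' channels quantify lateral and axial chromatic misalignment. A stack
#' containing more than one bead (two 26-connected components of >= 5
#' voxels) is rejected.
#'
#' @param stack [image_stack()] with C >= 2 channels and Z >= 5 planes.
#' @return a `ColocResult` list: `records` (per-channel list with
#'   `channel_wavelength`, `centroid`, `centroid_weighted`,
#'   `threshold_value`, `voxel_count`, `absent`), `xy_distance` and
#'   `z_distance` (symmetric C x C matrices, um).
#' @export
bead_centroids <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (n_c(stack) < 2L) stop("bead co-registration needs >= 2 channels")
  if (n_z(stack) < 5L) stop("bead co-registration needs >= 5 Z planes")
  if (stack$pixel_size_xy <= 0 || stack$z_step <= 0)
    stop("bead analysis needs XY and Z calibration")
  C <- n_c(stack)
  records <- vector("list", C)
  for (cc in seq_len(C)) {
    vol <- channel_zyx(stack, cc)
    bm <- bead_channel_mask(vol)
    rec <- list(channel_wavelength = stack$channel_wavelengths[cc],
                threshold_value = bm$threshold, absent = !any(bm$mask))
    if (rec$absent) {
      rec$centroid <- rec$centroid_weighted <- c(x = NA_real_, y = NA_real_,
                                                 z = NA_real_)
      rec$voxel_count <- 0L
    } else {
      assert_single_bead(bm$mask)
      rec <- c(rec, mask_centroid_um(bm$mask, vol, stack))
    }
    records[[cc]] <- rec
  }
  cent <- t(vapply(records, function(r) r$centroid, numeric(3)))
  xy <- as.matrix(stats::dist(cent[, c("x", "y"), drop = FALSE]))
  zd <- abs(outer(cent[, "z"], cent[, "z"], `-`))
  dimnames(xy) <- dimnames(zd) <-
    list(stack$channel_wavelengths, stack$channel_wavelengths)
  structure(list(records = records, xy_distance = xy, z_distance = zd),
            class = "ColocResult")
}

#' Point spread function metrology from a sub-resolution bead
#'
#' From a single-channel Z stack of a sub-resolution point source
#' (e.g. a 175 nm bead): the bead centroid is found exactly as in
#' [bead_centroids()], then raw (unfiltered) line profiles through the
#' centroid voxel along X, Y and Z are each fitted with a Gaussian; the
#' fitted FWHMs are the lateral and axial resolution in micrometres. If a
#' fit fails to converge the profile's direct half-maximum width is carried
#' as a flagged fallback.
#'
#' @param stack single-channel [image_stack()] Z stack containing one bead.
#' @return a `PsfResult` list: `lateral_fwhm_x`, `lateral_fwhm_y`,
#'   `axial_fwhm`, `lateral_fwhm_mean` (um), `centroid` (um),
#'   `fits` (the three `GaussianFit`s), `fit_failed` (named logical).
#' @export
psf_metrics <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (n_c(stack) != 1L) stop("psf_metrics expects a single channel")
  if (n_z(stack) < 7L) stop("psf_metrics needs >= 7 Z planes")
  if (stack$pixel_size_xy <= 0 || stack$z_step <= 0)
    stop("psf_metrics needs XY and Z calibration")
  vol <- channel_zyx(stack, 1L)
  bm <- bead_channel_mask(vol)
  if (!any(bm$mask)) stop("no object above the half-maximum threshold")
  assert_single_bead(bm$mask)
  cen <- mask_centroid_um(bm$mask, vol, stack)
  vi <- c(z = round(cen$centroid[["z"]] / stack$z_step) + 1L,
          y = round(cen$centroid[["y"]] / stack$pixel_size_xy) + 1L,
          x = round(cen$centroid[["x"]] / stack$pixel_size_xy) + 1L)

  prof <- list(
    x = intensity_profile((seq_len(dim(vol)[3]) - 1) * stack$pixel_size_xy,
                          vol[vi["z"], vi["y"], ], unit = "um"),
    y = intensity_profile((seq_len(dim(vol)[2]) - 1) * stack$pixel_size_xy,
                          vol[vi["z"], , vi["x"]], unit = "um"),
    z = intensity_profile((seq_len(dim(vol)[1]) - 1) * stack$z_step,
                          vol[, vi["y"], vi["x"]], unit = "um"))
  fits <- lapply(prof, fit_gaussian)
  fwhm_of <- function(ax) {
    if (fits[[ax]]$converged) return(fits[[ax]]$fwhm)
    ps <- peak_and_fwhm(prof[[ax]])             # flagged fallback
    if (ps$no_peak) NA_real_ else ps$fwhm
  }
  fw <- vapply(c("x", "y", "z"), fwhm_of, numeric(1))
  structure(list(lateral_fwhm_x = fw[["x"]], lateral_fwhm_y = fw[["y"]],
                 axial_fwhm = fw[["z"]],
                 lateral_fwhm_mean = mean(fw[c("x", "y")]),
                 centroid = cen$centroid, centroid_weighted = cen$centroid_weighted,
                 voxel_count = cen$voxel_count, threshold_value = bm$threshold,
                 fits = fits,
                 fit_failed = !vapply(fits, `[[`, logical(1), "converged"),
                 profiles = prof),
            class = "PsfResult")
}
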
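#' Axial resolution and chromatic correction from an XZ reflection scan
#'
#' A mirror slide imaged in reflection mode gives a horizontal band in an
#' XZ scan, one per laser line. For each channel a vertical profile (along
#' Z) is extracted at `line_x` — by default the centre column — averaging
#' over 10 pixels in X, and the reflection peak's Z position and FWHM are
#' measured. The FWHM is the axial resolution; the signed differences
#' between the per-channel peak positions measure the axial chromatic
#' correction of the objective.
#'
#' @param xz [image_stack()] whose Z axis holds the scan (Y extent 1,
#'   X >= 1, any number of channels); `z_step` must be > 0.
#' @param line_x optional 1-based column index of the measurement line
#'   (the programmatic stand-in for a manually drawn line).
#' @param averaging_width pixels averaged in X (default 10).
#' @return list with `channels` (data.frame: wavelength_nm, peak_z_um,
#'   fwhm_um, no_peak), `delta_z` (signed C x C matrix,
#'   `delta_z[i, j] = peak_z[i] - peak_z[j]`, antisymmetric), `reference_nm`
#'   (shortest wavelength), `delta_z_vs_reference`, `line_x`, and the
#'   per-channel `profiles`.
#' @export
axial_channels_analysis <- function(xz, line_x = NULL, averaging_width = 10L) {
  stopifnot(inherits(xz, "ImageStack"))
  if (n_z(xz) < 5L) stop("axial analysis needs a Z axis (>= 5 planes)")
  if (xz$z_step <= 0) stop("axial analysis needs z_step > 0")
  if (is.null(line_x)) line_x <- centre_index(n_x(xz))
  C <- n_c(xz)
  wl <- xz$channel_wavelengths
  peak_z <- fwhm <- rep(NA_real_, C)
  no_peak <- logical(C)
  profiles <- vector("list", C)
  for (cc in seq_len(C)) {
    img <- frame_zx(xz, t = 1L, c = cc)          # Z x X
    pr <- extract_profile(img, "vertical", center_index = line_x,
                          averaging_width = averaging_width,
                          spacing = xz$z_step, unit = "um")
    profiles[[cc]] <- pr
    ps <- peak_and_fwhm(pr)
    no_peak[cc] <- ps$no_peak
    if (!ps$no_peak) {
      peak_z[cc] <- ps$peak_position
      fwhm[cc] <- ps$fwhm
    }
  }
  dz <- outer(peak_z, peak_z, `-`)
  dimnames(dz) <- list(wl, wl)
  ref <- which.min(wl)
  list(channels = data.frame(wavelength_nm = wl, peak_z_um = peak_z,
                             fwhm_um = fwhm, no_peak = no_peak),
       delta_z = dz, reference_nm = wl[ref],
       delta_z_vs_reference = peak_z - peak_z[ref],
       line_x = line_x, profiles = profiles)
}

#' Z-focus drift and vibration from an XZT reflection time series
#'
#' Tracks the mirror-reflection peak through time: at every time point the
#' centre-column Z profile (10-pixel X averaging) yields the peak Z
#' position and its FWHM. Peak drift quantifies Z-galvo / focus stability;
#' frame-to-frame FWHM variation is a simple vibration indicator. Frames
#' without a detectable peak are recorded as missing — never interpolated.
#'
#' @param xzt single-channel [image_stack()] with T >= 2, Z axis, Y extent 1.
#' @return a `ZDriftTrace` list: `times` (s), `peak_z` (um, NA where
#'   missing), `fwhm` (um), `total_drift` (`max - min` of peak_z),
#'   `drift_rate_um_per_min` (least-squares slope), `n_missing`.
#' @export
zgalvo_drift <- function(xzt) {
  stopifnot(inherits(xzt, "ImageStack"))
  if (n_c(xzt) != 1L) stop("zgalvo_drift expects a single channel")
  Tn <- n_t(xzt)
  if (Tn < 2L) stop("zgalvo_drift needs at least 2 time points")
  if (xzt$z_step <= 0) stop("zgalvo_drift needs z_step > 0")
  line_x <- centre_index(n_x(xzt))
  peak_z <- fwhm <- rep(NA_real_, Tn)
  for (t in seq_len(Tn)) {
    pr <- extract_profile(frame_zx(xzt, t = t), "vertical",
                          center_index = line_x, averaging_width = 10L,
                          spacing = xzt$z_step, unit = "um")
    ps <- peak_and_fwhm(pr)
    if (!ps$no_peak) {
      peak_z[t] <- ps$peak_position
      fwhm[t] <- ps$fwhm
    }
  }
  times <- (seq_len(Tn) - 1) * xzt$frame_interval
  ok <- !is.na(peak_z)
  if (sum(ok) < 2L) stop("no reflection peak detected in the time series")
  slope <- stats::coef(stats::lm(peak_z[ok] ~ times[ok]))[[2]]  # um/s
  list(times = times, peak_z = peak_z, fwhm = fwhm,
       total_drift = max(peak_z, na.rm = TRUE) - min(peak_z, na.rm = TRUE),
       drift_rate_um_per_min = slope * 60,
       n_missing = sum(!ok))
}
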
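#' Field illumination uniformity of a flat-field image
#'
#' The frame is smoothed with a disc mean filter (radius 5 pixels) to
#' suppress dirt and scratches, then the horizontal and vertical intensity
#' profiles through the image centre are read out with 10-pixel orthogonal
#' averaging. The minimum and maximum over the two profiles' samples give
#' the uniformity statistic
#' `percent_difference = (max - min) / max * 100` — the percentage fall-off
#' from the brightest point along the centre lines. The alternative
#' normalisation `(max - min) / mean * 100` is also reported. A frame with
#' >= 1% of pixels at the bit-depth maximum is flagged saturated.
#'
#' @param image [image_stack()] holding a single 2-D frame (>= 64 px per
#'   axis), or a plain Y x X matrix.
#' @param wavelength laser line in nm (annotation only).
#' @param bit_depth used for the saturation check when `image` is a matrix.
#' @return a `FieldUniformity` list: `wavelength_nm`, `h_profile`,
#'   `v_profile`, `min_intensity`, `max_intensity`, `percent_difference`,
#'   `percent_difference_vs_mean`, `saturated`, `smoothed` (the filtered
#'   frame).
#' @export
field_uniformity <- function(image, wavelength = NA_real_, bit_depth = 16L) {
  if (inherits(image, "ImageStack")) {
    bit_depth <- image$bit_depth
    px_size <- image$pixel_size_xy
    img <- frame_yx(image)
  } else {
    px_size <- 1
    img <- image
  }
  stopifnot(is.matrix(img))
  if (nrow(img) < 64L || ncol(img) < 64L)
    stop("field image must be at least 64 px in each axis")
  saturated <- mean(img >= 2^bit_depth - 1) >= 0.01

  sm <- mean_filter_disc(img, radius = 5L)
  h <- extract_profile(sm, "horizontal", center_index = centre_index(nrow(sm)),
                       averaging_width = 10L, spacing = px_size,
                       unit = if (px_size == 1) "pixel" else "um")
  v <- extract_profile(sm, "vertical", center_index = centre_index(ncol(sm)),
                       averaging_width = 10L, spacing = px_size,
                       unit = if (px_size == 1) "pixel" else "um")
  samples <- c(h$intensities, v$intensities)
  mn <- min(samples); mx <- max(samples)
  list(wavelength_nm = wavelength, h_profile = h, v_profile = v,
       min_intensity = mn, max_intensity = mx,
       percent_difference = if (mx > 0) (mx - mn) / mx * 100 else 0,
       percent_difference_vs_mean = if (mean(samples) > 0)
         (mx - mn) / mean(samples) * 100 else 0,
       saturated = saturated, smoothed = sm)
}
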
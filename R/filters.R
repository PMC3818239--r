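#' Disc-shaped median filter
#'
#' Rank filter over a circular neighbourhood (`dx^2 + dy^2 <= r^2`), the
#' standard despeckling step before thresholding bead images. At the image
#' border the neighbourhood is clipped to the pixels that exist.
#'
#' @param img numeric Y x X matrix.
#' @param radius neighbourhood radius in pixels.
#' @return filtered matrix, same shape.
#' @export
median_filter_disc <- function(img, radius = 7L) {
  stopifnot(is.matrix(img), radius >= 1)
  .disc_median_cpp(img, as.integer(radius))
}

#' Disc-shaped mean filter
#'
#' Mean over a circular neighbourhood with reflect padding at the borders
#' (mirrored edges), so border samples are not darkened — important when
#' the downstream statistic is an illumination fall-off percentage.
#'
#' @inheritParams median_filter_disc
#' @export
mean_filter_disc <- function(img, radius = 5L) {
  stopifnot(is.matrix(img), radius >= 1)
  .disc_mean_cpp(img, as.integer(radius))
}

#' Percentile contrast stretch
#'
#' Linearly rescales intensities so the `lo` and `hi` quantiles map to the
#' full output range; used for display images only. A constant (degenerate
#' range) image is returned unchanged.
#'
#' @param img numeric matrix.
#' @param lo,hi quantile bounds (defaults 0.5% / 99.5%).
#' @param out_max output maximum (default 255).
#' @export
contrast_stretch <- function(img, lo = 0.005, hi = 0.995, out_max = 255) {
  q <- stats::quantile(img, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(img)
  out <- (img - q[1]) / (q[2] - q[1]) * out_max
  out[out < 0] <- 0; out[out > out_max] <- out_max
  out
}

# centre index of an axis of extent n (1-based; the spec's n %/% 2 in
# 0-based indexing)
centre_index <- function(n) n %/% 2L + 1L
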
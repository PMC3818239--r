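#' Intensity profile
#'
#' A 1-D sequence of (position, intensity) samples with a unit tag; the
#' shared currency of the axial, field, PSF, spectral and Z-galvo assays.
#'
#' @param positions strictly increasing numeric positions.
#' @param intensities same-length non-negative intensities.
#' @param unit position unit: `"um"`, `"nm"` or `"pixel"`.
#' @param averaging_width number of pixels averaged orthogonally when the
#'   profile was extracted from an image.
#' @return an `IntensityProfile`.
#' @export
intensity_profile <- function(positions, intensities, unit = "pixel",
                              averaging_width = 1L) {
  positions <- as.numeric(positions); intensities <- as.numeric(intensities)
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  structure(list(positions = positions, intensities = intensities,
                 unit = unit, averaging_width = as.integer(averaging_width)),
            class = "IntensityProfile")
}

#' Extract a 1-D intensity profile from a 2-D image
#'
#' Reads a line profile with orthogonal averaging: each sample is the
#' arithmetic mean over a band of `averaging_width` rows (for a horizontal
#' profile) or columns (vertical) centred on `center_index`, the band being
#' clipped to the image bounds. With `averaging_width = 1` this is exactly
#' the raw line read-out.
#'
#' @param image numeric Y x X matrix.
#' @param axis `"horizontal"` (profile runs along X, band spans rows) or
#'   `"vertical"` (profile runs along Y, band spans columns).
#' @param center_index 1-based row (horizontal) or column (vertical) index
#'   at the centre of the averaging band.
#' @param averaging_width band width in pixels (>= 1).
#' @param spacing physical distance between samples (default 1).
#' @param unit unit of `spacing`.
#' @return an [intensity_profile()] with positions `(i - 1) * spacing`.
#' @export
extract_profile <- function(image, axis = c("horizontal", "vertical"),
                            center_index = NULL, averaging_width = 1L,
                            spacing = 1, unit = "pixel") {
  axis <- match.arg(axis)
  stopifnot(is.matrix(image))
  ortho_n <- if (axis == "horizontal") nrow(image) else ncol(image)
  along_n <- if (axis == "horizontal") ncol(image) else nrow(image)
  if (is.null(center_index)) center_index <- centre_index(ortho_n)
  averaging_width <- as.integer(averaging_width)
  if (averaging_width < 1L) stop("averaging_width must be >= 1")
  if (averaging_width > ortho_n)
    stop("averaging_width (", averaging_width,
         ") exceeds the image extent (", ortho_n, ") orthogonal to the profile")
  lo <- center_index - averaging_width %/% 2L
  band <- lo:(lo + averaging_width - 1L)
  band <- band[band >= 1L & band <= ortho_n]
  vals <- if (axis == "horizontal") colMeans(image[band, , drop = FALSE])
  else rowMeans(image[, band, drop = FALSE])
  intensity_profile((seq_len(along_n) - 1) * spacing, vals, unit = unit,
                    averaging_width = averaging_width)
}

#' Peak position and full width at half maximum of a profile
#'
#' The peak is the maximum sample (ties broken towards the lowest
#' position). The half-maximum level is baseline-corrected:
#' `min + (max - min) / 2`, so the statistic is invariant under affine
#' intensity rescaling. The two half-level crossings are located by linear
#' interpolation between the outermost sample pairs straddling the level on
#' each side of the peak; the FWHM is their distance. A profile whose
#' maximum sits on either end (monotone, no interior peak) yields a
#' `no_peak` flag rather than an error.
#'
#' @param profile an [intensity_profile()].
#' @return a `PeakStats` list: `no_peak`, `peak_position`, `peak_intensity`,
#'   `fwhm`, `half_level`, `half_max_crossings` (length-2), `unit`.
#' @export
peak_and_fwhm <- function(profile) {
  stopifnot(inherits(profile, "IntensityProfile"))
  x <- profile$positions; y <- profile$intensities
  n <- length(y)
  if (n < 5L) stop("peak_and_fwhm needs at least 5 samples")
  pk <- which.max(y)                      # ties -> lowest position
  res <- list(no_peak = FALSE, peak_position = x[pk], peak_intensity = y[pk],
              fwhm = NA_real_, half_level = NA_real_,
              half_max_crossings = c(NA_real_, NA_real_), unit = profile$unit)
  if (pk == 1L || pk == n || diff(range(y)) == 0) {
    res$no_peak <- TRUE
    return(res)
  }
  half <- min(y) + (max(y) - min(y)) / 2
  res$half_level <- half

  cross_at <- function(i0, i1) {       # linear interpolation across the level
    x[i0] + (half - y[i0]) / (y[i1] - y[i0]) * (x[i1] - x[i0])
  }
  # outermost straddle left of the peak: smallest i with y[i-1] < half <= y[i]
  left <- NA_real_
  for (i in 2:pk) if (y[i - 1] < half && y[i] >= half) {
    left <- if (y[i] == half) x[i] else cross_at(i - 1L, i)
    break
  }
  # outermost straddle right of the peak: largest i with y[i] >= half > y[i+1]
  right <- NA_real_
  for (i in (n - 1L):pk) if (y[i] >= half && y[i + 1] < half) {
    right <- if (y[i] == half) x[i] else cross_at(i + 1L, i)
    break
  }
  if (is.na(left) || is.na(right)) {
    res$no_peak <- TRUE                # profile never drops below half level
    return(res)
  }
  res$half_max_crossings <- c(left, right)
  res$fwhm <- right - left
  res
}

#' Fit a Gaussian to an intensity profile
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2)) + b`,
#' initialised from [peak_and_fwhm()] (`mu <- peak position`,
#' `sigma <- fwhm / 2.355`, `b <- min`). On non-convergence or when no peak
#' is detectable, a failure flag is returned carrying moment-based fallback
#' estimates instead of fitted parameters.
#'
#' @param profile an [intensity_profile()] with at least 7 samples.
#' @return a `GaussianFit` list: `amplitude`, `mean`, `sigma`, `baseline`,
#'   `fwhm` (`= 2 * sqrt(2 * log(2)) * sigma`), `rss`, `converged`, `unit`.
#' @export
fit_gaussian <- function(profile) {
  stopifnot(inherits(profile, "IntensityProfile"))
  x <- profile$positions; y <- profile$intensities
  if (length(x) < 7L) stop("fit_gaussian needs at least 7 samples")
  k <- 2 * sqrt(2 * log(2))

  moment_fallback <- function() {
    b <- min(y); w <- pmax(y - b, 0)
    if (sum(w) == 0) w <- rep(1, length(y))
    mu <- sum(w * x) / sum(w)
    sg <- sqrt(sum(w * (x - mu)^2) / sum(w))
    list(amplitude = max(y) - b, mean = mu, sigma = sg, baseline = b,
         fwhm = k * sg, rss = NA_real_, converged = FALSE,
         unit = profile$unit)
  }

  ps <- peak_and_fwhm(profile)
  if (ps$no_peak) return(moment_fallback())
  start <- c(A = ps$peak_intensity - min(y), mu = ps$peak_position,
             sigma = max(ps$fwhm / k, diff(range(x)) / length(x)),
             b = min(y))
  sse <- function(p) {
    r <- y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
    sum(r * r)
  }
  scale_y <- max(diff(range(y)), 1)
  opt <- try(stats::optim(start, sse, method = "BFGS",
                          control = list(maxit = 500,
                                         reltol = 1e-14,
                                         parscale = c(scale_y, 1,
                                                      max(start[3], 1e-6),
                                                      scale_y))),
             silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence != 0 ||
      !is.finite(opt$value) || opt$par[3] <= 0 || opt$par[1] <= 0)
    return(moment_fallback())
  p <- opt$par
  list(amplitude = unname(p[1]), mean = unname(p[2]),
       sigma = abs(unname(p[3])), baseline = unname(p[4]),
       fwhm = k * abs(unname(p[3])), rss = opt$value, converged = TRUE,
       unit = profile$unit)
}
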
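# local maxima of a numeric vector; a plateau reports its first sample
local_maxima <- function(y) {
  n <- length(y)
  which(vapply(seq_len(n), function(i) {
    i > 1L && i < n && y[i] > y[i - 1L] && y[i] >= y[i + 1L]
  }, logical(1)))
}

# topographic prominence of peak p: height above the higher of the two
# valley floors separating it from higher ground (or the series edge)
peak_prominence <- function(y, p) {
  n <- length(y)
  left_floor <- {
    i <- p; m <- y[p]
    while (i > 1L && y[i - 1L] <= y[p]) { i <- i - 1L; m <- min(m, y[i]) }
    if (i == 1L) min(y[1:p]) else m
  }
  right_floor <- {
    i <- p; m <- y[p]
    while (i < n && y[i + 1L] <= y[p]) { i <- i + 1L; m <- min(m, y[i]) }
    if (i == n) min(y[p:n]) else m
  }
  y[p] - max(left_floor, right_floor)
}

#' Spectral detector accuracy from a lambda scan
#'
#' A lambda scan sweeps a narrow detection window across wavelengths while
#' reflecting laser light; the per-step mean image intensity forms the
#' detector's spectral response. Reflection peaks are detected as local
#' maxima with topographic prominence of at least 10% of the spectrum
#' maximum; each peak's wavelength, intensity and FWHM (measured on the
#' sub-profile between its flanking minima) are reported. Each reference
#' laser line is matched to the nearest detected peak within 20 nm; lines
#' with no such peak are reported absent — the diagnostic signature of a
#' faulty spectral slider. Two lines matching the same peak flag it as
#' merged (broad slider).
#'
#' @param series [image_stack()] with a `wavelength_axis` (>= 20 monotone
#'   steps).
#' @param detector_id label of the PMT being assessed.
#' @param reference_lines laser lines in nm (default 488, 561, 633).
#' @return a `SpectralResponse` list: `detector_id`, `wavelengths`,
#'   `mean_intensities`, `peaks` (data.frame: wavelength_nm, intensity,
#'   fwhm_nm, merged), `matches` (data.frame: line_nm, peak_nm, offset_nm,
#'   absent), `reference_lines`.
#' @export
lambda_response <- function(series, detector_id = "PMT1",
                            reference_lines = c(488, 561, 633)) {
  stopifnot(inherits(series, "ImageStack"))
  wl <- series$wavelength_axis
  if (is.null(wl)) stop("lambda scan requires a wavelength_axis in the sidecar")
  if (length(wl) < 20L) stop("lambda scan needs >= 20 wavelength steps")
  if (any(diff(wl) <= 0)) stop("wavelength_axis must be strictly increasing")
  Tn <- n_t(series)
  spectrum <- vapply(seq_len(Tn),
                     function(t) mean(series$pixels[t, 1, 1, , ]), numeric(1))

  cand <- local_maxima(spectrum)
  floor_level <- 0.10 * max(spectrum)
  cand <- cand[vapply(cand, function(p) peak_prominence(spectrum, p),
                      numeric(1)) >= floor_level]

  peaks <- data.frame(wavelength_nm = numeric(0), intensity = numeric(0),
                      fwhm_nm = numeric(0), merged = logical(0))
  if (length(cand)) {
    # windows between flanking minima (adjacent detected peaks or edges)
    bounds <- c(1L, vapply(seq_len(length(cand) - 1L), function(k) {
      seg <- cand[k]:cand[k + 1L]
      seg[which.min(spectrum[seg])]
    }, integer(1)), length(spectrum))
    for (k in seq_along(cand)) {
      win <- bounds[k]:bounds[k + 1L]
      fw <- NA_real_
      if (length(win) >= 5L) {
        ps <- peak_and_fwhm(intensity_profile(wl[win], spectrum[win],
                                              unit = "nm"))
        if (!ps$no_peak) fw <- ps$fwhm
      }
      peaks[k, c("wavelength_nm", "intensity", "fwhm_nm")] <-
        c(wl[cand[k]], spectrum[cand[k]], fw)
      peaks$merged[k] <- FALSE
    }
  }

  matches <- data.frame(line_nm = reference_lines, peak_nm = NA_real_,
                        offset_nm = NA_real_,
                        absent = rep(TRUE, length(reference_lines)))
  if (nrow(peaks)) {
    for (i in seq_along(reference_lines)) {
      d <- abs(peaks$wavelength_nm - reference_lines[i])
      j <- which.min(d)
      if (d[j] <= 20) {                 # matching ceiling: 20 nm
        matches$peak_nm[i] <- peaks$wavelength_nm[j]
        matches$offset_nm[i] <- peaks$wavelength_nm[j] - reference_lines[i]
        matches$absent[i] <- FALSE
      }
    }
    dup <- matches$peak_nm[!matches$absent]
    merged_at <- unique(dup[duplicated(dup)])
    peaks$merged <- peaks$wavelength_nm %in% merged_at
  }
  structure(list(detector_id = detector_id, wavelengths = wl,
                 mean_intensities = spectrum, peaks = peaks,
                 matches = matches, reference_lines = reference_lines),
            class = "SpectralResponse")
}
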
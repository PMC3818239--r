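#' Per-frame intensity statistics of a laser stability time lapse
#'
#' For every frame of a single-channel transmitted-light time series the
#' whole-frame mean and standard deviation are computed; the trace
#' summarises intensity drift over the recording. The headline number is
#' the maximum percentage change,
#' `(max(mean) - min(mean)) / overall_mean * 100`, where `overall_mean` is
#' the mean of the per-frame means. Standard deviations are population SDs
#' (divide by N), the convention used throughout the package.
#'
#' @param series an [image_stack()] with T >= 2 and `frame_interval > 0`.
#' @return a `StabilityTrace` list: `times` (s), `mean_intensity`,
#'   `sd_intensity`, `min_mean`, `max_mean`, `overall_mean`,
#'   `max_percent_change`.
#' @export
frame_statistics <- function(series) {
  stopifnot(inherits(series, "ImageStack"))
  Tn <- n_t(series)
  if (Tn < 2L) stop("frame_statistics needs at least 2 frames")
  if (series$frame_interval <= 0)
    stop("frame_statistics needs a positive frame_interval")
  flat <- matrix(aperm(series$pixels[, 1, 1, , , drop = FALSE],
                       c(4, 5, 1, 2, 3)),
                 ncol = Tn)                       # pixels x T
  m <- colMeans(flat)
  s <- sqrt(colMeans(flat^2) - m^2)               # population SD
  overall <- mean(m)
  list(times = (seq_len(Tn) - 1) * series$frame_interval,
       mean_intensity = m, sd_intensity = s,
       min_mean = min(m), max_mean = max(m), overall_mean = overall,
       max_percent_change = (max(m) - min(m)) / overall * 100)
}

#' Short-timescale laser noise from a single line scan
#'
#' Mean, population SD and coefficient of variation of the pixel
#' intensities along one horizontal line of a frame — noise at the pixel
#' dwell timescale.
#'
#' @param first_frame numeric Y x X matrix (conventionally the first frame
#'   of the time lapse).
#' @param row_index 1-based row; defaults to the centre row.
#' @return list with `mean`, `sd`, `cv` (`NA` with `cv_undefined = TRUE`
#'   for a zero-mean line) and the line as an [intensity_profile()].
#' @export
linescan_noise <- function(first_frame, row_index = NULL) {
  stopifnot(is.matrix(first_frame))
  if (is.null(row_index)) row_index <- centre_index(nrow(first_frame))
  if (row_index < 1L || row_index > nrow(first_frame))
    stop("row_index out of bounds")
  v <- as.numeric(first_frame[row_index, ])
  m <- mean(v)
  s <- sqrt(mean(v^2) - m^2)
  cv_undefined <- m == 0
  list(mean = m, sd = s, cv = if (cv_undefined) NA_real_ else s / m,
       cv_undefined = cv_undefined,
       profile = intensity_profile(seq_along(v) - 1, v, unit = "pixel"))
}

# fixed histogram grid: 0.5%-wide bins spanning +-10%, plus open-ended
# overflow bins; symmetric about 0 so drift sign is visible
noise_hist_edges <- c(-Inf, seq(-10, 10, by = 0.5), Inf)

bin_percent_changes <- function(pct) {
  inner <- seq(-10, 10, by = 0.5)
  # bin k is [edges[k], edges[k+1]); bin 1 and the last bin are open-ended
  counts <- tabulate(findInterval(pct, inner) + 1L,
                     nbins = length(inner) + 1L)
  list(edges = noise_hist_edges, frequencies = counts / length(pct),
       n = length(pct))
}

#' Laser noise histograms across timescales
#'
#' Quantifies intensity fluctuation at six timescales by histogramming
#' differences between adjacent data points, expressed as a percentage of
#' the whole-series mean intensity:
#' \describe{
#'   \item{us}{adjacent-pixel differences along the centre row of the first
#'     100 frames (pixel dwell time);}
#'   \item{ms}{adjacent-row mean differences within each of the first 100
#'     frames (line time);}
#'   \item{20s, 1min, 10min, 1h}{differences between the mean intensities
#'     of frames sub-sampled at the nearest integer frame lag to each
#'     nominal interval.}
#' }
#' Scales whose lag exceeds the series duration are omitted (with a
#' message); the us/ms scales are skipped with a warning when T < 100.
#'
#' @param series single-channel [image_stack()] time lapse.
#' @return a `NoiseHistogramSet`: named list of per-scale lists
#'   (`edges` in percent, `frequencies` summing to 1, `n`, `lag_frames`).
#' @export
multiscale_histograms <- function(series) {
  stopifnot(inherits(series, "ImageStack"))
  Tn <- n_t(series)
  flat <- matrix(aperm(series$pixels[, 1, 1, , , drop = FALSE],
                       c(4, 5, 1, 2, 3)),
                 ncol = Tn)
  frame_means <- colMeans(flat)
  series_mean <- mean(frame_means)
  if (series_mean == 0) stop("zero-mean series: percentages undefined")
  out <- list()

  if (Tn >= 100L) {
    yc <- centre_index(n_y(series))
    us <- unlist(lapply(seq_len(100L), function(t) {
      diff(as.numeric(series$pixels[t, 1, 1, yc, ]))
    }))
    out$us <- c(bin_percent_changes(us / series_mean * 100), lag_frames = 0)
    ms <- unlist(lapply(seq_len(100L), function(t) {
      diff(rowMeans(frame_yx(series, t)))
    }))
    out$ms <- c(bin_percent_changes(ms / series_mean * 100), lag_frames = 0)
  } else {
    warning("fewer than 100 frames: us/ms noise scales skipped")
  }

  if (series$frame_interval > 0) {
    nominal <- c(`20s` = 20, `1min` = 60, `10min` = 600, `1h` = 3600)
    for (nm in names(nominal)) {
      lag <- max(1L, round(nominal[[nm]] / series$frame_interval))
      if (lag > Tn - 1L) {
        message("noise scale ", nm, " exceeds the series duration; omitted")
        next
      }
      sub <- frame_means[seq(1L, Tn, by = lag)]
      d <- diff(sub)
      out[[nm]] <- c(bin_percent_changes(d / series_mean * 100),
                     lag_frames = lag)
    }
  }
  structure(out, class = "NoiseHistogramSet")
}
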
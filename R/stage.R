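#' Track a fluorescent bead through a stage time series
#'
#' Per frame: the image is median filtered (radius 7 pixels) to suppress
#' noise, a frame-specific threshold is set at half the filtered maximum,
#' and the original frame is masked with the binarisation (below-threshold
#' pixels set to 0). The intensity-weighted XY centroid and the mean of the
#' remaining non-zero intensities are recorded — the centroid for stage
#' repeatability/accuracy, the mean intensity as a Z-focus-drift proxy.
#' Frames with an empty mask are flagged missing; frames holding more than
#' one bead are rejected.
#'
#' @param series single-channel [image_stack()] T stack.
#' @param position_label which recording this trace belongs to
#'   (`stage1..3` / `stageacc1..3`).
#' @return a `StageTrace` list: `times` (s), `centroids` (T x 2 matrix,
#'   um), `mean_intensity`, `missing` (logical), `position_label`,
#'   `pixel_size_xy`, `stage_positions`, `axes_sign`.
#' @export
track_bead <- function(series, position_label = "stage1") {
  stopifnot(inherits(series, "ImageStack"))
  if (n_c(series) != 1L) stop("track_bead expects a single channel")
  if (series$pixel_size_xy <= 0) stop("track_bead needs XY calibration")
  Tn <- n_t(series)
  cent <- matrix(NA_real_, nrow = Tn, ncol = 2,
                 dimnames = list(NULL, c("x", "y")))
  mi <- rep(NA_real_, Tn)
  missing <- logical(Tn)
  for (t in seq_len(Tn)) {
    frame <- frame_yx(series, t = t)
    filtered <- median_filter_disc(frame, radius = 7L)
    thr <- max(filtered) / 2
    mask <- filtered >= thr
    if (!any(mask) || max(filtered) == 0) {
      missing[t] <- TRUE
      next
    }
    assert_single_bead(mask, what = "frame")
    masked <- frame
    masked[!mask] <- 0
    idx <- which(masked > 0)
    if (!length(idx)) {
      missing[t] <- TRUE
      next
    }
    co <- arrayInd(idx, dim(masked))            # [y, x]
    w <- masked[idx]
    cent[t, "x"] <- (sum(w * co[, 2]) / sum(w) - 1) * series$pixel_size_xy
    cent[t, "y"] <- (sum(w * co[, 1]) / sum(w) - 1) * series$pixel_size_xy
    mi[t] <- mean(w)
  }
  structure(list(times = (seq_len(Tn) - 1) * series$frame_interval,
                 centroids = cent, mean_intensity = mi, missing = missing,
                 position_label = position_label,
                 pixel_size_xy = series$pixel_size_xy,
                 stage_positions = series$stage_positions,
                 axes_sign = series$axes_sign),
            class = "StageTrace")
}

#' Stage repeatability from a bead trace
#'
#' Scatter of the bead centroid when the stage repeatedly revisits one
#' position: per-axis mean and population SD plus the maximum excursion
#' (largest Euclidean distance of any centroid from the mean position).
#'
#' @param trace a [track_bead()] result with >= 10 valid frames.
#' @return a `RepeatabilityStats` list: `mean_position` (um),
#'   `sd` (um, per axis), `max_excursion` (um), `n`.
#' @export
repeatability_stats <- function(trace) {
  stopifnot(inherits(trace, "StageTrace"))
  ok <- !trace$missing
  if (sum(ok) < 10L) stop("repeatability needs >= 10 valid frames")
  p <- trace$centroids[ok, , drop = FALSE]
  mu <- colMeans(p)
  sdv <- sqrt(colMeans(sweep(p, 2, mu)^2))        # population SD
  excur <- sqrt(rowSums(sweep(p, 2, mu)^2))
  list(mean_position = mu, sd = sdv, max_excursion = max(excur), n = nrow(p))
}

#' Stage accuracy: commanded versus executed moves
#'
#' Compares the stage movement recorded in the metadata with the bead
#' centroid movement actually observed in the image. Commanded move k is
#' `stage_positions[k+1] - stage_positions[k]`; the measured move is the
#' centroid displacement converted to stage coordinates. By convention a
#' commanded +X stage move shifts the specimen — and hence the bead — in
#' the -X image direction, so `measured = -axes_sign * displacement`; a
#' sidecar `axes_sign` field overrides the sign per axis for systems wired
#' the other way. Residuals are `commanded - measured`, per move and axis;
#' the scalar version compares Euclidean move lengths.
#'
#' @param trace a [track_bead()] result.
#' @param series optional [image_stack()] supplying `stage_positions` if
#'   the trace lacks them.
#' @return an `AccuracyStats` list: `commanded_moves`, `measured_moves`,
#'   `residuals` (all (T-1) x 2 matrices, um), `scalar_residuals` (um).
#' @export
accuracy_stats <- function(trace, series = NULL) {
  stopifnot(inherits(trace, "StageTrace"))
  sp <- trace$stage_positions %||%
    (if (!is.null(series)) series$stage_positions)
  if (is.null(sp))
    stop("stage accuracy requires stage_positions_um in the metadata sidecar")
  sp <- matrix(as.numeric(sp), ncol = 2)
  if (nrow(sp) != nrow(trace$centroids))
    stop("stage_positions length must match the number of frames")
  if (any(trace$missing))
    stop("accuracy undefined with missing frames (bead lost in ",
         sum(trace$missing), " frame(s))")
  sign2 <- rep_len(trace$axes_sign %||% c(1, 1), 2)
  commanded <- diff(sp)
  displacement <- diff(trace$centroids)
  measured <- sweep(-displacement, 2, sign2, `*`)
  colnames(commanded) <- colnames(measured) <- c("x", "y")
  residuals <- commanded - measured
  list(commanded_moves = commanded, measured_moves = measured,
       residuals = residuals,
       scalar_residuals = sqrt(rowSums(commanded^2)) -
         sqrt(rowSums(measured^2)))
}

#' Contrast-stretched pass-through of a galvo grid image
#'
#' The XY-galvo check images a calibration grid; no quantitative distortion
#' metric is derived — the frame is contrast enhanced (0.5/99.5 percentile
#' stretch, with a degenerate-range guard) for visual inspection in the
#' report.
#'
#' @param image [image_stack()] single frame or Y x X matrix.
#' @return the stretched matrix, same shape as the input frame.
#' @export
grid_passthrough <- function(image) {
  img <- if (inherits(image, "ImageStack")) frame_yx(image) else image
  stopifnot(is.matrix(img))
  contrast_stretch(img, lo = 0.005, hi = 0.995)
}

#' Concatenate stage traces recorded on the same bead
#'
#' The accuracy protocol records up to three series of the same bead;
#' this stitches their traces (and commanded positions) into one.
#'
#' @param traces list of [track_bead()] results.
#' @return a single `StageTrace`.
#' @export
concat_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  if (length(traces) == 1L) return(traces[[1]])
  sp <- lapply(traces, `[[`, "stage_positions")
  structure(list(times = unlist(lapply(traces, `[[`, "times")),
                 centroids = do.call(rbind, lapply(traces, `[[`, "centroids")),
                 mean_intensity = unlist(lapply(traces, `[[`, "mean_intensity")),
                 missing = unlist(lapply(traces, `[[`, "missing")),
                 position_label = traces[[1]]$position_label,
                 pixel_size_xy = traces[[1]]$pixel_size_xy,
                 stage_positions = if (!any(vapply(sp, is.null, logical(1))))
                   do.call(rbind, sp),
                 axes_sign = traces[[1]]$axes_sign),
            class = "StageTrace")
}
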
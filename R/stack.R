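#' Calibrated image stack
#'
#' The package's central container: an intensity raster indexed
#' `[t, c, z, y, x]` (absent axes have extent 1) with the physical
#' calibration needed to express measurements in micrometres, seconds and
#' nanometres. Conventions: indices are 1-based and the physical coordinate
#' of pixel `i` along an axis is `(i - 1) * spacing` (pixel-centre
#' convention), so distances are linear in the spacing.
#'
#' @param pixels numeric array with 5 dimensions `[t, c, z, y, x]`, or a
#'   matrix `[y, x]` which is promoted.
#' @param pixel_size_xy XY pixel size in micrometres (> 0 whenever physical
#'   measurements are requested).
#' @param z_step Z step in micrometres; 0 if the stack has no Z axis.
#' @param frame_interval time between frames in seconds; 0 if no T axis.
#' @param channel_wavelengths numeric vector, nm, one per channel.
#' @param wavelength_axis optional numeric vector, nm, one per T index
#'   (lambda scans).
#' @param stage_positions optional T x 2 matrix of commanded stage (x, y)
#'   positions in micrometres, one row per T index.
#' @param axes_sign length-2 vector of +-1: sign relating commanded stage
#'   motion to apparent bead motion in image coordinates (see
#'   [accuracy_stats()]).
#' @param bit_depth integer bit depth of the detector (8, 12 or 16).
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(pixels, pixel_size_xy = 1, z_step = 0,
                        frame_interval = 0, channel_wavelengths = NULL,
                        wavelength_axis = NULL, stage_positions = NULL,
                        axes_sign = c(1, 1), bit_depth = 16L) {
  if (is.matrix(pixels))
    pixels <- array(pixels, dim = c(1L, 1L, 1L, nrow(pixels), ncol(pixels)))
  if (!is.array(pixels) || length(dim(pixels)) != 5L)
    stop("pixels must be a [t, c, z, y, x] array (or a [y, x] matrix)")
  d <- dim(pixels)
  if (any(d < 1L)) stop("all axis extents must be >= 1")
  if (is.null(channel_wavelengths)) channel_wavelengths <- rep(NA_real_, d[2])
  if (length(channel_wavelengths) != d[2])
    stop("length of channel_wavelengths (", length(channel_wavelengths),
         ") must equal the C extent (", d[2], ")")
  if (!is.null(wavelength_axis) && length(wavelength_axis) != d[1])
    stop("length of wavelength_axis (", length(wavelength_axis),
         ") must equal the T extent (", d[1], ")")
  if (!is.null(stage_positions)) {
    stage_positions <- matrix(as.numeric(unlist(stage_positions)),
                              ncol = 2, byrow = !is.matrix(stage_positions))
    if (nrow(stage_positions) != d[1])
      stop("stage_positions must have one (x, y) row per T index")
  }
  if (pixel_size_xy < 0 || z_step < 0 || frame_interval < 0)
    stop("calibration values must be non-negative")
  structure(list(pixels = pixels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step, frame_interval = frame_interval,
                 channel_wavelengths = as.numeric(channel_wavelengths),
                 wavelength_axis = wavelength_axis,
                 stage_positions = stage_positions,
                 axes_sign = axes_sign,
                 bit_depth = as.integer(bit_depth)),
            class = "ImageStack")
}

#' @export
dim.ImageStack <- function(x) dim(x$pixels)

n_t <- function(s) dim(s$pixels)[1]
n_c <- function(s) dim(s$pixels)[2]
n_z <- function(s) dim(s$pixels)[3]
n_y <- function(s) dim(s$pixels)[4]
n_x <- function(s) dim(s$pixels)[5]

#' Extract a single 2-D frame as a Y x X matrix
#' @param stack an `ImageStack`.
#' @param t,c,z 1-based plane indices.
#' @export
frame_yx <- function(stack, t = 1L, c = 1L, z = 1L) {
  matrix(stack$pixels[t, c, z, , ], nrow = n_y(stack), ncol = n_x(stack))
}

# XZ reflection scans are stored with a real Z axis and Y extent 1;
# this view returns them as a Z x X matrix (rows = Z).
frame_zx <- function(stack, t = 1L, c = 1L) {
  matrix(stack$pixels[t, c, , 1, ], nrow = n_z(stack), ncol = n_x(stack))
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack  T=%d C=%d Z=%d Y=%d X=%d  (%g um/px, z step %g um, dt %g s, %d-bit)\n",
              d[1], d[2], d[3], d[4], d[5], x$pixel_size_xy, x$z_step,
              x$frame_interval, x$bit_depth))
  if (any(!is.na(x$channel_wavelengths)))
    cat("  channels:", paste0(x$channel_wavelengths, "nm", collapse = ", "), "\n")
  invisible(x)
}

# ---- sidecar metadata -------------------------------------------------------

sidecar_path_for <- function(tiff_path) {
  stem <- sub("\\.tiff?$", "", tiff_path, ignore.case = TRUE)
  for (ext in c(".meta.json", ".meta.yaml", ".meta.yml")) {
    p <- paste0(stem, ext)
    if (file.exists(p)) return(p)
  }
  NA_character_
}

# Flat YAML subset: "key: value" lines, values either scalars, inline lists
# [a, b, c], or lists of pairs [[x, y], ...]; '#' comments. Enough for the
# sidecar schema; full YAML needs no dependency this way.
parse_simple_yaml <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln)) stop("sidecar YAML line has no 'key: value': ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    out[[key]] <- if (grepl("^\\[", val)) {
      jsonlite::fromJSON(val, simplifyVector = TRUE)  # inline lists are JSON
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num) && !val %in% c("NA", "nan")) val else num
    }
  }
  out
}

sidecar_fields <- c("pixel_size_xy_um", "z_step_um", "frame_interval_s",
                    "channel_wavelengths_nm", "wavelength_axis_nm",
                    "stage_positions_um", "bit_depth", "size_t", "size_z",
                    "axes_sign")

read_sidecar <- function(path) {
  meta <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    parse_simple_yaml(readLines(path, warn = FALSE))
  }
  unknown <- setdiff(names(meta), sidecar_fields)
  if (length(unknown))
    warning("ignoring unknown sidecar keys: ", paste(unknown, collapse = ", "))
  meta[intersect(names(meta), sidecar_fields)]
}

# ---- stack <-> TIFF + sidecar ----------------------------------------------

#' Read a multi-page TIFF recording and its metadata sidecar
#'
#' The TIFF carries the pixels; a sidecar file `<stem>.meta.json` (or
#' `.meta.yaml`) alongside carries the calibration. Pages are ordered
#' T-major, then C, then Z (`page = ((t-1)*C + (c-1))*Z + z`). The C extent
#' is the length of `channel_wavelengths_nm` (default 1); the T extent is
#' `size_t` (default: length of `wavelength_axis_nm` or of
#' `stage_positions_um` if given, else 1); the Z extent is `size_z`
#' (default: remaining pages). If the TIFF embeds its own metadata (JSON in
#' ImageDescription) and it disagrees with the sidecar, the sidecar wins
#' and a warning is logged.
#'
#' @param tiff_path path to the `.tif` file.
#' @return an [image_stack()].
#' @export
read_stack <- function(tiff_path) {
  if (!file.exists(tiff_path)) stop("no such file: ", tiff_path)
  sc <- sidecar_path_for(tiff_path)
  if (is.na(sc))
    stop("missing metadata sidecar for ", tiff_path,
         ": expected <stem>.meta.json or <stem>.meta.yaml with fields ",
         "pixel_size_xy_um, z_step_um, frame_interval_s, ",
         "channel_wavelengths_nm, wavelength_axis_nm, stage_positions_um, ",
         "bit_depth (plus size_t/size_z for multi-axis stacks)")
  meta <- read_sidecar(sc)
  tif <- read_tiff(tiff_path)

  if (!is.na(tif$description)) {
    emb <- tryCatch(jsonlite::fromJSON(tif$description, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (!is.null(emb)) {
      for (k in intersect(names(emb), names(meta))) {
        same <- isTRUE(all.equal(unname(unlist(emb[[k]])),
                                 unname(unlist(meta[[k]])), tolerance = 1e-9))
        if (!same) {
          warning("embedded TIFF metadata disagrees with sidecar for '", k,
                  "'; the sidecar takes precedence")
          break
        }
      }
    }
  }

  n_pages <- length(tif$pages)
  C <- if (!is.null(meta$channel_wavelengths_nm))
    length(meta$channel_wavelengths_nm) else 1L
  Tn <- meta$size_t
  if (is.null(Tn)) {
    Tn <- if (!is.null(meta$wavelength_axis_nm)) length(meta$wavelength_axis_nm)
    else if (!is.null(meta$stage_positions_um))
      length(unlist(meta$stage_positions_um)) / 2
    else 1L
  }
  Tn <- as.integer(Tn)
  Z <- as.integer(if (!is.null(meta$size_z)) meta$size_z else n_pages / (Tn * C))
  if (Tn * C * Z != n_pages)
    stop("sidecar declares T*C*Z = ", Tn, "*", C, "*", Z, " = ", Tn * C * Z,
         " planes but the TIFF has ", n_pages, " pages: ", tiff_path)

  h <- nrow(tif$pages[[1]]); w <- ncol(tif$pages[[1]])
  px <- array(0, dim = c(Tn, C, Z, h, w))
  p <- 0L
  for (t in seq_len(Tn)) for (cc in seq_len(C)) for (z in seq_len(Z)) {
    p <- p + 1L
    px[t, cc, z, , ] <- tif$pages[[p]]
  }
  sp <- meta$stage_positions_um
  if (!is.null(sp) && !is.matrix(sp))
    sp <- matrix(unlist(sp), ncol = 2, byrow = TRUE)
  image_stack(px,
              pixel_size_xy = meta$pixel_size_xy_um %||% 1,
              z_step = meta$z_step_um %||% 0,
              frame_interval = meta$frame_interval_s %||% 0,
              channel_wavelengths = meta$channel_wavelengths_nm,
              wavelength_axis = meta$wavelength_axis_nm,
              stage_positions = sp,
              axes_sign = meta$axes_sign %||% c(1, 1),
              bit_depth = meta$bit_depth %||% tif$bits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stack_sidecar_list <- function(stack) {
  meta <- list(pixel_size_xy_um = stack$pixel_size_xy,
               z_step_um = stack$z_step,
               frame_interval_s = stack$frame_interval,
               bit_depth = stack$bit_depth,
               size_t = n_t(stack), size_z = n_z(stack))
  if (any(!is.na(stack$channel_wavelengths)) ||
      length(stack$channel_wavelengths) > 1L)
    meta$channel_wavelengths_nm <- stack$channel_wavelengths
  if (!is.null(stack$wavelength_axis))
    meta$wavelength_axis_nm <- stack$wavelength_axis
  if (!is.null(stack$stage_positions))
    meta$stage_positions_um <- unname(split(stack$stage_positions,
                                            row(stack$stage_positions)))
  if (!identical(stack$axes_sign, c(1, 1)))
    meta$axes_sign <- stack$axes_sign
  meta
}

#' Write an ImageStack as multi-page TIFF plus JSON sidecar
#'
#' The inverse of [read_stack()]: pixel values round-trip bit-exactly (they
#' are stored as unsigned integers at the stack's bit depth) and all sidecar
#' fields are preserved. The sidecar JSON is also embedded in the TIFF
#' ImageDescription so the file is self-describing.
#'
#' @param stack an [image_stack()].
#' @param tiff_path output path ending in `.tif`.
#' @return `tiff_path`, invisibly.
#' @export
write_stack <- function(stack, tiff_path) {
  meta <- stack_sidecar_list(stack)
  d <- dim(stack$pixels)
  pages <- vector("list", d[1] * d[2] * d[3])
  p <- 0L
  for (t in seq_len(d[1])) for (cc in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- p + 1L
    pages[[p]] <- matrix(stack$pixels[t, cc, z, , ], nrow = d[4], ncol = d[5])
  }
  bits <- if (stack$bit_depth > 8L) 16L else 8L
  json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  write_tiff(pages, tiff_path, bits = bits, description = as.character(json))
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             paste0(sub("\\.tiff?$", "", tiff_path, ignore.case = TRUE),
                    ".meta.json"))
  invisible(tiff_path)
}
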
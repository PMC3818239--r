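# PNG rendering helpers. These produce the quick-look images of the HTML
# record; all quantitative results live in the measurements TSV, never in
# the plots.

with_png <- function(path, width, height, expr) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  expr
  invisible(path)
}

# grayscale matrix -> PNG (used for grid pass-through and field images)
write_png_matrix <- function(img, path, main = NULL) {
  with_png(path, 480, 480, {
    rng <- range(img)
    norm <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
    graphics::par(mar = c(0.5, 0.5, if (is.null(main)) 0.5 else 2, 0.5))
    graphics::plot.new()
    graphics::plot.window(c(0, ncol(img)), c(0, nrow(img)), asp = 1)
    graphics::rasterImage(grDevices::as.raster(norm), 0, 0,
                          ncol(img), nrow(img))
    if (!is.null(main)) graphics::title(main)
  })
}

# up to three channels -> RGB raster (R = longest wavelength)
rgb_overlay_raster <- function(mats) {
  mats <- mats[seq_len(min(3, length(mats)))]
  norm <- lapply(mats, function(m) {
    rng <- range(m)
    if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  })
  while (length(norm) < 3) norm[[length(norm) + 1]] <- norm[[1]] * 0
  grDevices::as.raster(array(c(norm[[3]], norm[[2]], norm[[1]]),
                             dim = c(dim(norm[[1]]), 3)))
}

#' Plot an intensity profile
#' @param profile an [intensity_profile()].
#' @param path output PNG.
#' @param main plot title.
#' @param marks optional `PeakStats` whose peak and half-max crossings are
#'   dotted onto the curve.
#' @export
plot_profile <- function(profile, path, main = "intensity profile",
                         marks = NULL) {
  with_png(path, 560, 360, {
    graphics::plot(profile$positions, profile$intensities, type = "l",
                   xlab = paste0("position (", profile$unit, ")"),
                   ylab = "intensity", main = main)
    if (!is.null(marks) && !marks$no_peak) {
      graphics::points(marks$peak_position, marks$peak_intensity,
                       pch = 19, col = "red")
      graphics::points(marks$half_max_crossings,
                       rep(marks$half_level, 2), pch = 19, col = "blue")
    }
  })
}

plot_stability_trace <- function(fs, path) {
  with_png(path, 720, 480, {
    graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
    graphics::plot(fs$times, fs$mean_intensity, type = "l",
                   ylim = c(0, max(fs$mean_intensity) * 1.05),
                   xlab = "time (s)", ylab = "mean", main = "mean intensity")
    graphics::plot(fs$times, fs$mean_intensity, type = "l", xlab = "time (s)",
                   ylab = "mean", main = "mean intensity (rescaled)")
    graphics::plot(fs$times, fs$sd_intensity, type = "l", xlab = "time (s)",
                   ylab = "sd", main = "per-frame SD")
  })
}

plot_noise_histograms <- function(hs, path) {
  scales <- names(hs)
  with_png(path, 840, 560, {
    graphics::par(mfrow = c(2, ceiling(length(scales) / 2)),
                  mar = c(3, 3, 2, 1))
    for (nm in scales) {
      h <- hs[[nm]]
      mids <- (utils::head(h$edges, -1) + h$edges[-1]) / 2
      mids[1] <- -10.5; mids[length(mids)] <- 10.5   # overflow bins
      graphics::barplot(h$frequencies, names.arg = round(mids, 1),
                        main = paste0(nm, " (n=", h$n, ")"),
                        ylab = "rel. freq.")
    }
  })
}

plot_axial_overlay <- function(stack, ax, path) {
  mats <- lapply(seq_len(n_c(stack)), function(cc) frame_zx(stack, c = cc))
  with_png(path, 900, 420, {
    graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
    graphics::plot.new()
    graphics::plot.window(c(0, ncol(mats[[1]])), c(0, nrow(mats[[1]])))
    graphics::rasterImage(rgb_overlay_raster(mats), 0, 0,
                          ncol(mats[[1]]), nrow(mats[[1]]))
    graphics::abline(v = ax$line_x, col = "white", lwd = 2)
    graphics::title("XZ reflection overlay")
    graphics::plot(NA, xlim = range(ax$profiles[[1]]$positions),
                   ylim = c(0, max(vapply(ax$profiles, function(p)
                     max(p$intensities), numeric(1)))),
                   xlab = "z (um)", ylab = "intensity",
                   main = "axial profiles")
    cols <- c("blue", "green3", "red")
    for (i in seq_along(ax$profiles)) {
      graphics::lines(ax$profiles[[i]]$positions,
                      ax$profiles[[i]]$intensities,
                      col = cols[(i - 1) %% 3 + 1])
      if (!ax$channels$no_peak[i])
        graphics::points(ax$channels$peak_z_um[i],
                         max(ax$profiles[[i]]$intensities), pch = 19,
                         col = cols[(i - 1) %% 3 + 1])
    }
  })
}

plot_field <- function(fu, path) {
  with_png(path, 960, 360, {
    graphics::par(mfrow = c(1, 3), mar = c(3, 3, 2, 1))
    sm <- contrast_stretch(fu$smoothed)
    rng <- range(sm)
    norm <- if (diff(rng) > 0) (sm - rng[1]) / diff(rng) else sm * 0
    graphics::plot.new()
    graphics::plot.window(c(0, ncol(sm)), c(0, nrow(sm)), asp = 1)
    graphics::rasterImage(grDevices::as.raster(norm), 0, 0, ncol(sm), nrow(sm))
    graphics::abline(h = nrow(sm) / 2, v = ncol(sm) / 2, col = "black")
    graphics::title("field (contrast enhanced)")
    # same data on two intensity scales: full range and rescaled
    for (ylim in list(c(0, fu$max_intensity * 1.05),
                      c(fu$min_intensity * 0.98, fu$max_intensity * 1.02))) {
      graphics::plot(fu$h_profile$positions, fu$h_profile$intensities,
                     type = "l", ylim = ylim, xlab = "position",
                     ylab = "intensity",
                     main = if (ylim[1] == 0) "profiles (full scale)"
                     else "profiles (rescaled)")
      graphics::lines(fu$v_profile$positions, fu$v_profile$intensities,
                      col = "red")
    }
  })
}

# XY/XZ/YZ overlays with Z extended by z_step / pixel_size
plot_bead_overlay <- function(stack, cr, path) {
  zc <- centre_index(n_z(stack))
  ratio <- max(1, round(stack$z_step / stack$pixel_size_xy))
  expand_z <- function(m) m[rep(seq_len(nrow(m)), each = ratio), , drop = FALSE]
  with_png(path, 900, 340, {
    graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
    xy <- lapply(seq_len(n_c(stack)), function(cc)
      matrix(stack$pixels[1, cc, zc, , ], nrow = n_y(stack)))
    yc <- centre_index(n_y(stack)); xc <- centre_index(n_x(stack))
    xz <- lapply(seq_len(n_c(stack)), function(cc)
      expand_z(matrix(stack$pixels[1, cc, , yc, ], nrow = n_z(stack))))
    yz <- lapply(seq_len(n_c(stack)), function(cc)
      expand_z(matrix(stack$pixels[1, cc, , , xc], nrow = n_z(stack))))
    for (view in list(list(m = xy, t = "XY"), list(m = xz, t = "XZ"),
                      list(m = yz, t = "YZ"))) {
      graphics::plot.new()
      graphics::plot.window(c(0, ncol(view$m[[1]])), c(0, nrow(view$m[[1]])),
                            asp = 1)
      graphics::rasterImage(rgb_overlay_raster(view$m), 0, 0,
                            ncol(view$m[[1]]), nrow(view$m[[1]]))
      graphics::title(view$t)
    }
  })
}

plot_psf <- function(stack, ps, path) {
  with_png(path, 900, 340, {
    graphics::par(mfrow = c(1, 3), mar = c(3, 3, 2, 1))
    for (ax in c("x", "y", "z")) {
      pr <- ps$profiles[[ax]]
      fit <- ps$fits[[ax]]
      graphics::plot(pr$positions, pr$intensities, pch = 1,
                     xlab = paste0(ax, " (um)"), ylab = "intensity",
                     main = paste0(toupper(ax), " FWHM ",
                                   signif(switch(ax, x = ps$lateral_fwhm_x,
                                                 y = ps$lateral_fwhm_y,
                                                 z = ps$axial_fwhm), 4),
                                   " um"))
      if (fit$converged) {
        xx <- seq(min(pr$positions), max(pr$positions), length.out = 200)
        graphics::lines(xx, fit$amplitude *
                          exp(-(xx - fit$mean)^2 / (2 * fit$sigma^2)) +
                          fit$baseline, col = "red")
      }
    }
  })
}

# Z-section montage, gamma 0.1, contrast enhanced, pseudo-colour LUT
plot_psf_montage <- function(stack, path) {
  nz <- n_z(stack)
  ncol_m <- ceiling(sqrt(nz))
  nrow_m <- ceiling(nz / ncol_m)
  lut <- grDevices::hcl.colors(256, "Inferno")
  with_png(path, 720, 720, {
    graphics::par(mfrow = c(nrow_m, ncol_m), mar = c(0.1, 0.1, 0.1, 0.1))
    mx <- max(stack$pixels)
    for (z in seq_len(nz)) {
      m <- matrix(stack$pixels[1, 1, z, , ], nrow = n_y(stack))
      g <- (m / mx)^0.1                           # gamma 0.1
      idx <- matrix(pmin(255L, pmax(0L, round(g * 255))) + 1L, nrow = nrow(m))
      graphics::plot.new()
      graphics::plot.window(c(0, ncol(m)), c(0, nrow(m)), asp = 1)
      graphics::rasterImage(grDevices::as.raster(matrix(lut[idx],
                                                        nrow = nrow(m))),
                            0, 0, ncol(m), nrow(m))
    }
  })
}

plot_spectrum <- function(sr, path) {
  with_png(path, 640, 400, {
    graphics::plot(sr$wavelengths, sr$mean_intensities, type = "l",
                   xlab = "wavelength (nm)", ylab = "mean intensity",
                   main = paste0("lambda scan: ", sr$detector_id))
    graphics::abline(v = sr$reference_lines, col = "grey50", lty = 2)
    if (nrow(sr$peaks))
      graphics::points(sr$peaks$wavelength_nm, sr$peaks$intensity,
                       pch = 19, col = "red")
  })
}

plot_stage_scatter <- function(trace, rs, path) {
  with_png(path, 480, 480, {
    ok <- !trace$missing
    graphics::plot(trace$centroids[ok, "x"], trace$centroids[ok, "y"],
                   pch = 19, col = "grey60", asp = 1, xlab = "x (um)",
                   ylab = "y (um)",
                   main = paste0(trace$position_label, " centroid scatter"))
    graphics::points(rs$mean_position[1], rs$mean_position[2], pch = 19,
                     col = "red", cex = 1.4)
    graphics::arrows(rs$mean_position[1] - rs$sd[1], rs$mean_position[2],
                     rs$mean_position[1] + rs$sd[1], rs$mean_position[2],
                     angle = 90, code = 3, length = 0.05, col = "red")
    graphics::arrows(rs$mean_position[1], rs$mean_position[2] - rs$sd[2],
                     rs$mean_position[1], rs$mean_position[2] + rs$sd[2],
                     angle = 90, code = 3, length = 0.05, col = "red")
  })
}

plot_zdrift <- function(zd, path) {
  with_png(path, 640, 480, {
    graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
    graphics::plot(zd$times, zd$peak_z, type = "b", pch = 19, cex = 0.5,
                   xlab = "time (s)", ylab = "peak z (um)",
                   main = paste0("Z drift: total ",
                                 signif(zd$total_drift, 3), " um, ",
                                 signif(zd$drift_rate_um_per_min, 3),
                                 " um/min"))
    graphics::plot(zd$times, zd$fwhm, type = "b", pch = 19, cex = 0.5,
                   xlab = "time (s)", ylab = "FWHM (um)",
                   main = "reflection FWHM (vibration indicator)")
  })
}
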
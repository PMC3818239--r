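# Shared oracles and fixture shorthands. Oracles are deliberately naive
# re-implementations (loops, closed forms) independent of the package code
# paths they check.

FWHM_K <- 2 * sqrt(2 * log(2))

# noiseless sampled Gaussian as an IntensityProfile
gaussian_profile <- function(sigma, spacing, amp = 100, mu = NULL,
                             baseline = 0, half_width = 5 * sigma) {
  x <- seq(0, 2 * half_width, by = spacing)
  if (is.null(mu)) mu <- x[length(x) %/% 2 + 1]
  intensity_profile(x, amp * exp(-(x - mu)^2 / (2 * sigma^2)) + baseline,
                    unit = "um")
}

# brute-force disc mean filter with reflect padding (independent of Rcpp)
brute_mean_filter <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; cnt <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di * di + dj * dj <= radius * radius) {
        acc <- acc + img[refl(i + di, nr), refl(j + dj, nc)]
        cnt <- cnt + 1
      }
    }
    out[i, j] <- acc / cnt
  }
  out
}

# brute-force re-computation of the field-uniformity statistic
brute_field_percent_difference <- function(img) {
  sm <- brute_mean_filter(img, 5L)
  band_mean <- function(m, centre, horizontal) {
    lo <- centre - 5L
    idx <- (lo:(lo + 9L))
    idx <- idx[idx >= 1 & idx <= (if (horizontal) nrow(m) else ncol(m))]
    if (horizontal) colMeans(m[idx, , drop = FALSE])
    else rowMeans(m[, idx, drop = FALSE])
  }
  h <- band_mean(sm, nrow(sm) %/% 2 + 1, TRUE)
  v <- band_mean(sm, ncol(sm) %/% 2 + 1, FALSE)
  s <- c(h, v)
  (max(s) - min(s)) / max(s) * 100
}

# minimal valid config for orchestration tests
demo_config <- function(system = "TestSP5", objectives = "63x") {
  parse_config(c(paste0("system=", system),
                 paste0("objectives=", paste(objectives, collapse = ",")),
                 "lasers.field=405,488,561,633",
                 "lasers.spectral=488,561,633"))
}

# extract the per-run <section> blocks of a report page, verbatim
entry_sections <- function(page) {
  lines <- readLines(page, warn = FALSE)
  starts <- grep("^<!-- scopeqc:entry:", lines)
  ends <- which(lines == "</section>")
  mapply(function(s, e) paste(lines[s:e], collapse = "\n"), starts, ends)
}

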
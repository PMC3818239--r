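measurement_columns <- c("timestamp", "system", "objective", "assay",
                         "parameter", "value", "units")

#' Build measurement rows
#'
#' One row per named scalar result, the schema of the measurements TSV:
#' `timestamp  system  objective  assay  parameter  value  units`.
#'
#' @param system,objective,assay labels.
#' @param values named numeric vector (names become `parameter`).
#' @param units character, recycled across `values`.
#' @param timestamp ISO-8601 string; default: now (UTC).
#' @return data.frame of `MeasurementRow`s.
#' @export
measurement_rows <- function(system, objective, assay, values, units = "",
                             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                                tz = "UTC")) {
  stopifnot(length(values) >= 1L, !is.null(names(values)))
  ok <- is.finite(values)
  data.frame(timestamp = timestamp, system = system, objective = objective,
             assay = assay, parameter = names(values)[ok],
             value = as.numeric(values)[ok],
             units = rep_len(units, length(values))[ok],
             stringsAsFactors = FALSE)
}

#' Append measurement rows to a tab-delimited file
#'
#' Plain UTF-8 TSV openable in any editor or spreadsheet. The header is
#' written once; subsequent calls append rows only. Values are serialised
#' with 6 significant digits, so re-reading reproduces them within 1e-6
#' relative.
#'
#' @param rows data.frame with the [measurement_rows()] columns.
#' @param path output file.
#' @export
write_measurements <- function(rows, path) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  missing_cols <- setdiff(measurement_columns, names(rows))
  if (length(missing_cols))
    stop("rows lack column(s): ", paste(missing_cols, collapse = ", "))
  rows <- rows[measurement_columns]
  # 7 significant digits: guarantees <= 5e-7 relative round-trip error
  rows$value <- vapply(rows$value, function(v) format(v, digits = 7),
                       character(1))
  new_file <- !file.exists(path)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = new_file,
                     append = !new_file, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measurements TSV back into a data.frame
#' @param path file written by [write_measurements()].
#' @export
read_measurements <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = c(
                      timestamp = "character", system = "character",
                      objective = "character", assay = "character",
                      parameter = "character", value = "numeric",
                      units = "character"))
}

# ---- HTML record ------------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste(c("<table border='1' cellspacing='0' cellpadding='3'>", head, body,
          "</table>"), collapse = "\n")
}

nav_start <- "<!-- scopeqc:nav:start -->"
nav_end <- "<!-- scopeqc:nav:end -->"
entries_start <- "<!-- scopeqc:entries:start -->"
entries_end <- "<!-- scopeqc:entries:end -->"

objective_page_skeleton <- function(system, objective) {
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>%s &mdash; %s</title>", html_escape(system),
            html_escape(objective)),
    "<style>body{font-family:sans-serif;margin:1em;} section{border-top:2px solid #444;margin-top:1.5em;} nav{background:#eef;padding:0.5em;}</style>",
    "</head><body>",
    sprintf("<h1>%s / %s</h1>", html_escape(system), html_escape(objective)),
    nav_start, nav_end, entries_start, entries_end, "</body></html>")
}

render_entry <- function(entry) {
  out <- c(sprintf("<!-- scopeqc:entry:%s -->", entry$timestamp),
           "<section>",
           sprintf("<h2>Run %s</h2>", html_escape(entry$timestamp)))
  for (nm in names(entry$tables)) {
    out <- c(out, sprintf("<h3>%s</h3>", html_escape(nm)),
             html_table(entry$tables[[nm]]))
  }
  for (img in entry$images %||% character(0))
    out <- c(out, sprintf("<div><img src='%s' alt='%s'></div>",
                          html_escape(img), html_escape(basename(img))))
  c(out, "</section>")
}

render_nav <- function(report_dir, system) {
  pages <- sort(setdiff(list.files(file.path(report_dir, system),
                                   pattern = "\\.html$"), "index.html"))
  c("<nav>Objectives: ",
    paste(sprintf("<a href='%s'>%s</a>", pages,
                  html_escape(sub("\\.html$", "", pages))), collapse = " | "),
    "</nav>")
}

#' Append a run to the per-system, per-objective HTML record
#'
#' The report is a static tree `report_dir/<system>/index.html` plus one
#' page per objective. Each analysis run adds a new dated section to the
#' objective page; earlier sections are never modified (byte-for-byte,
#' except the regenerated navigation block), giving a tamper-evident
#' history of the instrument. A page whose structural markers are missing
#' (corrupted by hand editing) is backed up with a timestamp suffix and
#' rebuilt from the measurements TSV.
#'
#' @param report_dir root of the HTML tree.
#' @param system,objective labels.
#' @param entry list with `timestamp` (ISO-8601), `tables` (named list of
#'   data.frames) and optional `images` (paths relative to the objective
#'   page).
#' @param measurements_tsv TSV used to rebuild a corrupt page.
#' @export
update_html_report <- function(report_dir, system, objective, entry,
                               measurements_tsv = NULL) {
  sys_dir <- file.path(report_dir, system)
  dir.create(sys_dir, recursive = TRUE, showWarnings = FALSE)
  page <- file.path(sys_dir, paste0(objective, ".html"))

  lines <- if (file.exists(page)) readLines(page, warn = FALSE)
  else objective_page_skeleton(system, objective)

  if (!any(lines == entries_end) || !any(lines == nav_start) ||
      !any(lines == nav_end) || !any(lines == entries_start)) {
    backup <- paste0(page, ".corrupt-",
                     format(Sys.time(), "%Y%m%d%H%M%S"), ".bak")
    file.copy(page, backup)
    warning("report page ", page, " is corrupt; backed up to ", backup,
            " and rebuilt", if (!is.null(measurements_tsv))
              " from the measurements TSV")
    lines <- objective_page_skeleton(system, objective)
    if (!is.null(measurements_tsv) && file.exists(measurements_tsv)) {
      tsv <- read_measurements(measurements_tsv)
      tsv <- tsv[tsv$system == system & tsv$objective == objective, ]
      for (ts in unique(tsv$timestamp)) {
        old <- list(timestamp = ts,
                    tables = list(measurements = tsv[tsv$timestamp == ts,
                                                     c("assay", "parameter",
                                                       "value", "units")]))
        i_end <- which(lines == entries_end)
        lines <- append(lines, render_entry(old), after = i_end - 1L)
      }
    }
  }

  prev_ts <- sub("^<!-- scopeqc:entry:(.*) -->$", "\\1",
                 grep("^<!-- scopeqc:entry:", lines, value = TRUE))
  if (length(prev_ts) && any(prev_ts >= entry$timestamp))
    stop("report entries must be strictly time-ordered; page already has ",
         "an entry at or after ", entry$timestamp)

  i_end <- which(lines == entries_end)
  lines <- append(lines, render_entry(entry), after = i_end - 1L)

  # regenerate the navigation block (the only mutable region)
  i_ns <- which(lines == nav_start); i_ne <- which(lines == nav_end)
  writeLines(lines[seq_len(i_ns)], page)  # provisional, so nav sees this page
  lines <- c(lines[seq_len(i_ns)], render_nav(report_dir, system),
             lines[i_ne:length(lines)])
  writeLines(lines, page)

  index <- file.path(sys_dir, "index.html")
  pages <- sort(setdiff(list.files(sys_dir, pattern = "\\.html$"),
                        "index.html"))
  writeLines(c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
               sprintf("<title>%s</title>", html_escape(system)),
               "</head><body>",
               sprintf("<h1>%s</h1>", html_escape(system)),
               render_nav(report_dir, system),
               "</body></html>"), index)
  invisible(page)
}

# ---- orchestration ----------------------------------------------------------

assay_of_keyword <- function(kw) {
  if (grepl("^axial[0-9]{3}$", kw)) return("axial")
  if (grepl("^field[0-9]{3}$", kw)) return("field")
  if (grepl("^scanpmt[0-9]+$", kw)) return("spectral")
  switch(kw, laser = "laser", bead = "bead", psf = "psf", grid = "grid",
         stage = "stage", stageacc = "stageacc", zgalvo = "zgalvo",
         NA_character_)
}

#' Run every discoverable assay of a dataset
#'
#' Discovers the keyword-named recordings of one objective's directory,
#' dispatches each to its assay, appends all scalar results to
#' `out_dir/measurements.tsv`, renders the result images as PNGs under
#' `out_dir/img/`, and amends the HTML record. Per-assay failures are
#' isolated: a corrupt recording marks that assay failed and the run
#' continues; only a dataset with no recognised recordings is a hard
#' error.
#'
#' @param config a [parse_config()] result.
#' @param dataset_dir directory of recordings for one objective.
#' @param out_dir output directory (created).
#' @param objective objective label (must be listed in `config`).
#' @param html_dir optional HTML report root (default `out_dir/html`).
#' @param timestamp ISO-8601 run timestamp (defaults to now).
#' @return list with `rows` (the measurement data.frame), `failures`
#'   (named character of error messages), `dataset`, `status` (0 on
#'   success including isolated per-assay failures).
#' @export
run_suite <- function(config, dataset_dir, out_dir,
                      objective = basename(dataset_dir),
                      html_dir = file.path(out_dir, "html"),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                         tz = "UTC")) {
  stopifnot(inherits(config, "SystemConfig"))
  if (!objective %in% config$objectives)
    warning("objective ", sQuote(objective),
            " is not listed in the system configuration")
  ds <- discover_dataset(dataset_dir, objective)
  if (!length(ds$recordings))
    stop("no recognised recordings in ", dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "img")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)

  sysname <- config$system_name
  all_rows <- list(); failures <- character(0); tables <- list()
  images <- character(0)
  add_rows <- function(assay, values, units = "") {
    all_rows[[length(all_rows) + 1L]] <<-
      measurement_rows(sysname, objective, assay, values, units,
                       timestamp = timestamp)
  }
  img_path <- function(name) {
    p <- file.path(img_dir, paste0(objective, "_", name, "_",
                                   gsub("[:]", "", timestamp), ".png"))
    images <<- c(images, p)
    p
  }

  for (kw in names(ds$recordings)) {
    paths <- ds$recordings[[kw]]
    assay <- assay_of_keyword(kw)
    if (is.na(assay)) next
    res <- tryCatch({
      switch(assay,
        laser = {
          st <- read_stack(paths)
          fs <- frame_statistics(st)
          ln <- linescan_noise(frame_yx(st, t = 1L))
          hs <- multiscale_histograms(st)
          add_rows(kw, c(mean_intensity = fs$overall_mean,
                         min_mean = fs$min_mean, max_mean = fs$max_mean,
                         max_percent_change = fs$max_percent_change),
                   "counts")
          add_rows(kw, c(linescan_mean = ln$mean, linescan_sd = ln$sd,
                         linescan_cv = ln$cv), "")
          plot_stability_trace(fs, img_path(paste0(kw, "_trace")))
          plot_profile(ln$profile, img_path(paste0(kw, "_linescan")),
                       main = "first-frame line scan")
          plot_noise_histograms(hs, img_path(paste0(kw, "_hist")))
          tables[[kw]] <- data.frame(
            parameter = c("max_percent_change", "linescan_cv"),
            value = c(fs$max_percent_change, ln$cv))
          TRUE
        },
        axial = {
          st <- read_stack(paths)
          ax <- axial_channels_analysis(st)
          for (i in seq_len(nrow(ax$channels))) {
            ch <- ax$channels[i, ]
            if (ch$no_peak) next
            add_rows(kw, stats::setNames(
              c(ch$peak_z_um, ch$fwhm_um, ax$delta_z_vs_reference[i]),
              paste0(c("peak_z_", "fwhm_", "delta_z_vs_ref_"),
                     ch$wavelength_nm, "nm")), "um")
          }
          plot_axial_overlay(st, ax, img_path(paste0(kw, "_overlay")))
          tables[[kw]] <- ax$channels
          TRUE
        },
        field = {
          st <- read_stack(paths)
          wl <- as.numeric(sub("^field", "", kw))
          fu <- field_uniformity(st, wavelength = wl)
          add_rows(kw, c(min_intensity = fu$min_intensity,
                         max_intensity = fu$max_intensity), "counts")
          add_rows(kw, c(percent_difference = fu$percent_difference,
                         percent_difference_vs_mean =
                           fu$percent_difference_vs_mean), "%")
          plot_field(fu, img_path(paste0(kw, "_field")))
          tables[[kw]] <- data.frame(
            parameter = c("percent_difference", "saturated"),
            value = c(fu$percent_difference, as.numeric(fu$saturated)))
          TRUE
        },
        bead = {
          st <- read_stack(paths)
          cr <- bead_centroids(st)
          wls <- vapply(cr$records, `[[`, numeric(1), "channel_wavelength")
          for (i in seq_along(cr$records)) {
            r <- cr$records[[i]]
            if (r$absent) next
            add_rows(kw, stats::setNames(r$centroid,
                     paste0("centroid_", c("x_", "y_", "z_"), wls[i], "nm")),
                     "um")
          }
          pairs <- which(upper.tri(cr$xy_distance), arr.ind = TRUE)
          vals <- c()
          for (p in seq_len(nrow(pairs))) {
            i <- pairs[p, 1]; j <- pairs[p, 2]
            vals[paste0("xy_dist_", wls[i], "_", wls[j])] <-
              cr$xy_distance[i, j]
            vals[paste0("z_dist_", wls[i], "_", wls[j])] <- cr$z_distance[i, j]
          }
          add_rows(kw, vals, "um")
          plot_bead_overlay(st, cr, img_path(paste0(kw, "_overlay")))
          tables[[kw]] <- data.frame(pair = names(vals), value = vals,
                                      row.names = NULL)
          TRUE
        },
        psf = {
          st <- read_stack(paths)
          ps <- psf_metrics(st)
          add_rows(kw, c(lateral_fwhm_x = ps$lateral_fwhm_x,
                         lateral_fwhm_y = ps$lateral_fwhm_y,
                         lateral_fwhm_mean = ps$lateral_fwhm_mean,
                         axial_fwhm = ps$axial_fwhm), "um")
          plot_psf(st, ps, img_path(paste0(kw, "_views")))
          plot_psf_montage(st, img_path(paste0(kw, "_montage")))
          tables[[kw]] <- data.frame(
            parameter = c("lateral_fwhm_x", "lateral_fwhm_y", "axial_fwhm"),
            value = c(ps$lateral_fwhm_x, ps$lateral_fwhm_y, ps$axial_fwhm))
          TRUE
        },
        spectral = {
          st <- read_stack(paths)
          ref <- config$lasers_by_assay$spectral %||% c(488, 561, 633)
          sr <- lambda_response(st, detector_id = kw, reference_lines = ref)
          for (i in seq_len(nrow(sr$matches))) {
            m <- sr$matches[i, ]
            if (m$absent) {
              add_rows(kw, stats::setNames(-1, paste0("line_", m$line_nm,
                                                      "_absent")), "")
            } else {
              add_rows(kw, stats::setNames(
                c(m$peak_nm, m$offset_nm),
                paste0(c("peak_nm_line_", "offset_nm_line_"), m$line_nm)),
                "nm")
            }
          }
          plot_spectrum(sr, img_path(paste0(kw, "_spectrum")))
          tables[[kw]] <- sr$matches
          TRUE
        },
        grid = {
          st <- read_stack(paths)
          g <- grid_passthrough(st)
          write_png_matrix(g, img_path(paste0(kw, "_enhanced")))
          add_rows(kw, c(width_px = ncol(g), height_px = nrow(g)), "px")
          TRUE
        },
        stage = {
          for (k in seq_along(paths)) {
            st <- read_stack(paths[k])
            lab <- paste0("stage", k)
            tr <- track_bead(st, position_label = lab)
            rs <- repeatability_stats(tr)
            add_rows(kw, stats::setNames(
              c(rs$mean_position, rs$sd, rs$max_excursion),
              paste0(lab, "_", c("mean_x", "mean_y", "sd_x", "sd_y",
                                 "max_excursion"))), "um")
            plot_stage_scatter(tr, rs, img_path(paste0(lab, "_scatter")))
          }
          TRUE
        },
        stageacc = {
          traces <- lapply(seq_along(paths), function(k)
            track_bead(read_stack(paths[k]),
                       position_label = paste0("stageacc", k)))
          tr <- concat_traces(traces)
          ac <- accuracy_stats(tr)
          add_rows(kw, c(mean_residual_x = mean(ac$residuals[, "x"]),
                         mean_residual_y = mean(ac$residuals[, "y"]),
                         max_abs_residual = max(abs(ac$residuals)),
                         mean_scalar_residual = mean(ac$scalar_residuals)),
                   "um")
          tables[[kw]] <- data.frame(move = seq_len(nrow(ac$residuals)),
                                      residual_x = ac$residuals[, "x"],
                                      residual_y = ac$residuals[, "y"])
          TRUE
        },
        zgalvo = {
          st <- read_stack(paths)
          zd <- zgalvo_drift(st)
          add_rows(kw, c(total_drift = zd$total_drift,
                         drift_rate_um_per_min = zd$drift_rate_um_per_min,
                         mean_fwhm = mean(zd$fwhm, na.rm = TRUE),
                         sd_fwhm = stats::sd(zd$fwhm, na.rm = TRUE)), "um")
          plot_zdrift(zd, img_path(paste0(kw, "_drift")))
          TRUE
        })
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(res)) {
      failures[kw] <- res
      message("assay ", kw, " failed: ", res)
    }
  }

  rows <- do.call(rbind, all_rows)
  tsv <- file.path(out_dir, "measurements.tsv")
  if (!is.null(rows) && nrow(rows)) write_measurements(rows, tsv)
  if (length(failures))
    tables[["failures"]] <- data.frame(assay = names(failures),
                                       error = unname(failures))
  if (!is.null(rows) && nrow(rows)) {
    entry <- list(timestamp = timestamp, tables = tables,
                  images = file.path("..", "..", "img", basename(images)))
    update_html_report(html_dir, sysname, objective, entry,
                       measurements_tsv = tsv)
  }
  list(rows = rows, failures = failures, dataset = ds, status = 0L)
}
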
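#' Parse a system configuration file
#'
#' Line-oriented dialect describing one confocal system: which objective
#' lenses are installed and which laser lines each assay uses.
#'
#' ```
#' # comment
#' system=SP5-inverted
#' objectives=10x,20x,63x
#' lasers.field=405,488,561,633
#' lasers.axial=458,488,561
#' ```
#'
#' Unknown keys are ignored with a warning. Laser wavelengths must lie in
#' 350-700 nm (the visible-range lines of a confocal excitation set).
#'
#' @param text either a file path or a character vector of lines.
#' @return a `SystemConfig`: list with `system_name`, `objectives`
#'   (character), `lasers_by_assay` (named list of numeric nm vectors).
#' @export
parse_config <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text))
    readLines(text, warn = FALSE) else text
  raw_lines <- lines
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  idx <- which(keep); lines <- lines[keep]

  system_name <- NULL; objectives <- NULL
  lasers <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!grepl("=", ln))
      stop("configuration line ", idx[k], " is not 'key=value': ",
           sQuote(raw_lines[idx[k]]))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (key == "system") {
      system_name <- val
    } else if (key == "objectives") {
      objectives <- trimws(strsplit(val, ",")[[1]])
      objectives <- objectives[nzchar(objectives)]
    } else if (grepl("^lasers\\.", key)) {
      assay <- sub("^lasers\\.", "", key)
      nm <- suppressWarnings(as.numeric(trimws(strsplit(val, ",")[[1]])))
      if (anyNA(nm))
        stop("configuration line ", idx[k], ": non-numeric laser value in ",
             sQuote(raw_lines[idx[k]]))
      if (any(nm < 350 | nm > 700))
        stop("configuration line ", idx[k], ": laser wavelength outside ",
             "350-700 nm in ", sQuote(raw_lines[idx[k]]))
      lasers[[assay]] <- nm
    } else {
      warning("ignoring unknown configuration key ", sQuote(key),
              " (line ", idx[k], ")")
    }
  }
  if (is.null(system_name) || !nzchar(system_name))
    stop("configuration error: no 'system=NAME' line found")
  if (is.null(objectives) || !length(objectives))
    stop("configuration error: no non-empty 'objectives=' line found")
  dup <- unique(objectives[duplicated(objectives)])
  if (length(dup))
    stop("configuration error: duplicate objective label(s): ",
         paste(dup, collapse = ", "))
  structure(list(system_name = system_name, objectives = objectives,
                 lasers_by_assay = lasers),
            class = "SystemConfig")
}

#' @export
print.SystemConfig <- function(x, ...) {
  cat("SystemConfig:", x$system_name, "\n  objectives:",
      paste(x$objectives, collapse = ", "), "\n")
  for (a in names(x$lasers_by_assay))
    cat("  lasers.", a, ": ", paste(x$lasers_by_assay[[a]], collapse = ", "),
        " nm\n", sep = "")
  invisible(x)
}
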
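#' Discover the recordings of a QC dataset directory
#'
#' Scans one directory (one objective lens) for keyword-named TIFF
#' recordings. File stems are matched case-insensitively against the assay
#' keywords: `laser`, `axial<nm>`, `field<nm>`, `bead`, `psf`,
#' `scanpmt<k>`, `grid`, `stage1..3`, `stageacc1..3`, `zgalvo`. The
#' `stage`/`stageacc` series collapse to one entry each holding up to three
#' ordered paths; every other keyword maps to exactly one file. File and
#' folder names must not contain whitespace (a hard error), and files whose
#' stems match no keyword are returned in a skipped-report rather than
#' failing the run.
#'
#' @param dir dataset directory.
#' @param objective objective label this directory belongs to.
#' @return a `Dataset`: list with `root`, `objective`, `recordings` (named
#'   list keyword -> character vector of paths) and `skipped`.
#' @export
discover_dataset <- function(dir, objective = basename(dir)) {
  if (!dir.exists(dir)) stop("no such dataset directory: ", dir)
  files <- list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE, recursive = FALSE)
  bad <- grep("\\s", c(dir, files), value = TRUE)
  if (length(bad))
    stop("file and folder names must not contain any spaces: ",
         sQuote(bad[1]))

  recordings <- list(); skipped <- character(0)
  # stageacc before stage and the parameterised keywords before the bare
  # ones, so each stem matches its most specific keyword
  numbered <- list(stageacc = "^stageacc([1-3])", stage = "^stage([1-3])")
  parameterised <- c(axial = "axial([0-9]{3})", field = "field([0-9]{3})",
                     scanpmt = "scanpmt([0-9]+)")
  plain <- c("zgalvo", "laser", "bead", "psf", "grid")

  for (f in sort(files)) {
    stem <- tolower(sub("\\.tiff?$", "", basename(f), ignore.case = TRUE))
    matched <- FALSE
    for (kw in names(numbered)) {
      m <- regmatches(stem, regexec(numbered[[kw]], stem))[[1]]
      if (length(m)) {
        ord <- as.integer(m[2])
        cur <- recordings[[kw]] %||% c(NA_character_, NA_character_, NA_character_)
        if (!is.na(cur[ord]))
          stop("duplicate recording for keyword ", sQuote(paste0(kw, ord)),
               ": ", sQuote(basename(f)))
        cur[ord] <- f
        recordings[[kw]] <- cur
        matched <- TRUE
        break
      }
    }
    if (!matched) for (kw in names(parameterised)) {
      m <- regmatches(stem, regexec(parameterised[[kw]], stem))[[1]]
      if (length(m)) {
        key <- paste0(kw, m[2])
        if (!is.null(recordings[[key]]))
          stop("duplicate recording for keyword ", sQuote(key), ": ",
               sQuote(basename(f)))
        recordings[[key]] <- f
        matched <- TRUE
        break
      }
    }
    if (!matched) for (kw in plain) {
      if (grepl(kw, stem, fixed = TRUE)) {
        if (!is.null(recordings[[kw]]))
          stop("duplicate recording for keyword ", sQuote(kw), ": ",
               sQuote(basename(f)))
        recordings[[kw]] <- f
        matched <- TRUE
        break
      }
    }
    if (!matched) skipped <- c(skipped, f)
  }
  for (kw in names(numbered))
    if (!is.null(recordings[[kw]]))
      recordings[[kw]] <- recordings[[kw]][!is.na(recordings[[kw]])]
  if (length(recordings))
    recordings <- recordings[order(names(recordings))]
  structure(list(root = dir, objective = objective,
                 recordings = recordings, skipped = skipped),
            class = "Dataset")
}

#' @export
print.Dataset <- function(x, ...) {
  cat("Dataset", sQuote(x$objective), "at", x$root, "\n")
  for (kw in names(x$recordings))
    cat(sprintf("  %-10s %s\n", kw,
                paste(basename(x$recordings[[kw]]), collapse = ", ")))
  if (length(x$skipped))
    cat("  skipped:", paste(basename(x$skipped), collapse = ", "), "\n")
  invisible(x)
}
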
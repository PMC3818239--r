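#' Minimal multi-page TIFF codec
#'
#' Baseline TIFF only: uncompressed, single-sample grayscale, 8 or 16 bit,
#' little- or big-endian, any number of pages (IFDs). This deliberately
#' covers exactly the interchange subset the package writes itself; vendor
#' formats and compressed TIFFs are rejected with a clear error. An optional
#' ImageDescription tag is read back verbatim (used for embedded-metadata
#' precedence checks against the sidecar).
#'
#' @param path file path.
#' @return `read_tiff()`: list with `pages` (list of numeric Y x X matrices),
#'   `bits` (8 or 16) and `description` (character or `NA`).
#' @keywords internal
#' @noRd
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2L, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer",
                 size = 4L, signed = TRUE, endian = endian)
    if (v < 0) stop("TIFF offset exceeds 2GB; unsupported")
    v
  }
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic): ", path)

  read_entry_values <- function(entry_off) {
    type <- u16(entry_off + 2L)
    count <- u32(entry_off + 4L)
    size <- switch(as.character(type), `1` = 1L, `2` = 1L, `3` = 2L,
                   `4` = 4L, NULL)
    if (is.null(size)) return(NULL)  # type we never emit; skip
    total <- size * count
    voff <- if (total <= 4L) entry_off + 8L else u32(entry_off + 8L)
    bytes <- raw[(voff + 1):(voff + total)]
    if (type == 2L) return(rawToChar(bytes[bytes != as.raw(0)]))
    readBin(bytes, "integer", n = count, size = size,
            signed = (size == 4L), endian = endian)
  }

  pages <- list()
  description <- NA_character_
  bits <- NULL
  ifd_off <- u32(4L)
  while (ifd_off != 0L) {
    n_entries <- u16(ifd_off)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + (k - 1L) * 12L
      tags[[as.character(u16(eoff))]] <- read_entry_values(eoff)
    }
    getv <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width <- getv(256); height <- getv(257)
    if (is.null(width) || is.null(height))
      stop("TIFF page missing dimensions: ", path)
    page_bits <- getv(258, 1L)
    if (!page_bits %in% c(8L, 16L))
      stop("unsupported TIFF bit depth ", page_bits, " (only 8/16): ", path)
    if (getv(259, 1L) != 1L)
      stop("compressed TIFF not supported (baseline uncompressed only): ", path)
    if (getv(277, 1L) != 1L)
      stop("multi-sample TIFF not supported (grayscale only): ", path)
    if (!is.na(d <- getv(270, NA_character_)) && is.na(description))
      description <- d
    offsets <- getv(273); counts <- getv(279)
    if (is.null(offsets) || is.null(counts))
      stop("TIFF page missing strip layout: ", path)
    pix <- integer(0)
    for (s in seq_along(offsets)) {
      bytes <- raw[(offsets[s] + 1):(offsets[s] + counts[s])]
      pix <- c(pix, readBin(bytes, "integer", n = counts[s] %/% (page_bits / 8L),
                            size = page_bits / 8L, signed = FALSE,
                            endian = endian))
    }
    if (length(pix) != width * height)
      stop("TIFF strip data does not match page dimensions: ", path)
    # TIFF stores rows (Y) consecutively; matrix is Y x X
    pages[[length(pages) + 1L]] <-
      matrix(as.numeric(pix), nrow = height, ncol = width, byrow = TRUE)
    if (is.null(bits)) bits <- page_bits
    ifd_off <- u32(ifd_off + 2L + n_entries * 12L)
  }
  if (!length(pages)) stop("TIFF contains no images: ", path)
  list(pages = pages, bits = bits, description = description)
}

#' @param pages list of Y x X numeric matrices (all same shape) or a 3-D
#'   array indexed `[page, y, x]`; values are clamped to the range of `bits`
#'   and rounded to integers.
#' @param bits 8 or 16.
#' @param description optional ASCII string embedded as ImageDescription on
#'   the first page.
#' @keywords internal
#' @noRd
write_tiff <- function(pages, path, bits = 16L, description = NULL) {
  if (is.array(pages) && length(dim(pages)) == 3L)
    pages <- lapply(seq_len(dim(pages)[1]), function(p) pages[p, , , drop = TRUE])
  stopifnot(bits %in% c(8L, 16L), length(pages) >= 1L)
  height <- nrow(pages[[1]]); width <- ncol(pages[[1]])
  bytes_pp <- bits / 8L
  maxval <- 2^bits - 1

  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0))
    if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0))
  }

  # layout per page: [pixel strip][description (page 1 only)][IFD]
  n_tags <- function(p) if (p == 1L && !is.null(desc_raw)) 10L else 9L
  ifd_size <- function(p) 2L + n_tags(p) * 12L + 4L
  strip_bytes <- width * height * bytes_pp
  offset <- 8L
  strip_off <- integer(length(pages)); desc_off <- 0L
  ifd_off <- integer(length(pages))
  for (p in seq_along(pages)) {
    strip_off[p] <- offset
    offset <- offset + strip_bytes
    if (p == 1L && !is.null(desc_raw)) {
      desc_off <- offset
      offset <- offset + length(desc_raw)
    }
    ifd_off[p] <- offset
    offset <- offset + ifd_size(p)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2L)
  wb(ifd_off[1L], 4L)

  entry <- function(tag, type, count, value) {
    wb(tag, 2L); wb(type, 2L); wb(count, 4L)
    if (type == 3L && count == 1L) { wb(value, 2L); wb(0L, 2L) } else wb(value, 4L)
  }
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    stopifnot(nrow(m) == height, ncol(m) == width)
    v <- round(as.numeric(t(m)))          # row-major pixel order
    v[v < 0] <- 0; v[v > maxval] <- maxval
    wb(v, bytes_pp)
    if (p == 1L && !is.null(desc_raw)) writeBin(desc_raw, con)
    wb(n_tags(p), 2L)
    entry(256L, 4L, 1L, width)
    entry(257L, 4L, 1L, height)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)               # no compression
    entry(262L, 3L, 1L, 1L)               # BlackIsZero
    if (p == 1L && !is.null(desc_raw))
      entry(270L, 2L, length(desc_raw), desc_off)
    entry(273L, 4L, 1L, strip_off[p])
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, height)
    entry(279L, 4L, 1L, strip_bytes)
    wb(if (p < length(pages)) ifd_off[p + 1L] else 0L, 4L)
  }
  invisible(path)
}
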
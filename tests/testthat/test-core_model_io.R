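test_that("parse_config parses systems, objectives and lasers", {
  cfg <- parse_config(c("# demo", "system=SP5-1", "objectives=10x,20x,63x",
                        "lasers.field=405,488,561,633"))
  expect_s3_class(cfg, "SystemConfig")
  expect_identical(cfg$system_name, "SP5-1")
  expect_length(cfg$objectives, 3L)
  expect_equal(cfg$lasers_by_assay$field, c(405, 488, 561, 633))
})

test_that("parse_config rejects degenerate and invalid input", {
  expect_error(parse_config(character(0)), "system")
  expect_error(parse_config(c("system=S", "objectives=")), "objectives")
  expect_error(parse_config(c("system=S", "objectives=10x,20x,10x")),
               "duplicate.*10x")
  expect_error(parse_config(c("system=S", "objectives=10x",
                              "lasers.field=405,9000")), "350-700")
  expect_warning(parse_config(c("system=S", "objectives=10x",
                                "colour=mauve")), "unknown")
})

make_dataset_dir <- function(names) {
  d <- file.path(tempfile("ds"), "obj63x")
  dir.create(d, recursive = TRUE)
  for (nm in names) file.create(file.path(d, nm))
  d
}

test_that("discover_dataset maps keyword-named files to recordings", {
  d <- make_dataset_dir(c("bead.tif", "psf.tif", "field405.tif",
                          "notes_image.tif"))
  ds <- discover_dataset(d, "63x")
  expect_setequal(names(ds$recordings), c("bead", "psf", "field405"))
  expect_length(ds$skipped, 1L)
  # idempotent and independent of listing order
  ds2 <- discover_dataset(d, "63x")
  expect_identical(ds$recordings, ds2$recordings)
})

test_that("discover_dataset collects stage series and rejects whitespace", {
  d <- make_dataset_dir(c("stage1.tif", "stage2.tif", "stage3.tif",
                          "stageacc1.tif", "stageacc2.tif"))
  ds <- discover_dataset(d)
  expect_length(ds$recordings$stage, 3L)
  expect_length(ds$recordings$stageacc, 2L)
  expect_match(basename(ds$recordings$stage[1]), "^stage1")

  d2 <- make_dataset_dir("my bead.tif")
  expect_error(discover_dataset(d2), "must not contain any spaces.*my bead")
  d3 <- make_dataset_dir(c("bead.tif", "bead_old.tif"))
  expect_error(discover_dataset(d3), "duplicate")
})

test_that("write_stack / read_stack round-trips pixels and metadata", {
  fx <- generate_fixture("stage", list(n_frames = 12L, nx = 32L, ny = 32L),
                         seed = 5)
  p <- file.path(tempfile("rt"), "stage1.tif")
  dir.create(dirname(p))
  write_stack(fx$stack, p)
  st <- read_stack(p)
  expect_identical(st$pixels, fx$stack$pixels)     # bit-exact
  expect_equal(st$pixel_size_xy, fx$stack$pixel_size_xy)
  expect_equal(st$frame_interval, fx$stack$frame_interval)
  expect_equal(st$stage_positions, fx$stack$stage_positions)
  expect_equal(st$bit_depth, fx$stack$bit_depth)

  fx2 <- generate_fixture("lambda", list(n_steps = 25L, nx = 8L, ny = 8L),
                          seed = 5)
  p2 <- file.path(dirname(p), "scanpmt1.tif")
  write_stack(fx2$stack, p2)
  st2 <- read_stack(p2)
  expect_identical(st2$pixels, fx2$stack$pixels)
  expect_equal(st2$wavelength_axis, fx2$stack$wavelength_axis)
})

test_that("read_stack validates the sidecar contract", {
  fx <- generate_fixture("axial", list(nx = 16L, nz = 21L), seed = 1)
  d <- tempfile("sc"); dir.create(d)
  p <- file.path(d, "axial488.tif")
  write_stack(fx$stack, p)

  # sidecar declaring a wrong channel count -> extent mismatch error
  scp <- file.path(d, "axial488.meta.json")
  meta <- jsonlite::fromJSON(scp)
  meta$channel_wavelengths_nm <- c(405, 458, 488, 561)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)), scp)
  expect_error(suppressWarnings(read_stack(p)), "pages")

  # missing sidecar -> instructive error
  file.remove(scp)
  expect_error(read_stack(p), "sidecar.*pixel_size_xy_um")
})

test_that("sidecar wins over embedded TIFF metadata, with a warning", {
  fx <- generate_fixture("field", list(nx = 64L, ny = 64L), seed = 2)
  d <- tempfile("emb"); dir.create(d)
  p <- file.path(d, "field488.tif")
  write_stack(fx$stack, p)               # embeds metadata in ImageDescription
  scp <- file.path(d, "field488.meta.json")
  meta <- jsonlite::fromJSON(scp)
  meta$pixel_size_xy_um <- 0.77          # sidecar now disagrees
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)), scp)
  expect_warning(st <- read_stack(p), "sidecar takes precedence")
  expect_equal(st$pixel_size_xy, 0.77)
})

test_that("YAML sidecars (flat subset) are accepted", {
  fx <- generate_fixture("field", list(nx = 64L, ny = 64L), seed = 3)
  d <- tempfile("yml"); dir.create(d)
  p <- file.path(d, "field405.tif")
  write_stack(fx$stack, p)
  file.remove(file.path(d, "field405.meta.json"))
  writeLines(c("# flat sidecar", "pixel_size_xy_um: 0.25",
               "channel_wavelengths_nm: [405]", "bit_depth: 16"),
             file.path(d, "field405.meta.yaml"))
  st <- suppressWarnings(read_stack(p))  # embedded metadata now disagrees
  expect_equal(st$pixel_size_xy, 0.25)
  expect_equal(st$channel_wavelengths, 405)
})

test_that("image_stack enforces its axis and metadata invariants", {
  px <- array(0, dim = c(2, 1, 1, 4, 4))
  expect_error(image_stack(px, channel_wavelengths = c(488, 561)),
               "C extent")
  expect_error(image_stack(px, wavelength_axis = c(488, 500, 512)),
               "T extent")
  expect_error(image_stack(px, stage_positions = matrix(0, 3, 2)),
               "one \\(x, y\\) row per T")
  expect_silent(image_stack(px, wavelength_axis = c(488, 500)))
})
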
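rows_for <- function(values, ts = "2026-01-01T00:00:00Z") {
  measurement_rows("S1", "63x", "bead", values, "um", timestamp = ts)
}

test_that("measurements TSV appends without duplicating the header", {
  p <- tempfile(fileext = ".tsv")
  write_measurements(rows_for(c(a = 1, b = 2, c = 3)), p)
  expect_length(readLines(p), 4L)                 # header + 3 rows
  write_measurements(rows_for(c(d = 4), ts = "2026-01-02T00:00:00Z"), p)
  lines <- readLines(p)
  expect_length(lines, 5L)
  expect_length(grep("^timestamp\t", lines), 1L)
})

test_that("values round-trip through the TSV within 1e-6 relative", {
  p <- tempfile(fileext = ".tsv")
  vals <- c(root5 = sqrt(0.05), tiny = 1.234567e-7, big = 98765.4321)
  write_measurements(rows_for(vals), p)
  back <- read_measurements(p)
  expect_equal(back$value, unname(vals), tolerance = 1e-6)
  expect_error(write_measurements(data.frame(x = 1), p), "lack column")
})

test_that("HTML record grows by dated sections, prior entries immutable", {
  root <- tempfile("html")
  e1 <- list(timestamp = "2026-01-01T10:00:00Z",
             tables = list(bead = data.frame(pair = "488_561", value = 0.12)))
  update_html_report(root, "S1", "63x", e1)
  page <- file.path(root, "S1", "63x.html")
  expect_true(file.exists(page))
  expect_length(entry_sections(page), 1L)

  before <- entry_sections(page)
  e2 <- list(timestamp = "2026-02-01T10:00:00Z",
             tables = list(bead = data.frame(pair = "488_561", value = 0.19)))
  update_html_report(root, "S1", "63x", e2)
  after <- entry_sections(page)
  expect_length(after, 2L)
  expect_identical(after[1], before[1])           # byte-for-byte preserved

  # out-of-order timestamps are refused
  expect_error(update_html_report(root, "S1", "63x", e1), "time-ordered")
})

test_that("two objectives produce two pages under one system index", {
  root <- tempfile("html2")
  e <- list(timestamp = "2026-01-01T10:00:00Z",
            tables = list(t = data.frame(v = 1)))
  update_html_report(root, "S1", "10x", e)
  update_html_report(root, "S1", "63x", e)
  expect_setequal(list.files(file.path(root, "S1")),
                  c("index.html", "10x.html", "63x.html"))
  idx <- readLines(file.path(root, "S1", "index.html"))
  expect_true(any(grepl("10x.html", idx)) && any(grepl("63x.html", idx)))
})

test_that("a corrupt page is backed up and rebuilt from the TSV", {
  root <- tempfile("html3")
  tsv <- tempfile(fileext = ".tsv")
  write_measurements(rows_for(c(xy_dist = 0.11)), tsv)
  e1 <- list(timestamp = "2026-01-01T00:00:00Z",
             tables = list(t = data.frame(v = 1)))
  update_html_report(root, "S1", "63x", e1, measurements_tsv = tsv)
  page <- file.path(root, "S1", "63x.html")
  writeLines("<html><body>mangled by hand</body></html>", page)
  e2 <- list(timestamp = "2026-03-01T00:00:00Z",
             tables = list(t = data.frame(v = 2)))
  expect_warning(update_html_report(root, "S1", "63x", e2,
                                    measurements_tsv = tsv), "corrupt")
  expect_length(list.files(file.path(root, "S1"), pattern = "\\.bak$"), 1L)
  secs <- entry_sections(page)
  expect_length(secs, 2L)                   # rebuilt entry + new entry
  expect_match(secs[1], "xy_dist")          # history restored from TSV
})

test_that("run_suite analyses whatever the dataset offers", {
  d <- tempfile("one"); dir.create(d)
  fx <- generate_fixture("field", seed = 1)
  write_stack(fx$stack, file.path(d, "field488.tif"))
  out <- tempfile("out1")
  res <- run_suite(demo_config(), d, out, objective = "63x")
  expect_equal(res$status, 0L)
  expect_setequal(unique(res$rows$assay), "field488")
  expect_true(file.exists(file.path(out, "measurements.tsv")))
})

test_that("run_suite isolates per-assay failures", {
  d <- tempfile("fault"); dir.create(d)
  fx <- generate_fixture("field", seed = 2)
  write_stack(fx$stack, file.path(d, "field488.tif"))
  writeLines("this is not a TIFF", file.path(d, "bead.tif"))
  writeLines('{"pixel_size_xy_um": 0.1}', file.path(d, "bead.meta.json"))
  out <- tempfile("out2")
  res <- run_suite(demo_config(), d, out, objective = "63x")
  expect_equal(res$status, 0L)
  expect_named(res$failures, "bead")
  expect_setequal(unique(res$rows$assay), "field488")
})

test_that("run_suite refuses a dataset with nothing recognisable", {
  d <- tempfile("empty"); dir.create(d)
  expect_error(run_suite(demo_config(), d, tempfile(), objective = "63x"),
               "no recognised")
})
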
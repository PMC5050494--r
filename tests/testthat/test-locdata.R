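test_that("ThunderSTORM CSV is read with nm coordinates and 0-based frames", {
  path <- tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","frame"',
               "100,200,1", "110,210,1", "500,500,2"), path)
  tab <- read_localizations(path)
  expect_s3_class(tab, "loc_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$frame, c(0L, 0L, 1L))
  expect_equal(tab$x, c(100, 110, 500))
  expect_equal(loc_region(tab), c(100, 200, 500, 500))
})

test_that("pixel-unit coordinates are scaled by the pixel size", {
  path <- tempfile(fileext = ".csv")
  writeLines(c('"x [px]","y [px]","frame"',
               "100,200,1", "110,210,1", "500,500,2"), path)
  tab <- read_localizations(path, reader_config(pixel_size_nm = 100))
  expect_equal(tab$x, c(10000, 11000, 50000))
  expect_equal(tab$y, c(20000, 21000, 50000))
})

test_that("a missing mandatory column raises a schema error naming the role", {
  path <- tempfile(fileext = ".csv")
  writeLines(c('"y [nm]","frame"', "200,1"), path)
  expect_error(read_localizations(path), "'x'")
})

test_that("non-numeric cells are reported with their row number", {
  path <- tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","frame"', "100,200,1", "oops,210,1"), path)
  expect_error(read_localizations(path), "row 2")
})

test_that("the rapidSTORM dialect is parsed from its XML header", {
  path <- system.file("extdata", "rapidstorm_synthetic.txt",
                      package = "smlmtools")
  tab <- read_localizations(path)
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$frame[1:4], c(0L, 0L, 1L, 1L))  # already 0-based
  expect_equal(tab$x[1], 100)
  expect_true(all(c("photons", "psf_sigma") %in% names(tab)))
  # the ThunderSTORM twin of the same data agrees after frame re-basing
  ts <- read_localizations(system.file("extdata",
                                       "thunderstorm_synthetic.csv",
                                       package = "smlmtools"))
  expect_equal(ts$x, tab$x)
  expect_equal(ts$y, tab$y)
  expect_equal(ts$frame, tab$frame)
})

test_that("write/read round trips are lossless for both dialects", {
  for (dialect in c("thunderstorm", "internal")) {
    for (seed in 1:3) {
      tab <- random_table(n = 40L, seed = seed)
      path <- tempfile()
      write_localizations(tab, path, dialect = dialect)
      back <- read_localizations(path)
      expect_equal(back$x, tab$x, tolerance = 1e-9)
      expect_equal(back$y, tab$y, tolerance = 1e-9)
      expect_equal(back$frame, tab$frame)
      expect_equal(back$photons, tab$photons, tolerance = 1e-9)
    }
  }
})

test_that("an empty table writes a header-only file that reads back empty", {
  tab <- loc_table(data.frame(x = numeric(0), y = numeric(0),
                              frame = integer(0)))
  path <- tempfile(fileext = ".csv")
  write_localizations(tab, path, "thunderstorm")
  expect_equal(nrow(read_localizations(path)), 0L)
})

test_that("reading is independent of line endings", {
  lines <- c('"x [nm]","y [nm]","frame"', "100,200,1", "110,210,1")
  p_unix <- tempfile(); p_dos <- tempfile()
  writeLines(lines, p_unix, sep = "\n")
  writeLines(lines, p_dos, sep = "\r\n")
  expect_equal(as.data.frame(read_localizations(p_unix)),
               as.data.frame(read_localizations(p_dos)))
})

test_that("unknown extra columns are carried through untouched", {
  path <- tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","frame","detections"',
               "100,200,1,7", "110,210,1,9"), path)
  tab <- read_localizations(path)
  expect_equal(tab$detections, c(7, 9))
  out <- tempfile()
  write_localizations(tab, out, "internal")
  expect_equal(read_localizations(out)$detections, c(7, 9))
})

test_that("rectangular ROI filtering is half-open and updates the region", {
  tab <- three_row_table()
  sub <- filter_localizations(tab, roi = c(0, 0, 300, 300))
  expect_equal(nrow(sub), 2L)
  expect_equal(loc_region(sub), c(0, 0, 300, 300))
  # a point on the upper edge is excluded, on the lower edge included
  edge <- loc_table(data.frame(x = c(0, 300), y = c(0, 0), frame = 0L))
  expect_equal(nrow(filter_localizations(edge, roi = c(0, 0, 300, 300))), 1L)
})

test_that("frame and photon filters behave and compose", {
  tab <- three_row_table()
  expect_equal(nrow(filter_localizations(tab, frame_range = c(0, 0))), 2L)
  expect_error(filter_localizations(tab, frame_range = c(2, 1)), "inverted")
  expect_equal(as.data.frame(filter_localizations(tab)),
               as.data.frame(tab))  # all-NULL filters = identity
  wp <- random_table(30, seed = 4)
  kept <- filter_localizations(wp, min_photons = 1000)
  expect_true(all(kept$photons >= 1000))
})

test_that("filtering is idempotent", {
  tab <- random_table(60, seed = 5)
  f1 <- filter_localizations(tab, roi = c(2000, 2000, 15000, 15000),
                             frame_range = c(10, 80))
  f2 <- filter_localizations(f1, roi = c(2000, 2000, 15000, 15000),
                             frame_range = c(10, 80))
  expect_equal(as.data.frame(f1), as.data.frame(f2))
  expect_equal(loc_region(f1), loc_region(f2))
})

test_that("polygon ROIs use point-in-polygon containment", {
  tab <- loc_table(data.frame(x = c(10, 20, 90), y = c(10, 30, 90),
                              frame = 0L))
  tri <- cbind(c(0, 100, 0), c(0, 0, 100))
  expect_equal(nrow(filter_localizations(tab, roi = tri)), 2L)
  bowtie <- cbind(c(0, 100, 100, 0), c(0, 100, 0, 100))
  expect_error(filter_localizations(tab, roi = bowtie), "simple")
})

test_that("invariant violations are rejected at construction", {
  expect_error(loc_table(data.frame(x = NA_real_, y = 1, frame = 0)),
               "finite")
  expect_error(loc_table(data.frame(x = 1, y = 1, frame = -1)), "frame")
  expect_error(loc_table(data.frame(x = 1, y = 1, frame = 0,
                                    psf_sigma = 0)), "psf_sigma")
  expect_error(loc_table(data.frame(x = 5, y = 5, frame = 0),
                         region = c(0, 0, 1, 1)), "outside")
})
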
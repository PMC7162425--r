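test_that("detection_table validates its fields", {
  dt <- detection_table(x = c(0, 10), y = c(0, 5), frame = c(1, 2),
                        intensity = c(1200, 900), uncertainty = c(10, 20))
  expect_s3_class(dt, "detection_table")
  expect_equal(det_dim(dt), 2L)
  expect_equal(det_coords(dt), cbind(x = c(0, 10), y = c(0, 5)))

  dt3 <- detection_table(x = 0, y = 0, z = 5)
  expect_equal(det_dim(dt3), 3L)
  expect_equal(ncol(det_coords(dt3)), 3L)

  expect_error(detection_table(x = 1:3, y = 1:2), "equal length")
  expect_error(detection_table(x = c(0, NA), y = c(0, 1)), "finite")
  expect_error(detection_table(x = 0, y = 0, frame = -1), "non-negative")
  expect_error(detection_table(x = 0, y = 0, frame = 1.5), "non-negative")
  expect_error(detection_table(x = 0, y = 0, uncertainty = -2), ">= 0")
  expect_error(detection_table(x = 0, y = 0,
                               extra = data.frame(x = 1)), "reserved")
})

test_that("ThunderSTORM-style files round-trip including extra columns", {
  dt <- detection_table(x = c(100.5, 200.25), y = c(50, 75.5),
                        frame = c(3L, 4L), intensity = c(1500, 2500),
                        uncertainty = c(12.5, 8),
                        extra = data.frame(chi2 = c(1.1, 0.9)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(dt, path)

  header <- readLines(path, n = 1)
  expect_match(header, "x [nm]", fixed = TRUE)
  expect_match(header, "intensity [photon]", fixed = TRUE)

  back <- read_detections(path)
  expect_equal(as.data.frame(back), as.data.frame(dt))

  # tab-separated files are auto-detected
  path2 <- withr::local_tempfile(fileext = ".xls")
  write_detections(dt, path2, sep = "\t")
  expect_equal(as.data.frame(read_detections(path2)), as.data.frame(dt))

  # cluster labels appended on request
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_detections(dt, path3, labels = c(1L, 0L))
  raw <- read.csv(path3, check.names = FALSE)
  expect_equal(raw$cluster, c(1L, 0L))
})

test_that("read_detections reports format and parse errors precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_detections(path), "format error.*x \\[nm\\]")

  writeLines(c("x [nm],y [nm]", "1,2", "oops,4"), path)
  expect_error(read_detections(path), "parse error in column 'x \\[nm\\]', row 2")

  expect_error(read_detections(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("intensity filter keeps photon counts >= the bound, inclusively", {
  dt <- detection_table(x = 1:4, y = 1:4,
                        intensity = c(999, 1000, 1001, 500))
  kept <- filter_by_intensity(dt, 1000)
  expect_equal(kept$intensity, c(1000, 1001))
  expect_equal(kept$x, c(2, 3))
  expect_error(filter_by_intensity(detection_table(x = 1, y = 1)),
               "no intensity")
})

test_that("consecutive-frame linking merges chains within 75 nm", {
  # one fluorophore on for frames 1-3 (drifting 30 nm per frame), plus an
  # isolated detection two frames later at the same place
  dt <- detection_table(x = c(0, 30, 60, 60), y = c(0, 0, 0, 0),
                        frame = c(1L, 2L, 3L, 5L),
                        intensity = c(1000, 2000, 1000, 500),
                        uncertainty = c(20, 10, 30, 5))
  out <- link_consecutive_frames(dt, max_dist = 75)
  expect_equal(nrow(out), 2L)
  # intensity-weighted mean position, summed intensity, first frame, min sigma
  expect_equal(out$x[1], (0 * 1000 + 30 * 2000 + 60 * 1000) / 4000)
  expect_equal(out$intensity[1], 4000)
  expect_equal(out$frame[1], 1L)
  expect_equal(out$uncertainty[1], 10)
  expect_equal(out$x[2], 60)

  # beyond the linking radius nothing merges
  far <- detection_table(x = c(0, 76), y = c(0, 0), frame = c(1L, 2L))
  expect_equal(nrow(link_consecutive_frames(far, 75)), 2L)
  # at exactly the radius it does (inclusive)
  near <- detection_table(x = c(0, 75), y = c(0, 0), frame = c(1L, 2L))
  expect_equal(nrow(link_consecutive_frames(near, 75)), 1L)
})

test_that("frame linking claims nearest candidates one-to-one", {
  # two chains in frame 1; frame 2 has two candidates, each chain should
  # claim its nearest without double-claiming
  dt <- detection_table(x = c(0, 100, 10, 90), y = rep(0, 4),
                        frame = c(1L, 1L, 2L, 2L))
  out <- link_consecutive_frames(dt, max_dist = 75)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$x), c(5, 95))
})
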
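test_that("calibration rejects missing or non-positive fields", {
  expect_error(calibration(0), "pixel_size_xy")
  expect_error(calibration(-0.1), "pixel_size_xy")
  expect_error(calibration(0.1, z_step = 0), "z_step")
  expect_error(calibration(0.1, frame_interval = -3), "frame_interval")
  cal <- calibration(0.1)
  expect_error(cal_require(cal, "z_step", "angle"), "z_step")
  expect_error(cal_frame_interval_min(cal), "frame_interval")
})

test_that("calibrated images enforce axis and intensity invariants", {
  cal <- calibration(0.1)
  expect_error(calibrated_image(array(1, c(4, 4)), c("y", "y"), cal),
               "unique")
  expect_error(calibrated_image(array(1, c(4, 4)), c("z", "x"), cal), "'y'")
  expect_error(calibrated_image(array(-1, c(4, 4)), c("y", "x"), cal),
               "non-negative")
  # axis order normalized to (channel, time, z, y, x)
  img <- calibrated_image(array(seq_len(24), c(4, 3, 2)),
                          c("y", "x", "channel"), cal)
  expect_identical(img$axes, c("channel", "y", "x"))
  expect_identical(dim(img$data), c(2L, 4L, 3L))
  expect_equal(image_plane(img, 2)[1, 1], 13)
})

test_that("multi-channel TIFF round trip preserves data, axes and calibration", {
  cal <- calibration(0.1083, z_step = 0.25)
  set.seed(1)
  data <- array(sample(0:4095, 3 * 64 * 64, replace = TRUE), c(3, 64, 64))
  img <- calibrated_image(data, c("channel", "y", "x"), cal,
                          channel_names = c("poles", "kinetochores", "GFP"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_tiff(img, path)
  back <- read_calibrated_tiff(path)
  expect_identical(back$axes, img$axes)
  expect_identical(back$channel_names, img$channel_names)
  expect_equal(back$data, img$data)  # bit-exact for integer data
  expect_equal(back$calibration$pixel_size_xy, 0.1083)
  expect_equal(back$calibration$z_step, 0.25)
})

test_that("5D (c,t,z,y,x) stacks round-trip with axes preserved", {
  cal <- calibration(0.1, z_step = 0.2, frame_interval = 1,
                     time_unit = "min")
  set.seed(2)
  data <- array(sample(0:255, 2 * 3 * 4 * 8 * 8, replace = TRUE),
                c(2, 3, 4, 8, 8))
  img <- calibrated_image(data, c("channel", "time", "z", "y", "x"), cal)
  path <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_tiff(img, path)
  back <- read_calibrated_tiff(path)
  expect_identical(back$axes, c("channel", "time", "z", "y", "x"))
  expect_equal(back$data, img$data)
})

test_that("reading without calibration fails naming the missing field", {
  cal <- calibration(0.1)
  img <- calibrated_image(matrix(1, 8, 8), c("y", "x"), cal)
  path <- withr::local_tempfile(fileext = ".tif")
  write_calibrated_tiff(img, path)
  file.remove(sidecar_path <- paste0(path, ".json"))
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("z_step: 0.25", cfg)
  expect_error(read_calibrated_tiff(path, cfg), "pixel_size_xy")
  writeLines(c("pixel_size_xy: 0.1", "axes: [y, x]"), cfg)
  back <- read_calibrated_tiff(path, cfg)
  expect_equal(back$data[, ], matrix(1, 8, 8))
})

test_that("GroupTable round-trips through CSV and rejects duplicates", {
  tab <- group_table(c("ctrl", "ctrl", "kd"), c("r1", "r1", "r1"),
                     c("c1", "c2", "c1"), "fwhm_um", c(3.1, 3.4, 5.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(tab, path)
  back <- read_results_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # empty table -> header-only CSV
  empty <- group_table(character(), character(), character(), character(),
                       numeric())
  write_results_table(empty, path)
  expect_identical(readLines(path),
    "\"condition_label\",\"replicate_id\",\"cell_id\",\"metric_name\",\"value\"")
  expect_error(
    group_table(c("a", "a"), c("r", "r"), c("c", "c"), c("m", "m"), 1:2),
    "duplicate")
})

test_that("event tables enforce ordering invariants", {
  expect_error(event_table("c1", NA, 20L, 100L), "without nuclear envelope")
  expect_error(event_table("c1", 20L, 20L, 100L), "greater than")
  expect_error(event_table("c1", 20L, 30L, 25L), "movie_end_frame")
  ev <- event_table(c("a", "b"), c(10L, 15L), c(20L, NA), c(100L, 100L))
  expect_s3_class(ev, "EventTable")
})

test_that("physical lengths scale linearly with pixel size", {
  pp <- pole_pair(c(0, 0), c(100, 0))
  expect_equal(spindle_length(pp, calibration(0.1)), 10)
  expect_equal(spindle_length(pp, calibration(0.2)), 20)
  tr <- pole_track(1:3, c(0, 10, 20), c(0, 0, 0))
  v1 <- rotation_displacement(tr, calibration(0.1, frame_interval = 1,
                                              time_unit = "min"))
  v2 <- rotation_displacement(tr, calibration(0.2, frame_interval = 1,
                                              time_unit = "min"))
  expect_equal(v2, 2 * v1)
})
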
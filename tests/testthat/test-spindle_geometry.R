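test_that("pole detection recovers manifest positions to sub-pixel", {
  sim <- quiet_bipolar(14)
  pp <- detect_poles(sim$image, "poles", 2)
  px <- sim$manifest$pixel_size
  truth <- sim$manifest$pole_positions[, 1:2] / px
  # detected pair may come in either order
  d1 <- sqrt(sum((pp$p1 - truth[1, ])^2)) + sqrt(sum((pp$p2 - truth[2, ])^2))
  d2 <- sqrt(sum((pp$p1 - truth[2, ])^2)) + sqrt(sum((pp$p2 - truth[1, ])^2))
  expect_lt(min(d1, d2) / 2, 0.5)
})

test_that("monopolar detection with expected = 1 finds the single pole", {
  sim <- quiet_monopolar(15)
  p <- detect_poles(sim$image, "poles", 1)
  truth <- sim$manifest$pole_positions[1, 1:2] / sim$manifest$pixel_size
  expect_lt(sqrt(sum((p - truth)^2)), 0.5)
})

test_that("blank images raise a detection error", {
  img <- calibrated_image(matrix(5, 64, 64), c("y", "x"), calibration(0.1))
  expect_error(detect_poles(img, 1, 2), "maxima")
})

test_that("spindle length matches closed forms and the manifest", {
  cal <- calibration(0.1)
  expect_equal(spindle_length(pole_pair(c(0, 0), c(100, 0)), cal), 10)
  expect_error(pole_pair(c(5, 5), c(5, 5)), "distinct")
  sim <- quiet_bipolar(16, spindle_length = 12)
  pp <- detect_poles(sim$image, "poles", 2)
  expect_equal(spindle_length(pp, sim$image$calibration), 12,
               tolerance = 0.1 / 12)
})

test_that("pole-axis angle follows the dot-product closed forms", {
  cal <- calibration(0.1, z_step = 0.25)
  # in um: (10, 0, 0), (0, 0, 2), (3, 0, 4)
  expect_equal(pole_axis_angle(pole_pair(c(0, 0, 0), c(100, 0, 0)), cal), 0)
  expect_equal(pole_axis_angle(pole_pair(c(0, 0, 0), c(0, 0, 8)), cal), 90)
  expect_equal(pole_axis_angle(pole_pair(c(0, 0, 0), c(30, 0, 16)), cal),
               atan2(4, 3) * 180 / pi, tolerance = 1e-8)
  # missing z calibration is an explicit error
  expect_error(pole_axis_angle(pole_pair(c(0, 0, 0), c(30, 0, 16)),
                               calibration(0.1)), "z_step")
  expect_error(pole_axis_angle(pole_pair(c(0, 0), c(30, 0)), cal), "z")
})

test_that("angle is invariant to xy-rotation and pole swap", {
  cal <- calibration(0.1083, z_step = 0.25)
  base <- c(40, 25, 10)
  for (th in c(0.3, 1.2, 2.5)) {
    rot <- c(base[1] * cos(th) - base[2] * sin(th),
             base[1] * sin(th) + base[2] * cos(th), base[3])
    a0 <- pole_axis_angle(pole_pair(c(0, 0, 0), base), cal)
    expect_equal(pole_axis_angle(pole_pair(c(0, 0, 0), rot), cal), a0,
                 tolerance = 1e-10)
    expect_equal(pole_axis_angle(pole_pair(base, c(0, 0, 0)), cal), a0)
  }
})

test_that("length and angle are recovered on random synthetic pole pairs", {
  cal <- calibration(0.1083, z_step = 0.25)
  set.seed(99)
  for (i in 1:100) {
    p1 <- c(runif(2, 0, 50), runif(1, 0, 20))
    p2 <- c(runif(2, 0, 50), runif(1, 0, 20))
    if (all(p1 == p2)) next
    pp <- pole_pair(p1, p2)
    d_um <- c((p2[1:2] - p1[1:2]) * 0.1083, (p2[3] - p1[3]) * 0.25)
    expect_equal(spindle_length(pp, cal), sqrt(sum(d_um^2)),
                 tolerance = 1e-10)
    truth <- asin(abs(d_um[3]) / sqrt(sum(d_um^2))) * 180 / pi
    expect_equal(pole_axis_angle(pp, cal), truth, tolerance = 1e-6)
  }
})

test_that("rotation displacement implements path length over elapsed time", {
  cal <- calibration(0.1, frame_interval = 1, time_unit = "min")
  still <- pole_track(1:30, rep(5, 30), rep(5, 30))
  expect_equal(rotation_displacement(still, cal), 0)
  # 1 um advance per frame at 1 min/frame
  adv <- pole_track(1:10, seq(0, 90, by = 10), rep(0, 10))
  expect_equal(rotation_displacement(adv, cal), 1)
  # invariant to rigid translation
  shifted <- pole_track(1:10, seq(0, 90, by = 10) + 40, rep(25, 10))
  expect_equal(rotation_displacement(shifted, cal), 1)
  expect_error(rotation_displacement(pole_track(1, 0, 0), cal),
               "at least 2")
})

test_that("tracked rotation displacement matches the chord formula", {
  m <- rotation_manifest(44, radius = 5, rotation_rate = 6,
                         frame_interval_min = 1,
                         noise = noise_model("none"))
  sim <- simulate_rotation_movie(m)
  start <- m$pole_track_um[1, c("x", "y")] / m$pixel_size
  tr <- track_pole(sim$image, "poles", start = start)
  v <- rotation_displacement(tr, sim$image$calibration)
  expect_equal(v, 2 * 5 * sin(3 * pi / 180), tolerance = 0.05)
  # stationary spindle tracks to zero displacement
  m0 <- rotation_manifest(44, rotation_rate = 0, noise = noise_model("none"))
  sim0 <- simulate_rotation_movie(m0)
  tr0 <- track_pole(sim0$image, "poles",
                    start = m0$pole_track_um[1, c("x", "y")] / m0$pixel_size)
  expect_equal(rotation_displacement(tr0, sim0$image$calibration), 0,
               tolerance = 1e-6)
})
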
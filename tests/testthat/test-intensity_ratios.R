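make_image <- function(mat, pixel_size = 0.25) {
  calibrated_image(mat, c("y", "x"), calibration(pixel_size))
}

disk_mask <- function(ny, nx, cy, cx, r) {
  d <- sqrt(outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`))
  d <= r
}

test_that("background subtraction is exact and offset-invariant", {
  mat <- matrix(20, 64, 64)
  mat[20:30, 20:30] <- 100
  img <- make_image(mat)
  roi <- matrix(FALSE, 64, 64); roi[20:30, 20:30] <- TRUE
  bg <- matrix(FALSE, 64, 64); bg[50:60, 50:60] <- TRUE
  expect_equal(background_subtracted_mean(img, 1, roi, bg), 80)
  # identical statistics on a uniform image give zero
  uni <- make_image(matrix(50, 64, 64))
  expect_equal(background_subtracted_mean(uni, 1, roi, bg), 0)
  # adding a constant to the whole image changes nothing
  img2 <- make_image(mat + 50)
  expect_equal(background_subtracted_mean(img2, 1, roi, bg), 80)
  expect_error(background_subtracted_mean(img, 1, roi, roi), "disjoint")
})

test_that("band ROI geometry matches its stated physical width", {
  inner <- disk_mask(96, 96, 48, 48, 12)
  band <- band_roi(inner, 2.5, pixel_size = 0.25)  # 10 px ring
  expect_false(any(band & inner))
  d <- sqrt(outer((seq_len(96) - 48)^2, (seq_len(96) - 48)^2, `+`))
  expect_true(all(d[band] <= 12 + 10 + 1e-9))
  expect_true(all(d[band] > 12 - 1))
  # every non-inner pixel comfortably within 10 px of the disk is in the band
  expect_true(all(band[d > 13 & d <= 21.5]))
})

test_that("band ratio is 1 on uniform images and follows the manifest", {
  uni <- make_image(matrix(42, 96, 96))
  inner <- disk_mask(96, 96, 48, 48, 12)
  expect_equal(band_ratio(uni, 1, inner, 2.5), 1)
  sim <- quiet_monopolar(55, peripheral_to_inner_intensity = 2)
  r <- band_ratio(sim$image, "EB1", manifest_dna_mask(sim$manifest), 2.5)
  expect_equal(r, 2, tolerance = 0.05)
  # zero puncta: degenerate input errors out
  empty <- quiet_monopolar(55, eb1_density_inner = 0)
  expect_error(band_ratio(empty$image, "EB1",
                          manifest_dna_mask(empty$manifest), 2.5),
               "zero")
})

test_that("tubulin density separates body and shell intensities", {
  sim <- quiet_bipolar(61, peripheral_to_inner_intensity = 1)
  mask <- manifest_spindle_mask(sim$manifest)
  plane <- max_project(sim$image, "tubulin")
  bg <- background_roi_auto(plane,
                            foreground = plane > sim$manifest$background_level)
  v <- tubulin_density(sim$image, "tubulin", mask, bg)
  expect_equal(unname(v["peripheral_intensity"] / v["spindle_intensity"]),
               1, tolerance = 0.05)

  sim2 <- quiet_bipolar(61, peripheral_to_inner_intensity = 0.5)
  mask2 <- manifest_spindle_mask(sim2$manifest)
  plane2 <- max_project(sim2$image, "tubulin")
  bg2 <- background_roi_auto(plane2,
                             foreground = plane2 > sim2$manifest$background_level)
  v2 <- tubulin_density(sim2$image, "tubulin", mask2, bg2)
  expect_equal(unname(v2["peripheral_intensity"] / v2["spindle_intensity"]),
               0.5, tolerance = 0.05)

  # background-only image: both measurements vanish
  flat <- make_image(matrix(10, 96, 96), pixel_size = 0.1083)
  roi <- disk_mask(96, 96, 48, 48, 10)
  bg3 <- matrix(FALSE, 96, 96); bg3[1:8, 1:8] <- TRUE
  v3 <- tubulin_density(flat, 1, roi, bg3, band_width_um = 1)
  expect_equal(unname(v3), c(0, 0))
})

test_that("expression level normalizes to the control mean", {
  mat <- matrix(20, 64, 64); mat[25:40, 25:40] <- 120
  img <- make_image(mat)
  roi <- matrix(FALSE, 64, 64); roi[25:40, 25:40] <- TRUE
  bg <- matrix(FALSE, 64, 64); bg[1:10, 1:10] <- TRUE
  expect_equal(expression_level(img, 1, roi, bg, control_mean = 100), 1)
  img2 <- make_image(mat + (mat > 20) * 100)  # signal doubled, same bg
  expect_equal(expression_level(img2, 1, roi, bg, control_mean = 100), 2)
  expect_error(expression_level(img, 1, roi, bg, control_mean = 0),
               "positive")
  # cohort of synthetic controls self-normalizes to 1 on average
  vals <- sapply(1:20, function(s) {
    sim <- quiet_monopolar(400 + s, eb1_density_inner = 0.8)
    mask <- manifest_dna_mask(sim$manifest)
    plane <- max_project(sim$image, "EB1")
    bgm <- background_roi_auto(plane, foreground = plane > 0)
    background_subtracted_mean(sim$image, "EB1", mask, bgm)
  })
  norm <- vals / mean(vals)
  expect_equal(mean(norm), 1, tolerance = 1e-10)
  expect_lt(sd(norm) / sqrt(20), 0.05)
})

test_that("quartile ratio follows the discrete averaging rule", {
  # uniform profile
  expect_equal(profile_quartile_ratio(seq(0, 1, 0.01), rep(5, 101)), 1)
  # zero outer quarters, bright middle half
  pos <- seq(0, 1, length.out = 101)
  intens <- ifelse(pos >= 0.25 & pos <= 0.75, 1, 0)
  expect_equal(profile_quartile_ratio(pos, intens), 0)
  # triangular peaks confined to the outer 10% each side over a 0.1 baseline:
  # oracle = direct averaging of the same samples
  tri <- 0.1 + pmax(0, 1 - pos / 0.1) + pmax(0, 1 - (1 - pos) / 0.1)
  peripheral <- pos < 0.25 | pos > 0.75
  oracle <- mean(tri[peripheral]) / mean(tri[!peripheral])
  expect_equal(profile_quartile_ratio(pos, tri), oracle)
  # boundary samples at exactly 0.25/0.75 belong to the middle half
  expect_equal(profile_quartile_ratio(c(0, 0.25, 0.5, 0.75, 1),
                                      c(9, 4, 4, 4, 9)), 9 / 4)
})

test_that("line-scan ratio recovers manifest peripheral enrichment", {
  for (r in c(0.5, 2)) {
    sim <- quiet_bipolar(71, peripheral_to_inner_intensity = r)
    m <- sim$manifest
    mid <- colMeans(m$pole_positions[, 1:2]) / m$pixel_size
    ln <- quartile_line(mid, c(1, 0),
                        length_px = 4 * m$kmass_half_extent / m$pixel_size)
    expect_equal(linescan_quartile_ratio(sim$image, "GFP", ln), r,
                 tolerance = 0.1)
  }
  uni <- make_image(matrix(3, 128, 128))
  ln <- quartile_line(c(64, 64), c(1, 0), length_px = 60)
  expect_equal(linescan_quartile_ratio(uni, 1, ln), 1)
})

test_that("ratios are invariant to global intensity scaling", {
  sim <- quiet_monopolar(81, peripheral_to_inner_intensity = 2)
  inner <- manifest_dna_mask(sim$manifest)
  r1 <- band_ratio(sim$image, "EB1", inner, 2.5)
  scaled <- calibrated_image(sim$image$data * 7.3, sim$image$axes,
                             sim$image$calibration,
                             sim$image$channel_names)
  expect_equal(band_ratio(scaled, "EB1", inner, 2.5), r1, tolerance = 1e-12)

  sim2 <- quiet_bipolar(82, peripheral_to_inner_intensity = 2)
  mid <- colMeans(sim2$manifest$pole_positions[, 1:2]) /
    sim2$manifest$pixel_size
  ln <- quartile_line(mid, c(1, 0),
                      length_px = 4 * sim2$manifest$kmass_half_extent /
                        sim2$manifest$pixel_size)
  q1 <- linescan_quartile_ratio(sim2$image, "GFP", ln)
  scaled2 <- calibrated_image(sim2$image$data * 0.37, sim2$image$axes,
                              sim2$image$calibration,
                              sim2$image$channel_names)
  expect_equal(linescan_quartile_ratio(scaled2, "GFP", ln), q1,
               tolerance = 1e-12)
})

test_that("Otsu segmentation recovers the DNA disk", {
  sim <- quiet_monopolar(91)
  mask <- segment_roi_otsu(sim$image, "DNA")
  truth <- manifest_dna_mask(sim$manifest)
  jaccard <- sum(mask & truth) / sum(mask | truth)
  expect_gt(jaccard, 0.9)
})
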
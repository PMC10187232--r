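#' ROI utilities and band construction
#'
#' ROIs are logical (y, x) masks congruent with one image plane. The band
#' ROI — the morphological ring of a stated physical width around an inner
#' ROI — is built from the Euclidean distance transform (isotropic in um),
#' not a square structuring element, because the assays specify the band
#' width in micrometers.
#'
#' @param inner Logical (y, x) mask.
#' @param band_width_um Band width, um.
#' @param pixel_size um/px.
#' @return Logical mask of the ring: pixels outside `inner` within
#'   `band_width_um` of it. Disjoint from `inner` by construction.
#' @export
band_roi <- function(inner, band_width_um, pixel_size) {
  check_mask(inner, "inner ROI")
  if (band_width_um <= 0) stop("band width must be positive", call. = FALSE)
  # distance from each outside pixel to the nearest inner pixel
  d <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(1 - inner)))))
  d > 0 & d * pixel_size <= band_width_um
}

check_mask <- function(mask, what = "ROI") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(what, " must be a logical matrix", call. = FALSE)
  if (!any(mask))
    stop(what, " is empty", call. = FALSE)
  invisible(mask)
}

#' Segment an inner ROI by Otsu thresholding
#'
#' Automatic stand-in for a hand-drawn ROI: Otsu threshold on the stated
#' channel plane, keep the largest connected component, optionally fill
#' holes.
#'
#' @param image A [calibrated_image()].
#' @param channel Channel to segment.
#' @param time,z Plane selectors; z-stacks are max-projected when `z` is
#'   `NULL`.
#' @return Logical (y, x) mask.
#' @export
segment_roi_otsu <- function(image, channel, time = 1L, z = NULL) {
  plane <- if (is.null(z)) max_project(image, channel, time) else
    image_plane(image, channel, time, z)
  rng <- range(plane)
  if (diff(rng) == 0) stop("cannot segment a constant image", call. = FALSE)
  sc <- (plane - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(t(sc)))
  bw <- sc > th
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bw * 1)))))
  if (max(lab) == 0) stop("no foreground found", call. = FALSE)
  big <- which.max(tabulate(lab[lab > 0]))
  mask <- lab == big
  t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(mask * 1))))) > 0
}

#' Automatic background ROI
#'
#' Picks the darkest `tile`-square tile of the plane that contains no
#' foreground pixel — emulating "an ROI in a region containing no cells".
#'
#' @param plane Numeric (y, x) matrix.
#' @param foreground Optional logical mask of pixels to avoid.
#' @param tile Tile side, px.
#' @return Logical mask of the chosen tile.
#' @export
background_roi_auto <- function(plane, foreground = NULL, tile = 32L) {
  ny <- nrow(plane); nx <- ncol(plane)
  if (ny < tile || nx < tile)
    stop("image smaller than background tile", call. = FALSE)
  best <- NULL; best_mean <- Inf
  for (y0 in seq(1, ny - tile + 1, by = tile))
    for (x0 in seq(1, nx - tile + 1, by = tile)) {
      ys <- y0:(y0 + tile - 1); xs <- x0:(x0 + tile - 1)
      if (!is.null(foreground) && any(foreground[ys, xs])) next
      m <- mean(plane[ys, xs])
      if (m < best_mean) { best_mean <- m; best <- c(y0, x0) }
    }
  if (is.null(best))
    stop("no background tile free of foreground found", call. = FALSE)
  mask <- matrix(FALSE, ny, nx)
  mask[best[1]:(best[1] + tile - 1), best[2]:(best[2] + tile - 1)] <- TRUE
  mask
}

plane_for_roi <- function(image, channel, time = 1L) {
  max_project(image, channel, time)
}

#' Background-subtracted mean ROI intensity
#'
#' Mean intensity of the channel over the ROI minus the mean over the
#' background ROI. A negative result (background brighter than signal) is
#' reported as-is with a warning, never clipped.
#'
#' @param image A [calibrated_image()].
#' @param channel Channel to measure.
#' @param roi,background_roi Logical (y, x) masks; nonempty, disjoint.
#' @param time Frame selector.
#' @return Background-subtracted mean intensity.
#' @export
background_subtracted_mean <- function(image, channel, roi, background_roi,
                                       time = 1L) {
  check_mask(roi, "measurement ROI")
  check_mask(background_roi, "background ROI")
  if (any(roi & background_roi))
    stop("measurement and background ROIs must be disjoint", call. = FALSE)
  plane <- plane_for_roi(image, channel, time)
  out <- mean(plane[roi]) - mean(plane[background_roi])
  if (out < 0)
    warning("background-subtracted mean is negative", call. = FALSE)
  out
}

#' Peripheral band to inner ROI intensity ratio
#'
#' The polymerization (EB1) assay geometry: mean intensity in a band of
#' stated width around the inner (DNA) ROI divided by the mean inside it.
#' No background subtraction by default (pure ratio form); enable it by
#' passing a `background_roi`.
#'
#' @param image A [calibrated_image()].
#' @param channel Channel to measure (e.g. `"EB1"` or `"GFP"`).
#' @param inner_roi Logical (y, x) mask of the inner region.
#' @param band_width_um Band width in um (2.5 for the EB1 assay).
#' @param background_roi Optional mask; when given, its mean is subtracted
#'   from both region means before the ratio.
#' @param time Frame selector.
#' @return `mean(band) / mean(inner)`.
#' @export
band_ratio <- function(image, channel, inner_roi, band_width_um = 2.5,
                       background_roi = NULL, time = 1L) {
  check_mask(inner_roi, "inner ROI")
  band <- band_roi(inner_roi, band_width_um,
                   image$calibration$pixel_size_xy)
  if (!any(band)) stop("band ROI is empty", call. = FALSE)
  plane <- plane_for_roi(image, channel, time)
  bg <- if (is.null(background_roi)) 0 else {
    check_mask(background_roi, "background ROI")
    mean(plane[background_roi])
  }
  inner_mean <- mean(plane[inner_roi]) - bg
  if (inner_mean == 0)
    stop("inner ROI mean is zero; ratio undefined", call. = FALSE)
  (mean(plane[band]) - bg) / inner_mean
}

#' Spindle and peripheral tubulin density
#'
#' Background-subtracted mean tubulin intensity inside the spindle ROI and
#' in a 4.5 um band around it, reported separately (each is compared across
#' conditions on its own).
#'
#' @param image A [calibrated_image()].
#' @param tubulin_channel Tubulin channel.
#' @param spindle_roi Logical mask of the spindle body.
#' @param background_roi Mask of a region containing no cells.
#' @param band_width_um Band width (default 4.5).
#' @param time Frame selector.
#' @return Named numeric vector `c(spindle_intensity, peripheral_intensity)`.
#' @export
tubulin_density <- function(image, tubulin_channel, spindle_roi,
                            background_roi, band_width_um = 4.5,
                            time = 1L) {
  check_mask(spindle_roi, "spindle ROI")
  check_mask(background_roi, "background ROI")
  band <- band_roi(spindle_roi, band_width_um,
                   image$calibration$pixel_size_xy)
  if (!any(band)) stop("peripheral band is empty", call. = FALSE)
  plane <- plane_for_roi(image, tubulin_channel, time)
  bg <- mean(plane[background_roi])
  c(spindle_intensity = mean(plane[spindle_roi]) - bg,
    peripheral_intensity = mean(plane[band]) - bg)
}

#' Control-normalized expression level
#'
#' Background-subtracted mean signal over the spindle ROI divided by the
#' mean background-subtracted intensity of the control condition.
#'
#' @param image A [calibrated_image()].
#' @param channel Channel carrying the expression signal.
#' @param spindle_roi ROI centered around (and larger than) the spindle.
#' @param background_roi ROI in a region with no cells.
#' @param control_mean Mean background-subtracted control intensity (> 0).
#' @param time Frame selector.
#' @return Normalized expression level (1 = control average).
#' @export
expression_level <- function(image, channel, spindle_roi, background_roi,
                             control_mean, time = 1L) {
  if (!is.numeric(control_mean) || control_mean <= 0)
    stop("control_mean must be positive", call. = FALSE)
  background_subtracted_mean(image, channel, spindle_roi, background_roi,
                             time) / control_mean
}

#' Quartile line for peripheral-vs-spindle localization
#'
#' The 20-px-wide line used by the localization assay: centered on the
#' kinetochore mass, oriented along the pole axis, with total length twice
#' the kinetochore-mass extent, so the middle half of the line covers the
#' mass and the outer quarters the periphery.
#'
#' @param center `c(x, y)` 0-based pixel center.
#' @param direction `c(dx, dy)` axis direction (normalized internally).
#' @param length_px Total line length in px (twice the kinetochore-mass
#'   extent).
#' @param width_px Averaging width (default 20).
#' @return An object of class `"QuartileLine"`.
#' @export
quartile_line <- function(center, direction, length_px, width_px = 20L) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero", call. = FALSE)
  if (length_px <= 0) stop("length_px must be positive", call. = FALSE)
  structure(list(center = as.numeric(center),
                 direction = as.numeric(direction) / nrm,
                 length_px = length_px, width_px = as.integer(width_px)),
            class = "QuartileLine")
}

#' Peripheral-to-spindle quartile line-scan ratio
#'
#' Measures the intensity profile along a [quartile_line()] (bilinear
#' sampling, averaged across the line width), rescales positions to
#' `[0, 1]`, and returns the mean over the outer quarters divided by the
#' mean over the middle half. Boundaries are exact quarters with the
#' half-open convention `[0, 0.25)` and `(0.75, 1]` peripheral,
#' `[0.25, 0.75]` spindle — samples landing exactly on a boundary count as
#' spindle.
#'
#' @param image A [calibrated_image()].
#' @param channel Channel to measure (e.g. `"GFP"`).
#' @param line A [quartile_line()].
#' @param time Frame selector.
#' @return Peripheral / spindle intensity ratio.
#' @export
linescan_quartile_ratio <- function(image, channel, line, time = 1L) {
  stopifnot(inherits(line, "QuartileLine"))
  half <- line$length_px / 2
  from <- line$center - half * line$direction
  to <- line$center + half * line$direction
  plane <- plane_for_roi(image, channel, time)
  sam <- segment_samples(from, to, line$width_px)
  ny <- nrow(plane); nx <- ncol(plane)
  if (any(sam$axis_x < 0 | sam$axis_x > nx - 1 |
          sam$axis_y < 0 | sam$axis_y > ny - 1))
    stop("quartile line exits image bounds", call. = FALSE)
  v <- interp_bilinear(plane, sam$x, sam$y)
  intens <- colMeans(matrix(v, nrow = sam$n_off), na.rm = TRUE)
  pos <- sam$t_axis / sam$length_px  # normalized [0, 1] along the line
  profile_quartile_ratio(pos, intens)
}

#' Quartile ratio of a sampled profile
#'
#' The discrete averaging rule behind [linescan_quartile_ratio()], exposed
#' for profiles obtained elsewhere.
#'
#' @param pos Positions normalized to `[0, 1]`.
#' @param intens Intensities, same length.
#' @return Mean over `[0, 0.25) + (0.75, 1]` divided by mean over
#'   `[0.25, 0.75]`.
#' @export
profile_quartile_ratio <- function(pos, intens) {
  stopifnot(length(pos) == length(intens))
  peripheral <- pos < 0.25 | pos > 0.75
  middle <- !peripheral
  if (!any(peripheral) || !any(middle))
    stop("profile does not cover both peripheral and middle regions",
         call. = FALSE)
  mid_mean <- mean(intens[middle])
  if (mid_mean == 0)
    stop("middle-half mean is zero; ratio undefined", call. = FALSE)
  mean(intens[peripheral]) / mid_mean
}
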
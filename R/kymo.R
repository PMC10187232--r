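#' Kymograph
#'
#' A position-versus-time intensity matrix read out along one microtubule:
#' rows are frames, columns are positions along the line. Sloped traces are
#' moving particles; slope is velocity.
#'
#' @param matrix Numeric matrix, time rows x position columns.
#' @param pixel_size um/px along the line.
#' @param frame_interval s/frame.
#' @return An object of class `"Kymograph"`.
#' @export
kymograph <- function(matrix, pixel_size, frame_interval) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!is.numeric(pixel_size) || pixel_size <= 0 ||
      !is.numeric(frame_interval) || frame_interval <= 0)
    stop("pixel_size and frame_interval must be positive", call. = FALSE)
  structure(list(matrix = matrix, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat("Kymograph: ", nrow(x$matrix), " frames x ", ncol(x$matrix),
      " px (", x$pixel_size, " um/px, ", x$frame_interval, " s/frame)\n",
      sep = "")
  invisible(x)
}

#' Build a kymograph from a time lapse along a line segment
#'
#' Row `t` of the kymograph is the intensity profile along the segment at
#' frame `t`, sampled at unit-pixel spacing by bilinear interpolation and
#' averaged over `width_px` parallel offsets. A segment of length `L` px
#' yields `ceiling(L) + 1` columns (samples at 0, 1, ..., up to and
#' including the far end).
#'
#' @param movie A [calibrated_image()] with a time axis and `frame_interval`
#'   calibration in seconds.
#' @param channel Channel to read.
#' @param from,to `c(x, y)` segment endpoints, 0-based pixels.
#' @param width_px Averaging width perpendicular to the segment, >= 1.
#' @return A [kymograph()].
#' @export
build_kymograph <- function(movie, channel, from, to, width_px = 3L) {
  stopifnot("time" %in% movie$axes)
  n_t <- axis_len(movie, "time")
  fi_s <- cal_frame_interval_s(movie$calibration, "build_kymograph")
  sam <- segment_samples(from, to, width_px)
  ny <- axis_len(movie, "y"); nx <- axis_len(movie, "x")
  if (any(sam$axis_x < 0 | sam$axis_x > nx - 1 |
          sam$axis_y < 0 | sam$axis_y > ny - 1))
    stop("segment exits image bounds", call. = FALSE)
  mat <- matrix(0, n_t, length(sam$axis_x))
  for (it in seq_len(n_t)) {
    plane <- image_plane(movie, channel, time = it)
    v <- interp_bilinear(plane, sam$x, sam$y)
    mat[it, ] <- colMeans(matrix(v, nrow = sam$n_off), na.rm = TRUE)
  }
  kymograph(mat, movie$calibration$pixel_size_xy, fi_s)
}

# sample positions along a segment with perpendicular averaging offsets;
# returns n_off x n_samples grids flattened column-wise
segment_samples <- function(from, to, width_px) {
  stopifnot(width_px >= 1)
  d <- c(to[1] - from[1], to[2] - from[2])
  len <- sqrt(sum(d^2))
  if (len == 0) stop("segment endpoints coincide", call. = FALSE)
  u <- d / len
  nvec <- c(-u[2], u[1])
  t_axis <- seq(0, ceiling(len), by = 1)
  t_axis[length(t_axis)] <- min(t_axis[length(t_axis)], len)
  offs <- seq_len(width_px) - (width_px + 1) / 2
  ax <- from[1] + outer(rep(1, length(offs)), t_axis) * u[1]
  ay <- from[2] + outer(rep(1, length(offs)), t_axis) * u[2]
  x <- ax + nvec[1] * offs
  y <- ay + nvec[2] * offs
  list(x = as.vector(x), y = as.vector(y), n_off = length(offs),
       axis_x = from[1] + t_axis * u[1], axis_y = from[2] + t_axis * u[2],
       t_axis = t_axis, length_px = len)
}

#' Bounding-rectangle velocity of a kymograph run
#'
#' The manual measurement rule for single-molecule velocity: a rectangle is
#' drawn around a sloped trace; velocity is the rectangle width in pixels
#' times the pixel size, divided by the run time (height in frames times the
#' frame interval in seconds).
#'
#' @param width_px Run length in pixels (rectangle width), >= 0.
#' @param height_frames Number of time frames (rectangle height), >= 1.
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @return Velocity in um/s.
#' @export
rectangle_velocity <- function(width_px, height_frames, pixel_size,
                               frame_interval) {
  if (height_frames < 1) stop("height_frames must be >= 1", call. = FALSE)
  if (width_px < 0) stop("width_px must be >= 0", call. = FALSE)
  (width_px * pixel_size) / (height_frames * frame_interval)
}

#' Detect constant-velocity runs in a kymograph
#'
#' Automated counterpart of manual rectangle drawing: the kymograph is
#' thresholded, connected traces are labelled, each trace's per-frame ridge
#' (intensity-weighted column) is extracted and split where the slope
#' changes sign, and each resulting segment is measured two ways — by its
#' bounding rectangle (`velocity_rect`, the manual rule with width =
#' max - min ridge column + 1 px and height = number of frames spanned) and
#' by the least-squares slope of its ridge points (`velocity_fit`).
#'
#' Runs shorter than `min_frames` frames or moving less than
#' `min_displacement_px` are discarded as stationary/noise.
#'
#' @param kymo A [kymograph()].
#' @param threshold Intensity threshold; default `mean + 2 * sd` of the
#'   matrix.
#' @param min_frames Minimum temporal extent of a run, frames.
#' @param min_displacement_px Minimum spatial extent, px.
#' @return A data frame with one row per run: `width_px`, `height_frames`,
#'   `velocity_rect`, `velocity_fit` (um/s, unsigned), `run_length_um`,
#'   `duration_s`. Zero rows when nothing is above threshold.
#' @export
detect_runs <- function(kymo, threshold = NULL, min_frames = 5L,
                        min_displacement_px = 2) {
  stopifnot(inherits(kymo, "Kymograph"))
  mat <- kymo$matrix
  if (nrow(mat) < 3L)
    stop("kymograph must have at least 3 frames", call. = FALSE)
  if (is.null(threshold)) threshold <- mean(mat) + 2 * stats::sd(mat)
  bw <- mat > threshold
  empty <- data.frame(width_px = integer(), height_frames = integer(),
                      velocity_rect = numeric(), velocity_fit = numeric(),
                      run_length_um = numeric(), duration_s = numeric())
  if (!any(bw)) return(empty)
  # label connected traces (8-connectivity tolerates steep slopes)
  lab <- EBImage::bwlabel(EBImage::Image(t(bw * 1)))  # EBImage is (x, y)
  lab <- t(EBImage::imageData(lab))
  out <- empty
  for (id in seq_len(max(lab))) {
    sel <- lab == id
    frames <- which(rowSums(sel) > 0)
    # per-frame ridge: intensity-weighted centroid column of this trace
    ridge <- vapply(frames, function(fr) {
      cols <- which(sel[fr, ])
      w <- mat[fr, cols] - threshold
      sum(cols * w) / sum(w)
    }, numeric(1))
    segs <- split_at_reversals(ridge)
    for (sg in segs) {
      fr <- frames[sg]; rc <- ridge[sg]
      hgt <- fr[length(fr)] - fr[1] + 1L
      wid <- max(rc) - min(rc)
      if (hgt < min_frames || wid < min_displacement_px) next
      # rectangle convention: (max - min ridge column index) + 1, on
      # integer pixel columns as a human would draw it
      wid_q <- max(round(rc)) - min(round(rc)) + 1L
      v_rect <- rectangle_velocity(wid_q, hgt, kymo$pixel_size,
                                   kymo$frame_interval)
      slope <- stats::coef(stats::lm(rc ~ fr))[2]
      v_fit <- abs(slope) * kymo$pixel_size / kymo$frame_interval
      out <- rbind(out, data.frame(
        width_px = wid_q, height_frames = hgt,
        velocity_rect = v_rect, velocity_fit = v_fit,
        run_length_um = wid_q * kymo$pixel_size,
        duration_s = hgt * kymo$frame_interval))
    }
  }
  out[order(out$duration_s, decreasing = TRUE), , drop = FALSE]
}

# split ridge points where the slope sign genuinely reverses: a new segment
# starts once the ridge has retreated >= thresh px from its running
# extremum, so sub-pixel jitter does not fragment slow runs
split_at_reversals <- function(ridge, thresh = 2) {
  n <- length(ridge)
  if (n < 3L) return(list(seq_len(n)))
  segs <- list()
  start <- 1L; dir <- 0; ext <- ridge[1]; ext_i <- 1L
  for (i in 2:n) {
    if (dir == 0) {
      if (abs(ridge[i] - ridge[start]) >= 0.5)
        dir <- sign(ridge[i] - ridge[start])
      ext <- ridge[i]; ext_i <- i
    } else if ((ridge[i] - ext) * dir >= 0) {
      ext <- ridge[i]; ext_i <- i
    } else if ((ext - ridge[i]) * dir >= thresh) {
      segs[[length(segs) + 1L]] <- start:ext_i
      start <- ext_i; dir <- -dir; ext <- ridge[i]; ext_i <- i
    }
  }
  segs[[length(segs) + 1L]] <- start:n
  segs
}
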
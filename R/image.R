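#' Calibrated multi-dimensional fluorescence image
#'
#' The package's canonical image container: an intensity array with named
#' axes drawn from `channel`, `time`, `z`, `y`, `x`, normalized internally to
#' that order (absent axes dropped; `y` and `x` always present, last), plus a
#' [calibration()] and optional channel labels.
#'
#' Coordinate convention: pixel indices are 0-based and refer to pixel
#' centers; the physical position of pixel index `i` along x or y is
#' `i * pixel_size_xy` um (and `k * z_step` um along z). Intensities are
#' unitless non-negative reals — camera bit depth is deliberately not modeled.
#'
#' @param data Numeric array. Its dimensions must match `axes`; a plain
#'   matrix is taken as a single (y, x) plane.
#' @param axes Character vector naming each dimension of `data`, a permutation
#'   subset of `c("channel","time","z","y","x")` containing `y` and `x`.
#' @param calibration A [calibration()] object.
#' @param channel_names Optional character labels, one per channel (e.g.
#'   `"poles"`, `"kinetochores"`, `"tubulin"`, `"GFP"`, `"DNA"`, `"EB1"`).
#'
#' @return An object of class `"CalibratedImage"`: a list with elements
#'   `data` (array in canonical axis order), `axes`, `calibration`,
#'   `channel_names`.
#' @export
calibrated_image <- function(data, axes, calibration,
                             channel_names = NULL) {
  stopifnot(inherits(calibration, "Calibration"))
  if (is.matrix(data) && missing(axes)) axes <- c("y", "x")
  data <- as.array(data)
  if (length(axes) != length(dim(data)))
    stop("length(axes) must equal the number of array dimensions",
         call. = FALSE)
  canonical <- c("channel", "time", "z", "y", "x")
  if (anyDuplicated(axes) || !all(axes %in% canonical))
    stop("axes must be unique names from {channel, time, z, y, x}",
         call. = FALSE)
  if (!all(c("y", "x") %in% axes))
    stop("axes must include both 'y' and 'x'", call. = FALSE)
  if (!all(is.finite(data)) || any(data < 0))
    stop("image intensities must be finite and non-negative", call. = FALSE)
  ord <- order(match(axes, canonical))
  if (!identical(ord, seq_along(axes))) {
    data <- aperm(data, ord)
    axes <- axes[ord]
  }
  n_ch <- if ("channel" %in% axes) dim(data)[match("channel", axes)] else 1L
  if (!is.null(channel_names)) {
    if (length(channel_names) != n_ch)
      stop("channel_names must have one label per channel", call. = FALSE)
    channel_names <- as.character(channel_names)
  }
  structure(
    list(data = data, axes = axes, calibration = calibration,
         channel_names = channel_names),
    class = "CalibratedImage"
  )
}

#' @export
print.CalibratedImage <- function(x, ...) {
  cat("CalibratedImage [", paste(x$axes, dim(x$data), sep = "=",
                                 collapse = ", "), "]\n", sep = "")
  if (!is.null(x$channel_names))
    cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  print(x$calibration)
  invisible(x)
}

#' @export
dim.CalibratedImage <- function(x) dim(x$data)

axis_len <- function(img, axis) {
  i <- match(axis, img$axes)
  if (is.na(i)) 1L else dim(img$data)[i]
}

channel_index <- function(img, channel) {
  if (is.character(channel)) {
    if (is.null(img$channel_names))
      stop("image has no channel_names; select the channel by index",
           call. = FALSE)
    i <- match(channel, img$channel_names)
    if (is.na(i))
      stop("channel '", channel, "' not found; available: ",
           paste(img$channel_names, collapse = ", "), call. = FALSE)
    i
  } else {
    i <- as.integer(channel)
    if (i < 1L || i > axis_len(img, "channel"))
      stop("channel index out of range", call. = FALSE)
    i
  }
}

#' Extract one (y, x) plane or sub-stack of a CalibratedImage
#'
#' Indexes the canonical (channel, time, z, y, x) array by channel, frame and
#' slice, dropping the indexed axes. With `z = NULL` on a z-stack the z axis
#' is kept, giving a (z, y, x) array.
#'
#' @param img A [calibrated_image()].
#' @param channel Channel label or index (ignored if the image has no channel
#'   axis).
#' @param time Frame index (1-based) if the image has a time axis.
#' @param z Slice index (1-based), or `NULL` to keep the whole stack.
#' @return A numeric matrix (y, x) or array (z, y, x).
#' @export
image_plane <- function(img, channel = 1L, time = 1L, z = 1L) {
  stopifnot(inherits(img, "CalibratedImage"))
  idx <- rep(list(quote(expr = )), length(img$axes))
  names(idx) <- img$axes
  if ("channel" %in% img$axes) idx[["channel"]] <- channel_index(img, channel)
  if ("time" %in% img$axes) idx[["time"]] <- as.integer(time)
  keep_z <- "z" %in% img$axes && is.null(z)
  if ("z" %in% img$axes && !is.null(z)) idx[["z"]] <- as.integer(z)
  out <- do.call(`[`, c(list(img$data), unname(idx), list(drop = FALSE)))
  keep <- img$axes %in% c("y", "x") | (img$axes == "z" & keep_z)
  array(out, dim = dim(out)[keep])
}

#' Maximum-intensity projection of one channel over z
#'
#' @param img A [calibrated_image()] with (or without) a z axis.
#' @param channel Channel label or index.
#' @param time Frame index if the image is a time lapse.
#' @return A (y, x) matrix; for single-plane images, the plane itself.
#' @export
max_project <- function(img, channel = 1L, time = 1L) {
  if (!("z" %in% img$axes)) return(image_plane(img, channel, time))
  stack <- image_plane(img, channel, time, z = NULL)
  apply(stack, c(2, 3), max)
}

#' Bilinear interpolation of a (y, x) intensity matrix
#'
#' Samples `mat` at fractional 0-based pixel coordinates. Points outside the
#' image return `NA`.
#'
#' @param mat Numeric matrix indexed `[y + 1, x + 1]`.
#' @param x,y Numeric vectors of 0-based pixel coordinates.
#' @return Numeric vector of interpolated intensities.
#' @keywords internal
interp_bilinear <- function(mat, x, y) {
  ny <- nrow(mat); nx <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp the upper neighbor so points exactly on the last row/col still work
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  i00 <- cbind(y0[ok] + 1, x0[ok] + 1)
  i01 <- cbind(y0[ok] + 1, x1[ok] + 1)
  i10 <- cbind(y1[ok] + 1, x0[ok] + 1)
  i11 <- cbind(y1[ok] + 1, x1[ok] + 1)
  out[ok] <- (1 - fy[ok]) * ((1 - fx[ok]) * mat[i00] + fx[ok] * mat[i01]) +
    fy[ok] * ((1 - fx[ok]) * mat[i10] + fx[ok] * mat[i11])
  out
}
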
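#' Physical calibration of a microscopy acquisition
#'
#' Bundles the pixel size in the focal plane, the optional z-step of a
#' z-stack, and the optional frame interval of a time lapse. Every physical
#' quantity reported by this package (lengths in micrometers, velocities in
#' um/s or um/min, angles that mix xy and z displacements) is derived from
#' pixel/slice/frame indices through one of these fields; an operation that
#' needs a field that was not provided fails with an error naming the field
#' rather than assuming a default.
#'
#' @param pixel_size_xy Pixel size in the focal plane, um/pixel. Must be a
#'   single strictly positive number.
#' @param z_step Axial step between consecutive z slices, um/slice, or `NULL`
#'   for single-plane data.
#' @param frame_interval Time between consecutive frames, or `NULL` for fixed
#'   images. Interpreted in the unit given by `time_unit`.
#' @param time_unit Unit of `frame_interval`: `"s"` or `"min"`.
#'
#' @return An object of class `"Calibration"`.
#' @examples
#' calibration(pixel_size_xy = 0.1083, z_step = 0.25)
#' calibration(0.16, frame_interval = 3, time_unit = "min")
#' @export
calibration <- function(pixel_size_xy, z_step = NULL, frame_interval = NULL,
                        time_unit = c("s", "min")) {
  time_unit <- match.arg(time_unit)
  check_pos <- function(x, name, optional = FALSE) {
    if (is.null(x)) {
      if (optional) return(invisible(NULL))
      stop("calibration field '", name, "' is required", call. = FALSE)
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("calibration field '", name,
           "' must be a single strictly positive number", call. = FALSE)
    invisible(NULL)
  }
  check_pos(pixel_size_xy, "pixel_size_xy")
  check_pos(z_step, "z_step", optional = TRUE)
  check_pos(frame_interval, "frame_interval", optional = TRUE)
  structure(
    list(pixel_size_xy = pixel_size_xy, z_step = z_step,
         frame_interval = frame_interval, time_unit = time_unit),
    class = "Calibration"
  )
}

#' @export
print.Calibration <- function(x, ...) {
  cat("Calibration:\n")
  cat("  pixel_size_xy:", x$pixel_size_xy, "um/px\n")
  if (!is.null(x$z_step)) cat("  z_step:       ", x$z_step, "um/slice\n")
  if (!is.null(x$frame_interval))
    cat("  frame_interval:", x$frame_interval, x$time_unit, "/frame\n")
  invisible(x)
}

#' Fetch a calibration field, failing loudly when absent
#'
#' @param cal A [calibration()] object.
#' @param field One of `"pixel_size_xy"`, `"z_step"`, `"frame_interval"`.
#' @param context Short string naming the operation, used in the error.
#' @return The numeric field value.
#' @keywords internal
cal_require <- function(cal, field, context = "this operation") {
  stopifnot(inherits(cal, "Calibration"))
  v <- cal[[field]]
  if (is.null(v))
    stop(context, " requires calibration field '", field,
         "', which was not provided", call. = FALSE)
  v
}

#' Frame interval in minutes
#'
#' @param cal A [calibration()] object with a `frame_interval`.
#' @param context Error context string.
#' @return Frame interval converted to minutes.
#' @keywords internal
cal_frame_interval_min <- function(cal, context = "this operation") {
  fi <- cal_require(cal, "frame_interval", context)
  if (cal$time_unit == "s") fi / 60 else fi
}

#' Frame interval in seconds
#' @inheritParams cal_frame_interval_min
#' @return Frame interval converted to seconds.
#' @keywords internal
cal_frame_interval_s <- function(cal, context = "this operation") {
  fi <- cal_require(cal, "frame_interval", context)
  if (cal$time_unit == "min") fi * 60 else fi
}

#' Read a calibration configuration file
#'
#' Reads a YAML or JSON file with keys `pixel_size_xy` and optionally
#' `z_step`, `frame_interval`, `time_unit`, plus optional image-layout keys
#' (`axes`, `channel_names`) used by [read_calibrated_tiff()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file.
#' @return A list with element `calibration` (a [calibration()] object) and
#'   any remaining keys passed through.
#' @export
read_calibration_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$pixel_size_xy))
    stop("config is missing calibration field 'pixel_size_xy'", call. = FALSE)
  cal <- calibration(
    pixel_size_xy = cfg$pixel_size_xy,
    z_step = cfg$z_step,
    frame_interval = cfg$frame_interval,
    time_unit = if (is.null(cfg$time_unit)) "s" else cfg$time_unit
  )
  extra <- cfg[setdiff(names(cfg),
                       c("pixel_size_xy", "z_step", "frame_interval",
                         "time_unit"))]
  c(list(calibration = cal), extra)
}
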
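#' Kinetochore intensity profile along the pole-to-pole axis
#'
#' Samples the kinetochore channel along the segment joining the two poles —
#' the length of the line is defined by the pole-to-pole distance — by
#' bilinear interpolation at unit-pixel spacing, averaging over `width_px`
#' parallel lines perpendicular to the axis. Positions are in um from
#' pole 1.
#'
#' For z-stacks the channel is maximum-projected first. Perpendicular
#' averaging samples that fall outside the image are dropped from the mean;
#' the axis itself must stay inside the image.
#'
#' @param image A [calibrated_image()].
#' @param channel Kinetochore channel label or index.
#' @param poles A [pole_pair()] (xy components are used).
#' @param width_px Averaging width in pixels, >= 1 (default 20, matching the
#'   package-wide line-scan width).
#' @param time Frame index for time lapses.
#' @return A `"LineProfile"`: list with `positions_um` (monotone
#'   increasing), `intensities`, `normalized = FALSE`.
#' @export
extract_axis_profile <- function(image, channel, poles, width_px = 20L,
                                 time = 1L) {
  stopifnot(inherits(poles, "PolePair"), width_px >= 1)
  plane <- max_project(image, channel, time)
  from <- poles$p1[1:2]; to <- poles$p2[1:2]
  sam <- segment_samples(from, to, width_px)
  ny <- nrow(plane); nx <- ncol(plane)
  if (any(sam$axis_x < 0 | sam$axis_x > nx - 1 |
          sam$axis_y < 0 | sam$axis_y > ny - 1))
    stop("pole-to-pole segment exits image bounds", call. = FALSE)
  v <- interp_bilinear(plane, sam$x, sam$y)
  intens <- colMeans(matrix(v, nrow = sam$n_off), na.rm = TRUE)
  px <- image$calibration$pixel_size_xy
  line_profile(sam$t_axis * px, intens)
}

#' Construct a line profile
#'
#' @param positions_um Monotone increasing positions in um.
#' @param intensities Intensities, same length.
#' @param normalized Whether the profile has been normalized to max 1.
#' @return A `"LineProfile"`.
#' @export
line_profile <- function(positions_um, intensities, normalized = FALSE) {
  stopifnot(length(positions_um) == length(intensities))
  if (any(diff(positions_um) <= 0))
    stop("profile positions must be strictly increasing", call. = FALSE)
  if (normalized && max(intensities) != 1)
    stop("a normalized profile must have maximum exactly 1", call. = FALSE)
  structure(list(positions_um = as.numeric(positions_um),
                 intensities = as.numeric(intensities),
                 normalized = isTRUE(normalized)),
            class = "LineProfile")
}

#' Normalize a profile internally to its highest value
#'
#' Divides the intensities by their maximum so the profile peaks at exactly
#' 1. Idempotent; an all-zero (or non-positive-maximum) profile is an error.
#'
#' @param profile A [line_profile()].
#' @return The normalized `"LineProfile"`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "LineProfile"))
  m <- max(profile$intensities)
  if (m <= 0)
    stop("cannot normalize a profile with non-positive maximum",
         call. = FALSE)
  line_profile(profile$positions_um, profile$intensities / m,
               normalized = TRUE)
}

#' Fit a Gaussian to a line profile and report the FWHM
#'
#' Nonlinear least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2)) + c`
#' to the profile (Levenberg-Marquardt). The full width at half maximum is
#' `2 * sqrt(2 * log(2)) * sigma`. The constant offset `c` absorbs nonzero
#' backgrounds; set `offset = FALSE` to fit the pure Gaussian.
#'
#' Initialization: `A = max - min`, `mu` = intensity-weighted centroid,
#' `sigma` = profile span / 6, `c = min`; `sigma` is bounded to
#' (0, profile span]. Non-convergence (including unidentifiable fits such as
#' a constant profile) returns `converged = FALSE` with the failure message
#' in `diagnostics` — never a silent `NaN`.
#'
#' @param profile A [line_profile()] with at least 5 samples.
#' @param offset Include the constant offset term (default `TRUE`).
#' @return A `"GaussianFitResult"`: list with `amplitude`, `center_um`,
#'   `sigma_um`, `offset`, `fwhm_um`, `r_squared`, `converged`,
#'   `diagnostics`.
#' @export
fit_gaussian_fwhm <- function(profile, offset = TRUE) {
  stopifnot(inherits(profile, "LineProfile"))
  x <- profile$positions_um
  yv <- profile$intensities
  if (length(x) < 5L)
    stop("Gaussian fit requires at least 5 samples", call. = FALSE)
  span <- diff(range(x))
  failure <- function(msg) structure(
    list(amplitude = NA_real_, center_um = NA_real_, sigma_um = NA_real_,
         offset = NA_real_, fwhm_um = NA_real_, r_squared = NA_real_,
         converged = FALSE, diagnostics = msg),
    class = "GaussianFitResult")
  if (diff(range(yv)) == 0) return(failure("constant profile: fit is unidentifiable"))
  w <- yv - min(yv)
  mu0 <- sum(x * w) / sum(w)
  lower <- c(A = 0, mu = min(x), sigma = 1e-6, c = -Inf)
  upper <- c(A = Inf, mu = max(x), sigma = span, c = Inf)
  if (!offset) {
    lower <- lower[names(lower) != "c"]; upper <- upper[names(upper) != "c"]
  }
  form <- if (offset) yv ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + c
          else yv ~ A * exp(-(x - mu)^2 / (2 * sigma^2))
  # multi-start over sigma: jagged profiles (discrete puncta) have local
  # minima where a single spike is fit; keep the start with lowest SSE
  fit <- NULL; best_sse <- Inf; last_err <- "fit failed"
  for (s0 in span * c(1 / 12, 1 / 6, 1 / 3)) {
    start <- list(A = max(yv) - min(yv), mu = mu0, sigma = s0, c = min(yv))
    if (!offset) start$c <- NULL
    f <- tryCatch(
      minpack.lm::nlsLM(form, start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(f, "error")) { last_err <- conditionMessage(f); next }
    sse <- sum(stats::resid(f)^2)
    if (sse < best_sse) { best_sse <- sse; fit <- f }
  }
  if (is.null(fit)) return(failure(last_err))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  sst <- sum((yv - mean(yv))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum(res^2) / sst)) else NA_real_
  sigma <- unname(cf["sigma"])
  structure(
    list(amplitude = unname(cf["A"]), center_um = unname(cf["mu"]),
         sigma_um = sigma,
         offset = if (offset) unname(cf["c"]) else 0,
         fwhm_um = 2 * sqrt(2 * log(2)) * sigma,
         r_squared = r2, converged = TRUE, diagnostics = ""),
    class = "GaussianFitResult")
}

#' @export
print.GaussianFitResult <- function(x, ...) {
  if (!x$converged) {
    cat("GaussianFitResult: NOT converged (", x$diagnostics, ")\n",
        sep = "")
  } else {
    cat(sprintf(
      "GaussianFitResult: FWHM %.3f um (sigma %.3f, center %.3f, A %.2f, c %.2f), R^2 %.3f\n",
      x$fwhm_um, x$sigma_um, x$center_um, x$amplitude, x$offset,
      x$r_squared))
  }
  invisible(x)
}

#' Chromosome-alignment metric for one cell
#'
#' The full alignment pipeline: extract the kinetochore profile along the
#' pole-to-pole axis, normalize it internally to its highest value, fit a
#' Gaussian, and report the FWHM together with the spindle length. Smaller
#' FWHM means kinetochores are more tightly clustered at the metaphase
#' plate, i.e. better chromosome alignment.
#'
#' Fits that do not converge or fall below `r_squared_min` are flagged via
#' the `qc_pass` field, not dropped.
#'
#' @param image A [calibrated_image()] containing a kinetochore channel.
#' @param poles A [pole_pair()]; pass the output of [detect_poles()] or
#'   manually clicked coordinates.
#' @param channel Kinetochore channel (default `"kinetochores"`).
#' @param width_px Profile averaging width.
#' @param offset Include the offset term in the fit.
#' @param r_squared_min QC threshold on goodness of fit.
#' @return A one-row data frame: `fwhm_um`, `spindle_length_um`,
#'   `r_squared`, `converged`, `qc_pass`.
#' @export
alignment_metric <- function(image, poles, channel = "kinetochores",
                             width_px = 20L, offset = TRUE,
                             r_squared_min = 0.5) {
  prof <- extract_axis_profile(image, channel, poles, width_px)
  fit <- fit_gaussian_fwhm(normalize_profile(prof), offset = offset)
  data.frame(
    fwhm_um = fit$fwhm_um,
    spindle_length_um = spindle_length(poles, image$calibration),
    r_squared = fit$r_squared,
    converged = fit$converged,
    qc_pass = fit$converged && !is.na(fit$r_squared) &&
      fit$r_squared >= r_squared_min)
}
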
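#' Synthetic fluorescence-microscopy generator
#'
#' The generators in this file render idealized mitotic cells — bipolar and
#' monopolar spindles, rotating-spindle time lapses and single-molecule
#' kymographs — together with a ground-truth manifest recording every
#' parameter used, so that each measurement module can be tested by recovery
#' against known truth.
#'
#' Shared modelling choices:
#' * the point-spread function is an isotropic 2D Gaussian (default sigma
#'   1.3 px, a diffraction-limited spot at 60x-like sampling);
#' * the default field is 256 x 256 px at 0.1083 um/px;
#' * noise is Poisson shot noise on (signal + background) followed by
#'   Gaussian read noise, both switchable off for exact tests;
#' * random streams are drawn per channel from seeds derived from the
#'   manifest seed by a fixed splitting rule, so adding a channel does not
#'   perturb the others.
#'
#' @name synthgen
NULL

# fixed per-channel offsets for the seed-splitting rule
.channel_seed_offsets <- c(
  poles = 1L, kinetochores = 2L, tubulin = 3L, GFP = 4L, DNA = 5L,
  EB1 = 6L, noise = 7L, track = 8L, kymo = 9L
)

channel_seed <- function(seed, channel) {
  off <- .channel_seed_offsets[[channel]]
  if (is.null(off)) stop("no seed offset for channel '", channel, "'")
  (as.integer(seed) %% 2097152L) * 64L + off  # < 2^27, well under 2^31
}

#' Default noise model
#'
#' @param type `"poisson_gaussian"` (Poisson shot noise then additive
#'   Gaussian read noise), `"gaussian"` (additive only) or `"none"`.
#' @param read_sigma Read-noise standard deviation (intensity units).
#' @return A list describing the noise model.
#' @export
noise_model <- function(type = c("poisson_gaussian", "gaussian", "none"),
                        read_sigma = 2) {
  type <- match.arg(type)
  list(type = type, read_sigma = read_sigma)
}

apply_noise <- function(img, model, seed) {
  if (model$type == "none") return(img)
  set.seed(channel_seed(seed, "noise"))
  if (model$type == "poisson_gaussian")
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img))
  img <- img + stats::rnorm(length(img), 0, model$read_sigma)
  pmax(img, 0)
}

# add isotropic Gaussian spots to a (y, x) matrix; x/y in 0-based px
render_spots <- function(mat, x_px, y_px, amplitude, sigma_px) {
  ny <- nrow(mat); nx <- ncol(mat)
  amplitude <- rep_len(amplitude, length(x_px))
  w <- ceiling(4 * sigma_px)
  for (i in seq_along(x_px)) {
    xi <- x_px[i]; yi <- y_px[i]
    xs <- max(0, floor(xi) - w):min(nx - 1, ceiling(xi) + w)
    ys <- max(0, floor(yi) - w):min(ny - 1, ceiling(yi) + w)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - xi)^2 / (2 * sigma_px^2))
    gy <- exp(-(ys - yi)^2 / (2 * sigma_px^2))
    mat[ys + 1, xs + 1] <- mat[ys + 1, xs + 1] + amplitude[i] * outer(gy, gx)
  }
  mat
}

# 0-based pixel-center coordinate grids in um
field_grids <- function(ny, nx, pixel_size) {
  list(x = (seq_len(nx) - 1) * pixel_size,
       y = (seq_len(ny) - 1) * pixel_size)
}

new_manifest <- function(kind, fields) {
  structure(c(list(kind = kind, generator_version = 1L), fields),
            class = "GroundTruthManifest")
}

#' @export
print.GroundTruthManifest <- function(x, ...) {
  cat("GroundTruthManifest <", x$kind, ">, seed ", x$seed, "\n", sep = "")
  utils::str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Write / read a ground-truth manifest as JSON
#' @param manifest A manifest from one of the `*_manifest()` constructors.
#' @param path JSON path.
#' @return `path` invisibly, or the manifest.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(m$pole_positions)) m$pole_positions <-
      matrix(unlist(m$pole_positions), ncol = 3, byrow = FALSE,
             dimnames = list(NULL, c("x", "y", "z")))
  structure(m, class = "GroundTruthManifest")
}

common_field_defaults <- function(field_ny = 256L, field_nx = 256L,
                                  pixel_size = 0.1083, psf_sigma_px = 1.3,
                                  background_level = 10,
                                  noise = noise_model()) {
  list(field_ny = as.integer(field_ny), field_nx = as.integer(field_nx),
       pixel_size = pixel_size, psf_sigma_px = psf_sigma_px,
       background_level = background_level, noise = noise)
}

#' Ground-truth manifest for a bipolar metaphase cell
#'
#' Describes a bipolar spindle: two pole spots separated by
#' `spindle_length` along `axis_angle_deg` in the xy plane and centered in
#' the field, a kinetochore mass whose axial positions are drawn
#' `Normal(midpoint, kinetochore_spread_sigma)`, an elliptical tubulin
#' spindle body with an optional peripheral shell, and a GFP (motor) channel
#' with inner/peripheral zones along the pole axis used by the line-scan
#' localization assay.
#'
#' @param seed Integer RNG seed; everything rendered is reproducible from
#'   (manifest, generator version).
#' @param spindle_length Pole-to-pole distance, um.
#' @param kinetochore_spread_sigma SD of kinetochore axial positions about
#'   the spindle midpoint, um; the chromosome-alignment ground truth
#'   (true FWHM = `2*sqrt(2*log(2))` times this).
#' @param n_kinetochores Number of kinetochore puncta (92 = both sister
#'   kinetochores of 46 chromosomes).
#' @param kinetochore_lateral_sigma SD of lateral (off-axis) kinetochore
#'   offsets, um.
#' @param kinetochore_spot_sigma_px Rendered size of one kinetochore spot,
#'   px; wider than the bare PSF because a kinetochore is an extended
#'   object, not a point emitter.
#' @param axis_angle_deg Orientation of the pole axis in the xy plane.
#' @param pole_z Optional length-2 z positions of the poles, um measured
#'   from the first slice (slice `k`, 0-based, sits at `k * z_step` um);
#'   when given (or `n_z > 1`) a z-stack is rendered.
#' @param n_z,z_step Number of z slices and step (um) for z-stacks.
#' @param peripheral_to_inner_intensity Shell-to-body intensity ratio for
#'   the tubulin channel and outer-to-inner zone ratio for the GFP channel.
#' @param body_half_width Lateral semi-axis of the spindle body, um.
#' @param shell_width Width of the tubulin peripheral shell, um.
#' @param kmass_half_extent Half-extent of the GFP inner zone along the pole
#'   axis (the "kinetochore mass" half-length), um.
#' @param pole_amplitude,kinetochore_amplitude,tubulin_body_intensity,gfp_inner_intensity
#'   Peak intensities (unitless counts).
#' @param field_ny,field_nx,pixel_size,psf_sigma_px,background_level,noise
#'   Field geometry, optics and noise shared by all generators (see
#'   [noise_model()]).
#' @return A `"GroundTruthManifest"` list. `pole_positions` is a 2 x 3
#'   matrix of (x, y, z) in um; `spindle_length` always equals the Euclidean
#'   distance between the two pole positions.
#' @export
bipolar_manifest <- function(seed, spindle_length = 10,
                             kinetochore_spread_sigma = 1.5,
                             n_kinetochores = 92L,
                             kinetochore_lateral_sigma = 0.8,
                             kinetochore_spot_sigma_px = 3,
                             axis_angle_deg = 0,
                             pole_z = NULL, n_z = 1L, z_step = 0.25,
                             peripheral_to_inner_intensity = 0,
                             body_half_width = 2.5,
                             shell_width = 4.5,
                             kmass_half_extent = 3,
                             pole_amplitude = 400,
                             kinetochore_amplitude = 200,
                             tubulin_body_intensity = 150,
                             gfp_inner_intensity = 120,
                             field_ny = 256L, field_nx = 256L,
                             pixel_size = 0.1083, psf_sigma_px = 1.3,
                             background_level = 10,
                             noise = noise_model()) {
  if (kinetochore_spread_sigma <= 0)
    stop("kinetochore_spread_sigma must be positive", call. = FALSE)
  fov_x <- (field_nx - 1) * pixel_size
  fov_y <- (field_ny - 1) * pixel_size
  if (spindle_length >= min(fov_x, fov_y))
    stop("spindle_length (", spindle_length,
         " um) exceeds the field of view", call. = FALSE)
  th <- axis_angle_deg * pi / 180
  cx <- fov_x / 2; cy <- fov_y / 2
  u <- c(cos(th), sin(th))
  if (is.null(pole_z)) {
    pole_z <- if (n_z > 1L) rep((n_z - 1L) * z_step / 2, 2) else c(0, 0)
  } else {
    stopifnot(length(pole_z) == 2)
    n_z <- max(n_z, 2L)
    if (any(pole_z < 0) || any(pole_z > (n_z - 1L) * z_step))
      stop("pole_z must lie within the z-stack", call. = FALSE)
  }
  half_xy <- sqrt(max(spindle_length^2 - diff(pole_z)^2, 0)) / 2
  poles <- rbind(
    c(cx - half_xy * u[1], cy - half_xy * u[2], pole_z[1]),
    c(cx + half_xy * u[1], cy + half_xy * u[2], pole_z[2]))
  colnames(poles) <- c("x", "y", "z")
  new_manifest("bipolar", c(
    list(seed = as.integer(seed), pole_positions = poles,
         spindle_length = spindle_length,
         kinetochore_spread_sigma = kinetochore_spread_sigma,
         n_kinetochores = as.integer(n_kinetochores),
         kinetochore_lateral_sigma = kinetochore_lateral_sigma,
         kinetochore_spot_sigma_px = kinetochore_spot_sigma_px,
         axis_angle_deg = axis_angle_deg,
         n_z = as.integer(n_z), z_step = z_step,
         peripheral_to_inner_intensity = peripheral_to_inner_intensity,
         body_half_width = body_half_width, shell_width = shell_width,
         kmass_half_extent = kmass_half_extent,
         pole_amplitude = pole_amplitude,
         kinetochore_amplitude = kinetochore_amplitude,
         tubulin_body_intensity = tubulin_body_intensity,
         gfp_inner_intensity = gfp_inner_intensity),
    common_field_defaults(field_ny, field_nx, pixel_size, psf_sigma_px,
                          background_level, noise)))
}

# signed axial (u) and lateral (v) um coordinates of the field grid
# relative to the spindle midpoint and axis
axis_coords <- function(manifest, g) {
  p <- manifest$pole_positions
  mid <- (p[1, 1:2] + p[2, 1:2]) / 2
  th <- manifest$axis_angle_deg * pi / 180
  X <- matrix(g$x, length(g$y), length(g$x), byrow = TRUE) - mid[1]
  Y <- matrix(g$y, length(g$y), length(g$x)) - mid[2]
  list(u = X * cos(th) + Y * sin(th), v = -X * sin(th) + Y * cos(th))
}

#' Render a bipolar metaphase cell
#'
#' @param manifest A [bipolar_manifest()].
#' @param channels Channels to render, a subset of
#'   `c("poles", "kinetochores", "tubulin", "GFP", "DNA")`.
#' @return A list with elements `image` (a [calibrated_image()]) and
#'   `manifest` — the input manifest augmented with the realized kinetochore
#'   positions (`kinetochore_axial_um`, absolute um along the pole axis from
#'   pole 1, and `kinetochore_xy_um`).
#' @export
simulate_bipolar_cell <- function(manifest,
                                  channels = c("poles", "kinetochores",
                                               "tubulin", "GFP")) {
  stopifnot(inherits(manifest, "GroundTruthManifest"),
            manifest$kind == "bipolar")
  allowed <- c("poles", "kinetochores", "tubulin", "GFP", "DNA")
  if (!all(channels %in% allowed))
    stop("channels must be a subset of {", paste(allowed, collapse = ", "),
         "}", call. = FALSE)
  m <- manifest
  ny <- m$field_ny; nx <- m$field_nx; px <- m$pixel_size
  g <- field_grids(ny, nx, px)
  p <- m$pole_positions
  th <- m$axis_angle_deg * pi / 180
  uhat <- c(cos(th), sin(th)); vhat <- c(-sin(th), cos(th))
  mid <- (p[1, 1:2] + p[2, 1:2]) / 2
  half_xy <- sqrt(sum((p[2, 1:2] - p[1, 1:2])^2)) / 2

  # kinetochore ground truth (drawn once, recorded in the manifest)
  set.seed(channel_seed(m$seed, "kinetochores"))
  ax <- stats::rnorm(m$n_kinetochores, 0, m$kinetochore_spread_sigma)
  lat <- stats::rnorm(m$n_kinetochores, 0, m$kinetochore_lateral_sigma)
  lat <- pmin(pmax(lat, -m$body_half_width), m$body_half_width)
  kx <- mid[1] + ax * uhat[1] + lat * vhat[1]
  ky <- mid[2] + ax * uhat[2] + lat * vhat[2]
  m$kinetochore_axial_um <- half_xy + ax  # distance from pole 1 along axis
  m$kinetochore_lateral_um <- lat
  m$kinetochore_xy_um <- cbind(x = kx, y = ky)

  zs <- if (m$n_z > 1L) (seq_len(m$n_z) - 1) * m$z_step else 0
  z_center <- if (m$n_z > 1L) mean(zs) else 0
  psf_sigma_z_um <- 0.6  # axial extent of in-focus signal for z-stacks
  zw <- function(z_obj, z_slice) exp(-(z_slice - z_obj)^2 /
                                       (2 * psf_sigma_z_um^2))

  ac <- axis_coords(m, g)
  render_channel <- function(ch, z_slice) {
    mat <- matrix(0, ny, nx)
    if (ch == "poles") {
      w <- zw(p[, "z"], z_slice)
      mat <- render_spots(mat, p[, "x"] / px, p[, "y"] / px,
                          m$pole_amplitude * w, m$psf_sigma_px)
    } else if (ch == "kinetochores") {
      w <- zw(rep(z_center, length(kx)), z_slice)
      mat <- render_spots(mat, kx / px, ky / px,
                          m$kinetochore_amplitude * w,
                          m$kinetochore_spot_sigma_px %||% m$psf_sigma_px)
    } else if (ch == "tubulin") {
      a <- half_xy + 1; b <- m$body_half_width
      f <- (ac$u / a)^2 + (ac$v / b)^2
      body <- f <= 1
      a2 <- a + m$shell_width; b2 <- b + m$shell_width
      shell <- !body & ((ac$u / a2)^2 + (ac$v / b2)^2) <= 1
      mat <- m$tubulin_body_intensity *
        (body + m$peripheral_to_inner_intensity * shell) *
        zw(z_center, z_slice)
    } else if (ch == "GFP") {
      h <- m$kmass_half_extent
      inner <- abs(ac$u) <= h & abs(ac$v) <= m$body_half_width
      # outer zone extends slightly past 2h so a line of length 4h does not
      # end on a rasterized edge mixed with background
      outer <- abs(ac$u) > h & abs(ac$u) <= 2 * h + 0.5 &
        abs(ac$v) <= m$body_half_width
      mat <- m$gfp_inner_intensity *
        (inner + m$peripheral_to_inner_intensity * outer) *
        zw(z_center, z_slice)
    } else if (ch == "DNA") {
      inner <- abs(ac$u) <= m$kmass_half_extent &
        abs(ac$v) <= m$body_half_width
      mat <- 0.8 * m$gfp_inner_intensity * inner * zw(z_center, z_slice)
    }
    mat + m$background_level
  }

  data <- array(0, dim = c(length(channels), m$n_z, ny, nx))
  for (ic in seq_along(channels)) for (iz in seq_len(m$n_z)) {
    mat <- render_channel(channels[ic], zs[iz])
    data[ic, iz, , ] <- apply_noise(mat, m$noise,
                                    m$seed + 131L * ic + 17L * iz)
  }
  axes <- if (m$n_z > 1L) c("channel", "z", "y", "x") else
    c("channel", "y", "x")
  if (m$n_z == 1L) data <- array(data, dim = c(length(channels), ny, nx))
  cal <- calibration(px, z_step = if (m$n_z > 1L) m$z_step else NULL)
  img <- calibrated_image(data, axes, cal, channel_names = channels)
  list(image = img, manifest = m)
}

#' Ground-truth manifest for a monastrol-like monopolar cell
#'
#' One pole at the field center, DNA as a disk of radius `dna_radius` around
#' it, and an EB1 channel of puncta with independent densities inside the
#' DNA region versus a surrounding band — the geometry of the
#' band-ratio polymerization assay.
#'
#' @inheritParams bipolar_manifest
#' @param dna_radius Radius of the DNA disk, um.
#' @param band_width Width of the peripheral band, um.
#' @param eb1_density_inner EB1 puncta density inside the DNA disk,
#'   puncta/um^2.
#' @param peripheral_to_inner_intensity Ratio of band to inner puncta
#'   density; the ground truth for [band_ratio()] recovery.
#' @param eb1_amplitude,dna_intensity Peak intensities.
#' @return A `"GroundTruthManifest"` list.
#' @export
monopolar_manifest <- function(seed, dna_radius = 4, band_width = 2.5,
                               eb1_density_inner = 0.8,
                               peripheral_to_inner_intensity = 1,
                               eb1_amplitude = 150, dna_intensity = 100,
                               pole_amplitude = 400,
                               field_ny = 256L, field_nx = 256L,
                               pixel_size = 0.1083, psf_sigma_px = 1.3,
                               background_level = 0,
                               noise = noise_model()) {
  if (dna_radius <= 0 || band_width <= 0)
    stop("dna_radius and band_width must be positive", call. = FALSE)
  if (eb1_density_inner < 0 || peripheral_to_inner_intensity < 0)
    stop("densities must be non-negative", call. = FALSE)
  fov <- (min(field_nx, field_ny) - 1) * pixel_size
  if (2 * (dna_radius + band_width) >= fov)
    stop("DNA disk plus band exceeds the field of view", call. = FALSE)
  new_manifest("monopolar", c(
    list(seed = as.integer(seed),
         pole_positions = matrix(c((field_nx - 1) * pixel_size / 2,
                                   (field_ny - 1) * pixel_size / 2, 0),
                                 1, 3, dimnames = list(NULL, c("x","y","z"))),
         dna_radius = dna_radius, band_width = band_width,
         eb1_density_inner = eb1_density_inner,
         peripheral_to_inner_intensity = peripheral_to_inner_intensity,
         eb1_amplitude = eb1_amplitude, dna_intensity = dna_intensity,
         pole_amplitude = pole_amplitude),
    common_field_defaults(field_ny, field_nx, pixel_size, psf_sigma_px,
                          background_level, noise)))
}

#' Render a monopolar cell
#'
#' @param manifest A [monopolar_manifest()].
#' @param channels Subset of `c("poles", "DNA", "EB1")`.
#' @return A list `(image, manifest)`; the manifest gains the realized EB1
#'   puncta counts and positions per region.
#' @export
simulate_monopolar_cell <- function(manifest,
                                    channels = c("poles", "DNA", "EB1")) {
  stopifnot(inherits(manifest, "GroundTruthManifest"),
            manifest$kind == "monopolar")
  m <- manifest
  ny <- m$field_ny; nx <- m$field_nx; px <- m$pixel_size
  g <- field_grids(ny, nx, px)
  cx <- m$pole_positions[1, "x"]; cy <- m$pole_positions[1, "y"]
  R <- m$dna_radius; W <- m$band_width

  # EB1 puncta: uniform in each region at its stated density. A margin
  # annulus beyond the band continues the band density so the measured
  # band is not biased by an artificial drop to zero at its outer edge
  # (real cells have microtubules beyond the band too).
  set.seed(channel_seed(m$seed, "EB1"))
  marg <- 0.5
  a_in <- pi * R^2
  a_band <- pi * ((R + W)^2 - R^2)
  a_marg <- pi * ((R + W + marg)^2 - (R + W)^2)
  dens_band <- m$eb1_density_inner * m$peripheral_to_inner_intensity
  n_in <- round(m$eb1_density_inner * a_in)
  n_band <- round(dens_band * a_band)
  n_marg <- round(dens_band * a_marg)
  ring <- function(n, r0, r1) {
    r <- sqrt(r0^2 + stats::runif(n) * (r1^2 - r0^2))
    t <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(t), r * sin(t))
  }
  pts <- rbind(ring(n_in, 0, R), ring(n_band, R, R + W),
               ring(n_marg, R + W, R + W + marg))
  ex <- cx + pts[, 1]; ey <- cy + pts[, 2]
  m$eb1_n_inner <- n_in; m$eb1_n_band <- n_band; m$eb1_n_margin <- n_marg
  m$eb1_xy_um <- cbind(x = ex, y = ey)

  X <- matrix(g$x, ny, nx, byrow = TRUE) - cx
  Y <- matrix(g$y, ny, nx) - cy
  dist <- sqrt(X^2 + Y^2)
  render_channel <- function(ch) {
    mat <- matrix(0, ny, nx)
    if (ch == "poles") {
      mat <- render_spots(mat, cx / px, cy / px, m$pole_amplitude,
                          m$psf_sigma_px)
    } else if (ch == "DNA") {
      mat <- m$dna_intensity * (dist <= R)
    } else if (ch == "EB1") {
      if (length(ex))
        mat <- render_spots(mat, ex / px, ey / px, m$eb1_amplitude,
                            m$psf_sigma_px)
    }
    mat + m$background_level
  }
  data <- array(0, dim = c(length(channels), ny, nx))
  for (ic in seq_along(channels))
    data[ic, , ] <- apply_noise(render_channel(channels[ic]), m$noise,
                                m$seed + 131L * ic)
  img <- calibrated_image(data, c("channel", "y", "x"), calibration(px),
                          channel_names = channels)
  list(image = img, manifest = m)
}

#' True DNA-disk mask of a monopolar manifest
#' @param manifest A rendered or unrendered [monopolar_manifest()].
#' @return Logical (y, x) matrix, `TRUE` inside the DNA disk.
#' @export
manifest_dna_mask <- function(manifest) {
  stopifnot(manifest$kind == "monopolar")
  g <- field_grids(manifest$field_ny, manifest$field_nx,
                   manifest$pixel_size)
  X <- matrix(g$x, manifest$field_ny, manifest$field_nx, byrow = TRUE) -
    manifest$pole_positions[1, "x"]
  Y <- matrix(g$y, manifest$field_ny, manifest$field_nx) -
    manifest$pole_positions[1, "y"]
  sqrt(X^2 + Y^2) <= manifest$dna_radius
}

#' True spindle-body mask of a bipolar manifest
#' @param manifest A [bipolar_manifest()].
#' @return Logical (y, x) matrix, `TRUE` inside the elliptical spindle body.
#' @export
manifest_spindle_mask <- function(manifest) {
  stopifnot(manifest$kind == "bipolar")
  g <- field_grids(manifest$field_ny, manifest$field_nx,
                   manifest$pixel_size)
  ac <- axis_coords(manifest, g)
  p <- manifest$pole_positions
  a <- sqrt(sum((p[2, 1:2] - p[1, 1:2])^2)) / 2 + 1
  b <- manifest$body_half_width
  (ac$u / a)^2 + (ac$v / b)^2 <= 1
}

#' Ground-truth manifest for a rotating-spindle time lapse
#'
#' A bipolar spindle rotating rigidly in the xy plane about its centroid at
#' `rotation_rate` degrees per minute, imaged every `frame_interval_min`
#' minutes for `n_frames` frames.
#'
#' @inheritParams bipolar_manifest
#' @param radius Pole-to-centroid distance, um (half the spindle length).
#' @param rotation_rate Degrees per minute.
#' @param n_frames Number of frames.
#' @param frame_interval_min Minutes per frame.
#' @param start_angle_deg Axis orientation at frame 1.
#' @return A `"GroundTruthManifest"` whose `pole_track_um` lists the true
#'   (frame, x, y) positions of pole 1 (and `pole2_track_um` of pole 2).
#' @export
rotation_manifest <- function(seed, radius = 5, rotation_rate = 6,
                              n_frames = 31L, frame_interval_min = 1,
                              start_angle_deg = 0,
                              pole_amplitude = 400,
                              field_ny = 256L, field_nx = 256L,
                              pixel_size = 0.1083, psf_sigma_px = 1.3,
                              background_level = 10,
                              noise = noise_model()) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  cx <- (field_nx - 1) * pixel_size / 2
  cy <- (field_ny - 1) * pixel_size / 2
  t_min <- (seq_len(n_frames) - 1) * frame_interval_min
  ang <- (start_angle_deg + rotation_rate * t_min) * pi / 180
  track1 <- cbind(frame = seq_len(n_frames),
                  x = cx + radius * cos(ang), y = cy + radius * sin(ang))
  track2 <- cbind(frame = seq_len(n_frames),
                  x = cx - radius * cos(ang), y = cy - radius * sin(ang))
  new_manifest("rotation", c(
    list(seed = as.integer(seed), radius = radius,
         rotation_rate = rotation_rate, n_frames = as.integer(n_frames),
         frame_interval_min = frame_interval_min,
         start_angle_deg = start_angle_deg,
         center_um = c(x = cx, y = cy),
         pole_track_um = track1, pole2_track_um = track2,
         pole_amplitude = pole_amplitude),
    common_field_defaults(field_ny, field_nx, pixel_size, psf_sigma_px,
                          background_level, noise)))
}

#' Render a rotating-spindle time lapse
#'
#' @param manifest A [rotation_manifest()].
#' @return A list `(image, manifest)`; the image has axes
#'   `(channel, time, y, x)` with a single `"poles"` channel and
#'   frame-interval calibration in minutes.
#' @export
simulate_rotation_movie <- function(manifest) {
  stopifnot(inherits(manifest, "GroundTruthManifest"),
            manifest$kind == "rotation")
  m <- manifest
  ny <- m$field_ny; nx <- m$field_nx; px <- m$pixel_size
  data <- array(0, dim = c(1L, m$n_frames, ny, nx))
  for (it in seq_len(m$n_frames)) {
    mat <- matrix(0, ny, nx)
    xs <- c(m$pole_track_um[it, "x"], m$pole2_track_um[it, "x"]) / px
    ys <- c(m$pole_track_um[it, "y"], m$pole2_track_um[it, "y"]) / px
    mat <- render_spots(mat, xs, ys, m$pole_amplitude, m$psf_sigma_px)
    data[1L, it, , ] <- apply_noise(mat + m$background_level, m$noise,
                                    m$seed + 17L * it)
  }
  cal <- calibration(px, frame_interval = m$frame_interval_min,
                     time_unit = "min")
  img <- calibrated_image(data, c("channel", "time", "y", "x"), cal,
                          channel_names = "poles")
  list(image = img, manifest = m)
}

#' Ground-truth manifest for a single-molecule kymograph
#'
#' One or more constant-velocity runs on a noisy background, matching a
#' TIRF acquisition read out along one microtubule: position across columns,
#' time down rows.
#'
#' @param seed Integer RNG seed.
#' @param runs A data frame (or list coercible to one) with columns
#'   `velocity` (um/s, signed), `run_length` (um), `start_px` (0-based
#'   starting column) and `start_frame` (1-based starting row).
#' @param n_px,n_frames Kymograph width (positions) and height (frames).
#' @param pixel_size um/px.
#' @param frame_interval s/frame (0.1 s matches a 10 frames/s acquisition).
#' @param amplitude Peak ridge intensity above background.
#' @param snr Peak signal-to-noise ratio; Gaussian noise of SD
#'   `amplitude / snr` is added when `noise = TRUE`.
#' @param noise Logical; disable for exact tests.
#' @return A `"GroundTruthManifest"`; per-run truth is in `runs` with the
#'   implied `duration_s = run_length / |velocity|`.
#' @export
kymograph_manifest <- function(seed, runs, n_px = 80L, n_frames = 200L,
                               pixel_size = 0.1, frame_interval = 0.1,
                               amplitude = 100, snr = 10, noise = TRUE) {
  runs <- as.data.frame(runs)
  stopifnot(all(c("velocity", "run_length", "start_px", "start_frame") %in%
                  names(runs)))
  runs$duration_s <- ifelse(runs$velocity != 0,
                            runs$run_length / abs(runs$velocity), NA_real_)
  new_manifest("kymograph", list(
    seed = as.integer(seed), runs = runs, n_px = as.integer(n_px),
    n_frames = as.integer(n_frames), pixel_size = pixel_size,
    frame_interval = frame_interval, amplitude = amplitude, snr = snr,
    noise = isTRUE(noise), psf_sigma_px = 1.0, background_level = 10))
}

#' Render a kymograph with constant-velocity runs
#'
#' @param manifest A [kymograph_manifest()].
#' @return A list `(kymograph, manifest)` where `kymograph` is a
#'   [kymograph()] (time rows x position columns).
#' @export
simulate_kymograph <- function(manifest) {
  stopifnot(inherits(manifest, "GroundTruthManifest"),
            manifest$kind == "kymograph")
  m <- manifest
  mat <- matrix(m$background_level, m$n_frames, m$n_px)
  for (i in seq_len(nrow(m$runs))) {
    r <- m$runs[i, ]
    n_run <- if (r$velocity == 0) m$n_frames - r$start_frame + 1L else
      max(1L, round(r$duration_s / m$frame_interval))
    frames <- r$start_frame + seq_len(n_run) - 1L
    frames <- frames[frames <= m$n_frames]
    pos_px <- r$start_px + r$velocity * (seq_along(frames) - 1L) *
      m$frame_interval / m$pixel_size
    keep <- pos_px >= 0 & pos_px <= m$n_px - 1
    frames <- frames[keep]; pos_px <- pos_px[keep]
    cols <- seq_len(m$n_px) - 1
    for (k in seq_along(frames)) {
      mat[frames[k], ] <- mat[frames[k], ] +
        m$amplitude * exp(-(cols - pos_px[k])^2 / (2 * m$psf_sigma_px^2))
    }
  }
  if (m$noise) {
    set.seed(channel_seed(m$seed, "kymo"))
    mat <- pmax(mat + stats::rnorm(length(mat), 0, m$amplitude / m$snr), 0)
  }
  list(kymograph = kymograph(mat, m$pixel_size, m$frame_interval),
       manifest = m)
}
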
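#' Synthetic mini-CA1 fixtures
#'
#' The fixture generator builds a desk-scale stand-in for a segmented
#' hippocampal CA1 sheet: a bent rectangular sheet (half-pipe) whose deep
#' (stratum oriens, SO) surface carries a sinusoidal gyrification along the
#' long (antero-posterior) axis. The superficial boundary of the pyramidal
#' layer (SR surface) and the stratum lacunosum-moleculare (SLM) surface are
#' parallel offsets of the SO surface along the depth axis. The two
#' transversal ends are marked by CA2-like and subiculum-like landmark
#' patches. All quantities are in micrometres.
#'
#' @param length_um,width_um,thickness_um sheet extent: long
#'   (antero-posterior) axis, transversal (CA2 to subiculum) axis, and full
#'   depth from the SO surface to the SLM surface.
#' @param gyrification_amplitude amplitude (um) of the sinusoidal folding of
#'   the surfaces along the long axis.
#' @param gyrification_wavelength wavelength (um) of that fold.
#' @param bend_depth depth (um) of the transversal half-pipe bend.
#' @param sr_frac,so_frac,slm_frac fractional depths (of `thickness_um`,
#'   measured from the SO surface) of the SO/SP boundary, the SP/SR boundary
#'   (the "SR surface" landmark) and the SR/SLM boundary.
#' @param grid_spacing vertex spacing (um) of the sampled surfaces; must be
#'   small enough that the nearest-vertex error is below the imaging
#'   resolution.
#' @return an object of class `mini_ca1_geometry`: surface point grids
#'   (`so_surface`, `sr_surface`, `slm_surface`, each an n x 3 matrix),
#'   landmark patches `ca2_patch` and `sub_patch`, and the generating
#'   parameters.
#' @examples
#' geom <- make_mini_ca1_landmarks(length_um = 2000, width_um = 1000)
#' range(geom$so_surface[, 3])
#' @export
make_mini_ca1_landmarks <- function(length_um = 6000, width_um = 3000,
                                    thickness_um = 1500,
                                    gyrification_amplitude = 200,
                                    gyrification_wavelength = 2000,
                                    bend_depth = 600,
                                    so_frac = 0.2, sr_frac = 0.55,
                                    slm_frac = 0.85,
                                    grid_spacing = 25) {
  stopifnot_scalar_pos(length_um, "length_um")
  stopifnot_scalar_pos(width_um, "width_um")
  stopifnot_scalar_pos(thickness_um, "thickness_um")
  stopifnot_scalar_pos(gyrification_wavelength, "gyrification_wavelength")
  stopifnot_scalar_pos(grid_spacing, "grid_spacing")
  if (gyrification_amplitude < 0) stop("gyrification_amplitude must be >= 0")
  if (!(0 < so_frac && so_frac < sr_frac && sr_frac < slm_frac &&
        slm_frac < 1))
    stop("fractional depths must satisfy 0 < so_frac < sr_frac < slm_frac < 1")

  geom <- structure(list(
    sheet_extent = c(length = length_um, width = width_um,
                     thickness = thickness_um),
    gyrification_amplitude = gyrification_amplitude,
    gyrification_wavelength = gyrification_wavelength,
    bend_depth = bend_depth,
    so_frac = so_frac, sr_frac = sr_frac, slm_frac = slm_frac,
    grid_spacing = grid_spacing), class = "mini_ca1_geometry")

  xs <- seq(0, length_um, by = grid_spacing)
  ys <- seq(0, width_um, by = grid_spacing)
  g <- expand.grid(x = xs, y = ys)
  geom$so_surface <- cbind(g$x, g$y, geometry_z(geom, g$x, g$y, 0))
  geom$sr_surface <- cbind(g$x, g$y, geometry_z(geom, g$x, g$y, sr_frac))
  geom$slm_surface <- cbind(g$x, g$y, geometry_z(geom, g$x, g$y, 1))
  colnames(geom$so_surface) <- colnames(geom$sr_surface) <-
    colnames(geom$slm_surface) <- c("x", "y", "z")

  # end walls spanning the full depth at y = 0 (CA2 side) and y = width
  ts <- seq(0, 1, length.out = max(2L, ceiling(thickness_um / grid_spacing)))
  wall <- function(yv) {
    w <- expand.grid(x = xs, t = ts)
    cbind(x = w$x, y = yv, z = geometry_z(geom, w$x, rep(yv, nrow(w)), w$t))
  }
  geom$ca2_patch <- wall(0)
  geom$sub_patch <- wall(width_um)
  stopifnot(all(is.finite(geom$so_surface)), all(is.finite(geom$slm_surface)))
  geom
}

#' Depth coordinate of the mini-CA1 surfaces
#'
#' Closed form of the generated sheet: the SO surface is
#' `z = bend_depth * (2 y / W - 1)^2 + A * (1 + sin(2 pi x / lambda))` and
#' the other layers are offsets `t * thickness` above it, with `t` the
#' fractional depth (0 = SO surface, 1 = SLM surface). The `+ A` offset
#' keeps all coordinates non-negative so any placement can be rendered to a
#' pixel grid.
#'
#' @param geometry a `mini_ca1_geometry` object.
#' @param x,y coordinates (um), recycled to a common length.
#' @param t fractional depth in `[0, 1]`.
#' @return z coordinates (um).
#' @export
geometry_z <- function(geometry, x, y, t) {
  W <- geometry$sheet_extent[["width"]]
  base <- geometry$bend_depth * (2 * y / W - 1)^2 +
    geometry$gyrification_amplitude *
      (1 + sin(2 * pi * x / geometry$gyrification_wavelength))
  base + t * geometry$sheet_extent[["thickness"]]
}

#' Imaging parameters for synthetic section stacks
#'
#' @param xy_resolution,z_resolution in-plane and inter-slice resolution
#'   (um/pixel, um/slice).
#' @param soma_intensity,background_intensity 8-bit grayscale values of a
#'   stained soma pixel and of the background; staining is dark on light so
#'   the soma intensity must be the lower one.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @return a validated `imaging_params` list.
#' @export
make_imaging_params <- function(xy_resolution = 20, z_resolution = 20,
                                soma_intensity = 30,
                                background_intensity = 200,
                                noise_sd = 10) {
  stopifnot_scalar_pos(xy_resolution, "xy_resolution")
  stopifnot_scalar_pos(z_resolution, "z_resolution")
  if (soma_intensity >= background_intensity)
    stop("soma_intensity must be below background_intensity ",
         "(dark staining on light background)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(xy_resolution = xy_resolution, z_resolution = z_resolution,
                 soma_intensity = soma_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd), class = "imaging_params")
}

#' Default soma density profile of the toy placement
#'
#' The profile emulates the anisotropy reported for human CA1: most somas in
#' a thick pyramidal layer with density increasing towards the SR border
#' (`sp_gradient` is the SR-side over SO-side density ratio inside SP) and an
#' antero-posterior ramp (`longitudinal_ramp` is the anterior over posterior
#' density ratio).
#'
#' @param stratum_weights non-negative weights for the SO, SP, SR and SLM
#'   layers (normalized internally).
#' @param sp_gradient density ratio across the SP depth (SR side / SO side).
#' @param longitudinal_ramp density ratio along the long axis
#'   (anterior / posterior).
#' @return a `density_profile` list.
#' @export
density_profile <- function(stratum_weights = c(so = 0.1, sp = 0.7,
                                                sr = 0.15, slm = 0.05),
                            sp_gradient = 3, longitudinal_ramp = 2) {
  if (any(stratum_weights < 0)) stop("profile weights must all be >= 0")
  if (sum(stratum_weights) <= 0) stop("profile weights must not all be zero")
  stopifnot(length(stratum_weights) == 4L)
  names(stratum_weights) <- c("so", "sp", "sr", "slm")
  if (sp_gradient <= 0 || longitudinal_ramp <= 0)
    stop("gradients must be positive")
  structure(list(stratum_weights = stratum_weights / sum(stratum_weights),
                 sp_gradient = sp_gradient,
                 longitudinal_ramp = longitudinal_ramp),
            class = "density_profile")
}

# inverse-CDF draw from a linear density ramp f(u) = a + (1 - a) u on [0, 1]
# where a is the density at u = 0 relative to u = 1
sample_linear_ramp <- function(n, ratio) {
  u <- runif(n)
  if (abs(ratio - 1) < 1e-12) return(u)
  a <- ratio
  z <- (a + 1) / 2
  (-a + sqrt(a^2 + 2 * (1 - a) * u * z)) / (1 - a)
}

#' Generate a toy soma placement inside the mini-CA1 sheet
#'
#' Somas are distributed across the four layers according to the stratum
#' weights, with a within-SP depth gradient and an antero-posterior ramp,
#' then labelled: 90%/10% excitatory/inhibitory split (configurable) and the
#' seven interneuron classes assigned by the landmark rules of
#' [assign_interneuron_classes()].
#'
#' @param geometry a `mini_ca1_geometry`.
#' @param n number of somas (>= 1).
#' @param profile a [density_profile()].
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param config a [class_config()]; `NULL` labels every soma "PC".
#' @return a placement data frame with columns `gid, x, y, z, type, class`.
#' @export
make_toy_placement <- function(geometry, n, profile = density_profile(),
                               seed = 1, config = class_config()) {
  stopifnot(inherits(geometry, "mini_ca1_geometry"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  ext <- geometry$sheet_extent
  with_seed(seed, {
    # anterior (x = 0) to posterior ramp: density ratio ramp:1
    u <- sample_linear_ramp(n, profile$longitudinal_ramp)
    x <- u * ext[["length"]]
    y <- runif(n, 0, ext[["width"]])
    stratum <- sample(names(profile$stratum_weights), n, replace = TRUE,
                      prob = profile$stratum_weights)
    bands <- rbind(so = c(0, geometry$so_frac),
                   sp = c(geometry$so_frac, geometry$sr_frac),
                   sr = c(geometry$sr_frac, geometry$slm_frac),
                   slm = c(geometry$slm_frac, 1))
    v <- runif(n)
    in_sp <- stratum == "sp"
    if (any(in_sp) && abs(profile$sp_gradient - 1) > 1e-12) {
      # within-SP density increases towards the SR side by sp_gradient
      v[in_sp] <- 1 - sample_linear_ramp(sum(in_sp), profile$sp_gradient)
    }
    t <- bands[stratum, 1] + v * (bands[stratum, 2] - bands[stratum, 1])
    z <- geometry_z(geometry, x, y, t)
    placement <- data.frame(gid = seq_len(n), x = x, y = y, z = z,
                            type = "exc", class = "PC",
                            stringsAsFactors = FALSE)
    if (!is.null(config)) {
      split <- population_split(n, config$inhibitory_ratio)
      if (split$n_inh > 0) {
        inh <- sample.int(n, split$n_inh)
        placement$type[inh] <- "inh"
        placement$class[inh] <- NA_character_
        placement <- assign_interneuron_classes(
          placement, geometry_landmarks(geometry), config,
          seed = NULL)
      }
    }
    placement
  })
}

#' Landmark point clouds of a mini-CA1 geometry
#'
#' @param geometry a `mini_ca1_geometry`.
#' @return named list of point matrices with roles `so`, `sr`, `slm`,
#'   `ca2`, `sub`.
#' @export
geometry_landmarks <- function(geometry) {
  list(so = geometry$so_surface, sr = geometry$sr_surface,
       slm = geometry$slm_surface, ca2 = geometry$ca2_patch,
       sub = geometry$sub_patch)
}

#' Render a placement as a synthetic stained section stack
#'
#' Each soma renders as one dark pixel (optionally a 3 x 3 blob) at
#' `(row, col, slice) = (round(y / xy_res), round(x / xy_res),
#' round(z / z_res))`, 0-based, emulating dark-soma-on-light silver-stained
#' sections at soma-sized pixels. Gaussian noise of `noise_sd` is added and
#' intensities clamped to 0..255.
#'
#' @param placement placement data frame (`gid, x, y, z`).
#' @param imaging an [make_imaging_params()] object.
#' @param seed seed for the noise.
#' @param dims optional `(rows, cols, slices)`; defaults to the smallest
#'   stack containing all somas. A soma outside the given volume is an
#'   error naming its GID.
#' @param blob if `TRUE` render 3 x 3 blobs instead of single pixels.
#' @return list with `stack` (rows x cols x slices array of 0..255 values)
#'   and `truth` (data frame `gid, x_um, y_um, z_um, row, col, slice`,
#'   indices 0-based).
#' @export
render_synthetic_stack <- function(placement, imaging = make_imaging_params(),
                                   seed = 1, dims = NULL, blob = FALSE) {
  stopifnot(inherits(imaging, "imaging_params"))
  if (any(placement$x < 0 | placement$y < 0 | placement$z < 0))
    stop("somas must have non-negative coordinates")
  col <- as.integer(round(placement$x / imaging$xy_resolution))
  row <- as.integer(round(placement$y / imaging$xy_resolution))
  slc <- as.integer(round(placement$z / imaging$z_resolution))
  if (is.null(dims)) {
    dims <- c(max(row) + 1L, max(col) + 1L, max(slc) + 1L)
  } else {
    bad <- which(row >= dims[1] | col >= dims[2] | slc >= dims[3])
    if (length(bad))
      stop("soma outside imaged volume, GID ", placement$gid[bad[1]])
  }
  truth <- data.frame(gid = placement$gid, x_um = placement$x,
                      y_um = placement$y, z_um = placement$z,
                      row = row, col = col, slice = slc)
  stack <- array(imaging$background_intensity, dim = dims)
  for (i in seq_len(nrow(truth))) {
    r <- row[i] + 1L; cc <- col[i] + 1L; s <- slc[i] + 1L
    if (blob) {
      rr <- max(1L, r - 1L):min(dims[1], r + 1L)
      cs <- max(1L, cc - 1L):min(dims[2], cc + 1L)
      stack[rr, cs, s] <- imaging$soma_intensity
    } else {
      stack[r, cc, s] <- imaging$soma_intensity
    }
  }
  if (imaging$noise_sd > 0) {
    with_seed(seed, {
      stack <- stack + rnorm(length(stack), 0, imaging$noise_sd)
    })
    stack <- pmin(pmax(stack, 0), 255)
  }
  list(stack = stack, truth = truth, imaging = imaging)
}
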
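#' Voxel density grid of a placement
#'
#' Partitions 3D soma positions into a uniform grid of cubic voxels
#' (half-open intervals `[lo, lo + s)` on every axis, so each soma counts
#' in exactly one voxel) and returns per-voxel neuron counts. The uniform
#' fixed-depth partition is contract-equivalent to the recursive octree
#' subdivision often used for this task.
#'
#' @param placement placement data frame (or n x 3 matrix).
#' @param voxel_size voxel edge length in um (default 300).
#' @param origin grid origin; defaults to the voxel-aligned floor of the
#'   placement minimum so that every soma is inside the grid.
#' @return a `density_grid`: list with `origin`, `voxel_size` and the 3D
#'   integer `counts` array (x, y, z order).
#' @export
voxel_density <- function(placement, voxel_size = 300, origin = NULL) {
  stopifnot_scalar_pos(voxel_size, "voxel_size")
  pos <- if (is.data.frame(placement))
    as.matrix(placement[, c("x", "y", "z")]) else as.matrix(placement)
  if (is.null(origin))
    origin <- floor(apply(pos, 2, min) / voxel_size) * voxel_size
  idx <- floor(sweep(pos, 2, origin) / voxel_size)
  if (any(idx < 0)) stop("placement extends below the grid origin")
  dims <- apply(idx, 2, max) + 1
  counts <- array(0L, dim = dims)
  flat <- idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]) + 1
  tab <- tabulate(flat, nbins = prod(dims))
  counts[] <- tab
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 counts = counts), class = "density_grid")
}

# count somas inside a cubic voxel centred at `center`
count_in_voxel <- function(pos, center, size) {
  h <- size / 2
  sum(pos[, 1] >= center[1] - h & pos[, 1] < center[1] + h &
      pos[, 2] >= center[2] - h & pos[, 2] < center[2] + h &
      pos[, 3] >= center[3] - h & pos[, 3] < center[3] + h)
}

#' Transversal (SO-to-SR) density gradient inside the pyramidal layer
#'
#' For each of `n_slices` transversal slices along the long axis, mean
#' densities are sampled in three stripes of the SP running parallel to the
#' CA1 surfaces: lateral (SO side), middle, and medial (SR side), each
#' sampled at `n_voxels_per_stripe` cubic voxels spaced along the
#' transversal axis at the stripe's fractional depth. The per-slice
#' percent increase is `(medial - lateral) / lateral * 100`, summarized as
#' mean and standard error over slices.
#'
#' @param placement placement data frame.
#' @param geometry the `mini_ca1_geometry` the placement lives in (supplies
#'   the SP depth band and the surface closed form).
#' @param n_slices number of transversal slices (default 10).
#' @param n_voxels_per_stripe voxels sampled per stripe (default 25).
#' @param voxel_size sampling voxel edge (um, default 300).
#' @return list with per-slice stripe densities (neurons/mm^3), per-slice
#'   `percent_increase`, and `mean`/`sem` of the increase; slices with an
#'   empty lateral stripe are skipped with a warning.
#' @export
transversal_profile <- function(placement, geometry, n_slices = 10,
                                n_voxels_per_stripe = 25, voxel_size = 300) {
  pos <- as.matrix(placement[, c("x", "y", "z")])
  ext <- geometry$sheet_extent
  # three stripe depths: SP band split in three
  band <- c(geometry$so_frac, geometry$sr_frac)
  t_stripes <- band[1] + (c(1, 3, 5) / 6) * diff(band)
  xs <- seq(ext[["length"]] / (2 * n_slices), ext[["length"]],
            length.out = n_slices)
  ys <- seq(ext[["width"]] / (2 * n_voxels_per_stripe), ext[["width"]],
            length.out = n_voxels_per_stripe)
  vol_mm3 <- (voxel_size / 1000)^3
  dens <- array(NA_real_, dim = c(n_slices, 3, n_voxels_per_stripe))
  for (i in seq_len(n_slices)) {
    for (k in 1:3) {
      for (j in seq_len(n_voxels_per_stripe)) {
        center <- c(xs[i], ys[j],
                    geometry_z(geometry, xs[i], ys[j], t_stripes[k]))
        dens[i, k, j] <- count_in_voxel(pos, center, voxel_size) / vol_mm3
      }
    }
  }
  stripe_means <- apply(dens, c(1, 2), mean)
  colnames(stripe_means) <- c("lateral_so", "middle", "medial_sr")
  pct <- rep(NA_real_, n_slices)
  for (i in seq_len(n_slices)) {
    if (stripe_means[i, 1] == 0) {
      warning("empty lateral stripe in slice ", i, ": slice skipped")
      next
    }
    pct[i] <- (stripe_means[i, 3] - stripe_means[i, 1]) /
      stripe_means[i, 1] * 100
  }
  ok <- !is.na(pct)
  list(stripe_densities = stripe_means, percent_increase = pct,
       mean = mean(pct[ok]),
       sem = stats::sd(pct[ok]) / sqrt(sum(ok)))
}

#' Antero-posterior density profile
#'
#' Samples `axis_positions` positions along the long axis; at each, `reps`
#' cubic voxels (edge `voxel_size`, default 1,000 um) are placed at random
#' transversal positions with centres jittered uniformly within half a
#' voxel, and the profile point is the mean of their densities. The summary
#' statistic is the percent difference between the mean of the first four
#' and the mean of the last four profile points,
#' `(first4 - last4) / last4 * 100` by default (`direction = "first_vs_last"`;
#' the opposite convention is available as `"last_vs_first"`).
#'
#' @param placement placement data frame.
#' @param geometry the `mini_ca1_geometry`.
#' @param axis_positions number of profile points (default 25).
#' @param reps sampled voxels per position (default 13).
#' @param voxel_size sampling voxel edge (um, default 1000).
#' @param seed seed for the jitter.
#' @param direction sign convention of the percent difference.
#' @return list with `profile` (mean density per position, neurons/mm^3),
#'   the per-position sample matrix, and `percent_difference` (`NA` if
#'   fewer than 8 profile points are non-empty).
#' @export
longitudinal_profile <- function(placement, geometry, axis_positions = 25,
                                 reps = 13, voxel_size = 1000, seed = 1,
                                 direction = c("first_vs_last",
                                               "last_vs_first")) {
  direction <- match.arg(direction)
  pos <- as.matrix(placement[, c("x", "y", "z")])
  ext <- geometry$sheet_extent
  xs <- seq(voxel_size / 2, ext[["length"]] - voxel_size / 2,
            length.out = axis_positions)
  vol_mm3 <- (voxel_size / 1000)^3
  with_seed(seed, {
    samples <- matrix(NA_real_, axis_positions, reps)
    for (i in seq_len(axis_positions)) {
      for (r in seq_len(reps)) {
        yc <- runif(1, 0, ext[["width"]])
        center <- c(xs[i], yc, geometry_z(geometry, xs[i], yc, 0.5)) +
          runif(3, -voxel_size / 2, voxel_size / 2)
        samples[i, r] <- count_in_voxel(pos, center, voxel_size) / vol_mm3
      }
    }
    profile <- rowMeans(samples)
    nonempty <- sum(profile > 0)
    pct <- NA_real_
    if (nonempty >= 8) {
      first4 <- mean(profile[1:4])
      last4 <- mean(profile[(axis_positions - 3):axis_positions])
      pct <- if (direction == "first_vs_last") {
        (first4 - last4) / last4 * 100
      } else {
        (last4 - first4) / first4 * 100
      }
    } else {
      warning("fewer than 8 non-empty profile points: ",
              "percent difference not computed")
    }
    list(positions = xs, profile = profile, samples = samples,
         percent_difference = pct)
  })
}

#' Export a density grid as a CSV of voxel centres and counts
#'
#' @param grid a `density_grid`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_density_csv <- function(grid, path) {
  d <- dim(grid$counts)
  centers <- expand.grid(ix = seq_len(d[1]) - 1, iy = seq_len(d[2]) - 1,
                         iz = seq_len(d[3]) - 1)
  df <- data.frame(
    x = grid$origin[1] + (centers$ix + 0.5) * grid$voxel_size,
    y = grid$origin[2] + (centers$iy + 0.5) * grid$voxel_size,
    z = grid$origin[3] + (centers$iz + 0.5) * grid$voxel_size,
    count = as.vector(grid$counts))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
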
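#' Point budget of a geometric probability volume
#'
#' Dendritic clouds are scattered at a fixed density of one point per
#' `point_volume` cubic micrometres (default 64,000 um^3, a 40 um voxel):
#' the budget is `floor(volume / point_volume)`, never below one point.
#' For example a pyramidal apical-dendrite cone of about 11,780,000 um^3
#' yields 184 points.
#'
#' @param volume shape volume in um^3.
#' @param point_volume volume represented by one point (um^3).
#' @return integer point count.
#' @export
point_budget <- function(volume, point_volume = 64000) {
  stopifnot_scalar_pos(point_volume, "point_volume")
  if (any(volume <= 0)) stop("volume must be positive")
  pmax(1L, as.integer(floor(volume / point_volume)))
}

#' Cone specification
#'
#' A cone from apex `O` to base centre `P` with base radius `R`. The axis
#' is `d = P - O` with height `H = |d|`; `u` and `v` are deterministic
#' orthonormal in-plane vectors of the base circle.
#'
#' @param apex,base_center 3-vectors (um).
#' @param radius base radius (um).
#' @return a `cone_spec` list with fields `O`, `P`, `R`, `d`, `H`, `u`, `v`.
#' @export
cone_spec <- function(apex, base_center, radius) {
  d <- base_center - apex
  H <- sqrt(sum(d^2))
  if (H <= 0) stop("degenerate cone: apex equals base centre")
  stopifnot_scalar_pos(radius, "radius")
  dh <- d / H
  e <- diag(3)[, which.min(abs(dh))]
  u <- cross3(dh, e)
  u <- u / sqrt(sum(u^2))
  v <- cross3(dh, u)
  structure(list(O = apex, P = base_center, R = radius, d = d, H = H,
                 u = u, v = v), class = "cone_spec")
}

cone_volume <- function(spec) pi * spec$R^2 * spec$H / 3

#' Sample points from a cone
#'
#' Surface mode scatters points exactly on the lateral surface: at height
#' `h` from the apex the point sits at radius `R * h / H` in the base-plane
#' directions, i.e. `O + (h/H) d + R (h/H) (cos(theta) u + sin(theta) v)`.
#' Volume mode (the default for dendritic clouds) scatters uniformly in the
#' solid cone by inverse transform (`h = H * runif()^(1/3)`, in-disc radius
#' `sqrt(runif())` of the local radius).
#'
#' @param spec a [cone_spec()].
#' @param n number of points.
#' @param seed optional seed (`NULL` continues the current stream).
#' @param mode `"volume"` or `"surface"`.
#' @param h,theta optional fixed parameter values (recycled), mainly for
#'   exactness checks; `h = 0` returns the apex exactly.
#' @return n x 3 point matrix.
#' @export
sample_cone_points <- function(spec, n, seed = NULL,
                               mode = c("volume", "surface"),
                               h = NULL, theta = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cone_spec"), n >= 1)
  with_seed(seed, {
    th <- if (is.null(theta)) runif(n, 0, 2 * pi) else rep_len(theta, n)
    if (mode == "surface") {
      hh <- if (is.null(h)) runif(n, 0, spec$H) else rep_len(h, n)
      rad <- spec$R * hh / spec$H
    } else {
      hh <- if (is.null(h)) spec$H * runif(n)^(1 / 3) else rep_len(h, n)
      rad <- sqrt(runif(n)) * spec$R * hh / spec$H
    }
    f <- hh / spec$H
    base <- outer(f, spec$d)
    lat <- (rad * cos(th)) %o% spec$u + (rad * sin(th)) %o% spec$v
    sweep(base + lat, 2, spec$O, "+")
  })
}

#' Ellipsoid specification
#'
#' An ellipsoid given by its centre, an orthonormal orientation matrix `U`
#' (columns are the principal directions) and semi-axis lengths
#' `lambda = (l1, l2, l3)`. The associated symmetric shape matrix is
#' `Q = U diag(lambda) t(U)`.
#'
#' @param center 3-vector (um).
#' @param axes 3 x 3 orthonormal matrix of principal directions.
#' @param semi_axes positive 3-vector of semi-axis lengths (um).
#' @return an `ellipsoid_spec` list.
#' @export
ellipsoid_spec <- function(center, axes = diag(3), semi_axes) {
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("non-orthonormal orientation matrix")
  if (any(semi_axes <= 0)) stop("semi-axis lengths must be positive")
  structure(list(center = center, U = axes, lambda = semi_axes,
                 Q = axes %*% diag(semi_axes) %*% t(axes)),
            class = "ellipsoid_spec")
}

ellipsoid_volume <- function(spec) 4 / 3 * pi * prod(spec$lambda)

#' Sample points from an ellipsoid
#'
#' Surface mode scatters points on the surface through the parametric
#' equations `(l1 cos(t) sin(p), l2 sin(t) sin(p), l3 cos(p))` with
#' `t in [0, 2 pi)`, `p in [-pi, 0]`, rotated by the orientation matrix;
#' every surface point satisfies `|diag(1/lambda) t(U) (x - center)| = 1`
#' to numerical precision. Volume mode scatters uniformly in the solid
#' ellipsoid (uniform ball scaled by the semi-axes), so the sample
#' covariance converges to `U diag(lambda^2 / 5) t(U)`.
#'
#' @param spec an [ellipsoid_spec()].
#' @param n number of points.
#' @param seed optional seed.
#' @param mode `"volume"` or `"surface"`.
#' @return n x 3 point matrix.
#' @export
sample_ellipsoid_points <- function(spec, n, seed = NULL,
                                    mode = c("volume", "surface")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "ellipsoid_spec"), n >= 1)
  with_seed(seed, {
    if (mode == "surface") {
      th <- runif(n, 0, 2 * pi)
      ph <- runif(n, -pi, 0)
      w <- cbind(cos(th) * sin(ph), sin(th) * sin(ph), cos(ph))
    } else {
      g <- matrix(rnorm(3 * n), n)
      w <- unit_rows(g) * runif(n)^(1 / 3)
    }
    s <- sweep(w, 2, spec$lambda, "*")
    sweep(s %*% t(spec$U), 2, spec$center, "+")
  })
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-neuron orientation frames from anatomical landmarks
#'
#' The transversal plane of a neuron contains its soma and spans the two
#' minimum-distance vectors to the CA2 and subiculum landmark surfaces; its
#' normal (the local longitudinal direction) is their normalized cross
#' product. The apical direction points towards the nearest SR-surface
#' vertex and the basal direction towards the nearest SO-surface vertex.
#' When the CA2 and subiculum vectors are numerically collinear the plane
#' normal falls back to the cross product of the transversal and apical
#' directions, with a warning.
#'
#' @param placement placement data frame.
#' @param landmarks named list with `so`, `sr`, `ca2`, `sub` (and `slm`)
#'   clouds.
#' @return list of n x 3 matrices `apical`, `basal`, `normal` (transversal
#'   plane normal), `t_hat` (CA2-to-subiculum direction), plus the
#'   per-landmark distances from [landmark_distances()].
#' @export
orient_frames <- function(placement, landmarks) {
  ld <- landmark_distances(placement[, c("x", "y", "z")],
                           landmarks[c("so", "sr", "ca2", "sub")])
  v_ca2 <- ld$ca2$direction
  v_sub <- ld$sub$direction
  normal <- rowcross(v_ca2, v_sub)
  nn <- sqrt(rowSums(normal^2))
  apical <- ld$sr$direction
  basal <- ld$so$direction
  t_hat <- unit_rows(v_sub - v_ca2)
  # the two landmark vectors are close to antiparallel for somas far from
  # both ends; below this sine threshold their cross product is dominated
  # by nearest-vertex noise and the local surface normal (the basal
  # direction, which points at the nearest SO vertex) defines the plane
  bad <- nn < 0.1
  if (any(bad)) {
    warning(sum(bad), " neuron(s) with collinear CA2/subiculum vectors: ",
            "falling back to the surface-normal plane")
    normal[bad, ] <- rowcross(t_hat[bad, , drop = FALSE],
                              basal[bad, , drop = FALSE])
  }
  normal <- unit_rows(normal)
  list(apical = apical, basal = basal, normal = normal, t_hat = t_hat,
       distances = ld)
}

#' Build a surface-following axonal tube for a pyramidal cell
#'
#' The tube centreline follows the deep (SO) CA1 surface inside a slab of
#' the neuron's transversal plane: SO-surface points within `slab_half` of
#' the plane are binned along the transversal direction, spline-resampled
#' into an ordered curve running from the CA2 side to the subiculum side,
#' and truncated at the soma's arc position minus a back-propagation
#' extent `min(back_max, k_back * geodesic distance to CA2)`. Tube points
#' are scattered uniformly within radius `r` of the centreline.
#'
#' @param soma 3-vector soma position.
#' @param normal,t_hat transversal plane normal and CA2-to-subiculum
#'   direction for this neuron (rows of [orient_frames()] output).
#' @param so_surface SO-surface point matrix.
#' @param r tube radius (um, default 150: a 300 um diameter cross-section).
#' @param back_max back-propagation cap towards CA2 (um, default 500).
#' @param k_back back-propagation gain (fraction of the geodesic distance
#'   to CA2; default 0.1, giving the typical ~150 um back-projection on the
#'   shipped fixture).
#' @param n_points points scattered in the tube.
#' @param slab_half half-thickness of the transversal slab (um).
#' @param resample_step centreline resampling step (um).
#' @param seed optional seed.
#' @return list with `spec` (a `tube_spec`: `centerline` N x 3, `radius`,
#'   `back_extent`) and `points` (n x 3).
#' @export
build_axon_tube <- function(soma, normal, t_hat, so_surface, r = 150,
                            back_max = 500, k_back = 0.1, n_points = 220,
                            slab_half = 40, resample_step = 25,
                            seed = NULL) {
  stopifnot_scalar_pos(r, "r")
  q <- as.matrix(so_surface)[, 1:3, drop = FALSE]
  off <- sweep(q, 2, soma)
  keep <- abs(off %*% normal) <= slab_half
  if (sum(keep) < 2)
    stop("fewer than 2 SO-surface points intersect the transversal slab: ",
         "surface too sparse")
  qk <- q[keep, , drop = FALSE]
  s <- (qk - matrix(soma, nrow(qk), 3, byrow = TRUE)) %*% t_hat
  # bin along the transversal direction and average to an ordered polyline
  bins <- factor(floor((s - min(s)) / resample_step))
  bins <- factor(bins, levels = as.character(sort(as.numeric(levels(bins)))))
  poly <- apply(qk, 2, function(col) tapply(col, bins, mean))
  poly <- matrix(poly, ncol = 3)
  if (nrow(poly) < 2)
    stop("fewer than 2 SO-surface points intersect the transversal slab: ",
         "surface too sparse")
  seg <- sqrt(rowSums(diff(poly)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  xout <- seq(0, L, by = resample_step)
  center <- cbind(spline(arc, poly[, 1], xout = xout)$y,
                  spline(arc, poly[, 2], xout = xout)$y,
                  spline(arc, poly[, 3], xout = xout)$y)
  # soma arc position; the CA2 side is the start (t_hat points to Sub)
  d2 <- colSums((t(center) - soma)^2)
  s0 <- xout[which.min(d2)]
  back_extent <- min(back_max, k_back * s0)
  keep_arc <- xout >= (s0 - back_extent)
  # somas at the subiculum end keep at least one tube segment
  if (sum(keep_arc) < 2)
    keep_arc[max(1, length(xout) - 1):length(xout)] <- TRUE
  center <- center[keep_arc, , drop = FALSE]
  xout <- xout[keep_arc]
  spec <- structure(list(centerline = center, radius = r,
                         back_extent = back_extent,
                         arc = xout - xout[1]), class = "tube_spec")
  with_seed(seed, {
    a <- runif(n_points, 0, spec$arc[length(spec$arc)])
    idx <- findInterval(a, spec$arc, all.inside = TRUE)
    frac <- (a - spec$arc[idx]) / pmax(spec$arc[idx + 1] - spec$arc[idx],
                                       1e-12)
    base <- center[idx, , drop = FALSE] +
      (center[idx + 1, , drop = FALSE] - center[idx, , drop = FALSE]) * frac
    tang <- unit_rows(center[idx + 1, , drop = FALSE] -
                      center[idx, , drop = FALSE])
    e1 <- rowcross(tang, matrix(normal, n_points, 3, byrow = TRUE))
    e1 <- unit_rows(e1)
    e2 <- unit_rows(rowcross(tang, e1))
    rad <- sqrt(runif(n_points)) * r
    th <- runif(n_points, 0, 2 * pi)
    pts <- base + e1 * (rad * cos(th)) + e2 * (rad * sin(th))
    list(spec = spec, points = pts)
  })
}

#' Default morphology parameter table
#'
#' One block per neuron class listing the geometric shapes of its axonal
#' and dendritic probability volumes, with normal-distribution means and
#' standard deviations of every linear dimension at rodent scale (um,
#' multiplied by `scale_factor` when realized). These defaults are
#' representative values assembled from rodent CA1 morphology literature
#' and public repositories; users with measured per-class tables should
#' supply their own. The pyramidal apical cone defaults are chosen so its
#' mean scaled volume is about 11,780,000 um^3 (184 dendritic points at
#' the default point volume).
#'
#' @param scale_factor rodent-to-human linear scale (default 1.5).
#' @param point_volume um^3 represented by one dendritic point (default
#'   64,000, a 40 um voxel).
#' @param truncation_floor sampled dimensions are truncated below this
#'   multiple of their scaled mean (default 0.2) so no dimension can be
#'   zero or negative.
#' @param axon_sample_points surface points scattered per axonal ellipsoid
#'   (the convex hull only needs the surface).
#' @return a `morphology_params` list.
#' @export
default_morphology_params <- function(scale_factor = 1.5,
                                      point_volume = 64000,
                                      truncation_floor = 0.2,
                                      axon_sample_points = 120) {
  el <- function(a, b, c, sdfrac = 0.1, offset_dir = "none", offset = 0)
    list(kind = "ellipsoid",
         semi_axes = rbind(mean = c(a, b, c), sd = c(a, b, c) * sdfrac),
         offset_dir = offset_dir, offset = offset)
  cn <- function(h, rr, sdfrac = 0.1, direction)
    list(kind = "cone", direction = direction,
         height = c(mean = h, sd = h * sdfrac),
         radius = c(mean = rr, sd = rr * sdfrac))
  classes <- list(
    PC = list(
      axon = list(list(kind = "tube")),
      dendrites = list(cn(600, 74.6, 0.1, "apical"),
                       cn(200, 100, 0.1, "basal"))),
    Perisomatic = list(
      axon = list(el(200, 200, 100)),
      dendrites = list(cn(300, 60, 0.1, "apical"),
                       cn(200, 60, 0.1, "basal"))),
    OLM = list(
      axon = list(el(40, 40, 250, 0.1, "apical", 250),
                  el(160, 160, 80, 0.1, "apical", 600)),
      dendrites = list(el(160, 160, 60))),
    IVY = list(
      axon = list(el(220, 220, 150)),
      dendrites = list(el(120, 120, 90))),
    TRI = list(
      axon = list(el(150, 150, 350)),
      dendrites = list(el(110, 110, 110))),
    SCA = list(
      axon = list(el(180, 180, 120, 0.1, "basal", 200)),
      dendrites = list(el(130, 130, 100, 0.1, "apical", 200))),
    PPA = list(
      axon = list(el(250, 250, 140, 0.1, "apical", 150)),
      dendrites = list(cn(220, 60, 0.1, "apical"),
                       cn(150, 50, 0.1, "basal"))),
    NGF = list(
      axon = list(el(250, 250, 180, 0.1, "basal", 400)),
      dendrites = list(el(100, 100, 60))))
  structure(list(scale_factor = scale_factor, point_volume = point_volume,
                 truncation_floor = truncation_floor,
                 axon_sample_points = axon_sample_points,
                 tube = list(radius = 100, back_max = 500, k_back = 0.1,
                             slab_half = 40, points = 220),
                 classes = classes), class = "morphology_params")
}

# draw one dimension from Normal(mean * s, sd * s) truncated at
# floor_frac * mean * s (resampling, clamp after 100 tries)
sample_dim <- function(mean, sd, s, floor_frac) {
  m <- mean * s
  x <- rnorm(1, m, sd * s)
  tries <- 0
  while (x <= floor_frac * m && tries < 100) {
    x <- rnorm(1, m, sd * s)
    tries <- tries + 1
  }
  max(x, floor_frac * m)
}

#' Sample realized shape dimensions for one neuron
#'
#' Every linear dimension of the class recipe is drawn from a normal
#' distribution with the rodent mean and standard deviation scaled by the
#' rodent-to-human factor, truncated at the configured floor so dimensions
#' stay strictly positive.
#'
#' @param class neuron class name.
#' @param params a [default_morphology_params()].
#' @param seed optional seed.
#' @return the class recipe with `height`, `radius` and `semi_axes`
#'   replaced by realized values (and offsets scaled).
#' @export
sample_class_parameters <- function(class, params = default_morphology_params(),
                                    seed = NULL) {
  recipe <- params$classes[[class]]
  if (is.null(recipe)) stop("unknown neuron class: ", class)
  s <- params$scale_factor
  fl <- params$truncation_floor
  with_seed(seed, {
    realize <- function(shape) {
      if (shape$kind == "cone") {
        shape$height <- sample_dim(shape$height[["mean"]],
                                   shape$height[["sd"]], s, fl)
        shape$radius <- sample_dim(shape$radius[["mean"]],
                                   shape$radius[["sd"]], s, fl)
      } else if (shape$kind == "ellipsoid") {
        shape$semi_axes <- vapply(1:3, function(j)
          sample_dim(shape$semi_axes["mean", j], shape$semi_axes["sd", j],
                     s, fl), numeric(1))
        shape$offset <- shape$offset * s
      }
      shape
    }
    list(axon = lapply(recipe$axon, realize),
         dendrites = lapply(recipe$dendrites, realize))
  })
}

# orthonormal orientation matrix with columns (transversal, longitudinal,
# apical), Gram-Schmidt against the apical direction
orientation_matrix <- function(t_hat, normal, apical) {
  a <- apical / max(sqrt(sum(apical^2)), 1e-12)
  t1 <- t_hat - sum(t_hat * a) * a
  t1 <- t1 / max(sqrt(sum(t1^2)), 1e-12)
  n1 <- cross3(a, t1)
  cbind(t1, n1, a)
}

offset_direction <- function(dir, apical, basal) {
  switch(dir,
         none = c(0, 0, 0),
         apical = apical,
         basal = basal,
         stop("unknown offset direction: ", dir))
}

#' Build the morphology cloud of one neuron
#'
#' Assembles the class recipe into an axonal point cloud (convex-hullable)
#' and a dendritic point cloud. Dendritic point counts come from
#' [point_budget()] applied to each realized shape volume; axonal
#' ellipsoids are sampled on their surface, and the pyramidal axon is the
#' surface-following tube of [build_axon_tube()].
#'
#' @param soma 3-vector position.
#' @param gid neuron GID (for error messages).
#' @param class neuron class.
#' @param frame_row list with `apical`, `basal`, `normal`, `t_hat`
#'   3-vectors for this neuron.
#' @param realized realized dimensions from [sample_class_parameters()].
#' @param params a [default_morphology_params()].
#' @param so_surface SO-surface cloud (needed for the pyramidal tube).
#' @param size_scale extra multiplier on all realized linear dimensions
#'   (used by the parameter-perturbation experiments).
#' @param seed optional seed.
#' @return a `morphology_cloud` list: `gid`, `class`, `axon_points`,
#'   `hull` (facet normals/offsets), `axon_box`, `dendrite_points`,
#'   `dend_box`, `budgets`.
#' @export
build_morphology <- function(soma, gid, class, frame_row, realized,
                             params = default_morphology_params(),
                             so_surface = NULL, size_scale = 1,
                             seed = NULL) {
  apical <- frame_row$apical
  basal <- frame_row$basal
  with_seed(seed, {
    axon_pts <- list()
    for (shape in realized$axon) {
      if (shape$kind == "tube") {
        if (is.null(so_surface))
          stop("pyramidal tube requires the SO surface (GID ", gid, ")")
        make_tube <- function(nrm) build_axon_tube(
          soma, nrm, frame_row$t_hat, so_surface,
          r = params$tube$radius * params$scale_factor * size_scale,
          back_max = params$tube$back_max, k_back = params$tube$k_back,
          n_points = params$tube$points, slab_half = params$tube$slab_half)
        # near-landmark somas can get a transversal plane that misses the
        # SO surface; retry in the surface-normal fallback plane
        tube <- tryCatch(make_tube(frame_row$normal), error = function(e) {
          fb <- cross3(frame_row$t_hat, basal)
          fbn <- sqrt(sum(fb^2))
          if (fbn < 1e-9) stop(e)
          make_tube(fb / fbn)
        })
        axon_pts[[length(axon_pts) + 1]] <- tube$points
      } else if (shape$kind == "ellipsoid") {
        ctr <- soma + offset_direction(shape$offset_dir, apical, basal) *
          shape$offset * size_scale
        spec <- ellipsoid_spec(ctr,
                               orientation_matrix(frame_row$t_hat,
                                                  frame_row$normal, apical),
                               shape$semi_axes * size_scale)
        axon_pts[[length(axon_pts) + 1]] <-
          sample_ellipsoid_points(spec, params$axon_sample_points,
                                  mode = "surface")
      } else {
        spec <- cone_spec(soma, soma + apical * shape$height * size_scale,
                          shape$radius * size_scale)
        axon_pts[[length(axon_pts) + 1]] <-
          sample_cone_points(spec, params$axon_sample_points,
                             mode = "surface")
      }
    }
    axon_points <- do.call(rbind, axon_pts)
    hull <- tryCatch(.hull3d_cpp(axon_points),
                     error = function(e)
                       stop("degenerate axonal hull for GID ", gid, ": ",
                            conditionMessage(e)))
    dend_pts <- list()
    budgets <- integer(0)
    for (shape in realized$dendrites) {
      if (shape$kind == "cone") {
        dirv <- if (identical(shape$direction, "basal")) basal else apical
        spec <- cone_spec(soma, soma + dirv * shape$height * size_scale,
                          shape$radius * size_scale)
        nb <- point_budget(cone_volume(spec), params$point_volume)
        dend_pts[[length(dend_pts) + 1]] <-
          sample_cone_points(spec, nb, mode = "volume")
      } else {
        ctr <- soma + offset_direction(shape$offset_dir, apical, basal) *
          shape$offset * size_scale
        spec <- ellipsoid_spec(ctr,
                               orientation_matrix(frame_row$t_hat,
                                                  frame_row$normal, apical),
                               shape$semi_axes * size_scale)
        nb <- point_budget(ellipsoid_volume(spec), params$point_volume)
        dend_pts[[length(dend_pts) + 1]] <-
          sample_ellipsoid_points(spec, nb, mode = "volume")
      }
      budgets <- c(budgets, nb)
    }
    dendrite_points <- do.call(rbind, dend_pts)
    structure(list(gid = gid, class = class, axon_points = axon_points,
                   hull = hull, axon_box = bounding_box(axon_points),
                   dendrite_points = dendrite_points,
                   dend_box = bounding_box(dendrite_points),
                   budgets = budgets), class = "morphology_cloud")
  })
}

#' Build morphology clouds for a whole placement
#'
#' @param placement placement data frame with assigned classes.
#' @param landmarks landmark list (see [geometry_landmarks()]).
#' @param params a [default_morphology_params()].
#' @param seed master seed; generation is reproducible bit-for-bit.
#' @param size_scale multiplier on all linear shape dimensions (0.5 and 2
#'   reproduce the halved/doubled perturbation experiments).
#' @return list of `morphology_cloud` objects, one per neuron, in
#'   placement order.
#' @export
build_morphologies <- function(placement, landmarks,
                               params = default_morphology_params(),
                               seed = 1, size_scale = 1) {
  if (anyNA(placement$class))
    stop("placement has unassigned classes")
  frames <- orient_frames(placement, landmarks)
  n <- nrow(placement)
  out <- vector("list", n)
  # per-neuron seeds decouple dimension sampling from point sampling, so
  # realized shape dimensions are identical across size_scale settings
  base <- as.integer(seed) %% 1073741789L
  for (i in seq_len(n)) {
    si <- (base * 2L + 7919L * i) %% 2147483587L
    frame_row <- list(apical = frames$apical[i, ],
                      basal = frames$basal[i, ],
                      normal = frames$normal[i, ],
                      t_hat = frames$t_hat[i, ])
    realized <- sample_class_parameters(placement$class[i], params,
                                        seed = si)
    out[[i]] <- build_morphology(
      soma = as.numeric(placement[i, c("x", "y", "z")]),
      gid = placement$gid[i], class = placement$class[i],
      frame_row = frame_row, realized = realized, params = params,
      so_surface = landmarks$so, size_scale = size_scale,
      seed = (si + 1L) %% 2147483587L)
  }
  out
}
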
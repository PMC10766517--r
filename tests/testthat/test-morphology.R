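test_that("point budget follows the one-point-per-voxel rule", {
  expect_equal(point_budget(11780000, 64000), 184)
  expect_equal(point_budget(64000, 64000), 1)
  expect_equal(point_budget(640000, 64000), 10)
  expect_equal(point_budget(100, 64000), 1)  # floor of one point
  # doubling linear dimensions multiplies the budget by ~8
  v <- 5.3e6
  expect_lte(abs(point_budget(8 * v, 64000) - 8 * point_budget(v, 64000)), 7)
})

test_that("cone samples satisfy the analytic containment and moments", {
  spec <- cone_spec(c(0, 0, 0), c(0, 0, 100), 50)
  for (mode in c("volume", "surface")) {
    p <- sample_cone_points(spec, 10000, seed = 1, mode = mode)
    expect_true(all(p[, 3] >= -1e-9 & p[, 3] <= 100 + 1e-9))
    expect_true(all(sqrt(p[, 1]^2 + p[, 2]^2) <= 0.5 * p[, 3] + 1e-6))
  }
  # surface points sit exactly on the lateral surface
  ps <- sample_cone_points(spec, 2000, seed = 2, mode = "surface")
  expect_equal(sqrt(ps[, 1]^2 + ps[, 2]^2), 0.5 * ps[, 3],
               tolerance = 1e-9)
  # h = 0 is the apex exactly
  apex <- sample_cone_points(spec, 5, seed = 3, mode = "surface", h = 0)
  expect_equal(apex, matrix(0, 5, 3))

  # solid-cone centroid at 3H/4 from the apex
  n <- 1e5
  pv <- sample_cone_points(spec, n, seed = 4, mode = "volume")
  sd_mean <- 100 * sqrt(3 / 80) / sqrt(n)
  expect_lt(abs(mean(pv[, 3]) - 75), 3 * sd_mean)

  # oblique cone stays inside its own geometry
  spec2 <- cone_spec(c(10, -5, 3), c(110, 95, 53), 40)
  p2 <- sample_cone_points(spec2, 5000, seed = 5)
  ax <- spec2$d / spec2$H
  rel <- sweep(p2, 2, spec2$O)
  h <- rel %*% ax
  radial <- sqrt(rowSums((rel - h %*% t(ax))^2))
  expect_true(all(h >= -1e-9 & h <= spec2$H + 1e-9))
  expect_true(all(radial <= 40 * h / spec2$H + 1e-6))

  expect_error(cone_spec(c(0, 0, 0), c(0, 0, 0), 10), "degenerate")
})

test_that("ellipsoid samples satisfy the quadratic-form containment", {
  # sphere case: all surface points at distance r
  sp <- ellipsoid_spec(c(1, 2, 3), diag(3), c(40, 40, 40))
  ps <- sample_ellipsoid_points(sp, 3000, seed = 1, mode = "surface")
  expect_equal(sqrt(rowSums(sweep(ps, 2, c(1, 2, 3))^2)),
               rep(40, 3000), tolerance = 1e-9)

  # rotated anisotropic ellipsoid
  th <- 0.7
  U <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  lam <- c(150, 80, 50)
  spec <- ellipsoid_spec(c(5, -3, 9), U, lam)
  for (mode in c("volume", "surface")) {
    p <- sample_ellipsoid_points(spec, 20000, seed = 2, mode = mode)
    w <- sweep(p, 2, spec$center) %*% spec$U
    q <- sqrt(rowSums(sweep(w, 2, lam, "/")^2))
    if (mode == "surface") {
      expect_equal(q, rep(1, nrow(p)), tolerance = 1e-6)
    } else {
      expect_true(all(q <= 1 + 1e-9))
    }
  }

  # second moments of the uniform solid: U diag(lambda^2/5) U^T
  n <- 1e5
  pv <- sample_ellipsoid_points(spec, n, seed = 3, mode = "volume")
  S <- stats::cov(pv)
  target <- U %*% diag(lam^2 / 5) %*% t(U)
  # 3 sigma of the moment estimate (var of w^2 for uniform ball = 4/175)
  tol3 <- 3 * sqrt(4 / 175) * max(lam)^2 / sqrt(n)
  expect_lt(max(abs(S - target)), tol3)

  expect_error(ellipsoid_spec(c(0, 0, 0), matrix(1, 3, 3), c(1, 1, 1)),
               "orthonormal")
  expect_error(ellipsoid_spec(c(0, 0, 0), diag(3), c(1, -1, 1)), "positive")
})

test_that("orientation frames follow the landmark geometry", {
  # orthogonal landmark vectors: plane normal is their cross product
  pl <- data.frame(gid = 1L, x = 0, y = 0, z = 0)
  lmk <- list(so = matrix(c(0, 0, -7), 1), sr = matrix(c(0, 0, 9), 1),
              ca2 = matrix(c(10, 0, 0), 1), sub = matrix(c(0, 5, 0), 1))
  fr <- orient_frames(pl, lmk)
  expect_equal(abs(as.numeric(fr$normal)), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(fr$apical), c(0, 0, 1))
  expect_equal(as.numeric(fr$basal), c(0, 0, -1))

  # apical always points at the nearest SR vertex
  geom <- tiny_geom()
  pls <- make_toy_placement(geom, 200, seed = 3, config = NULL)
  lm <- geometry_landmarks(geom)
  fr2 <- suppressWarnings(orient_frames(pls, lm))
  d <- landmark_distances(pls, lm["sr"])$sr
  expect_true(all(rowSums(fr2$apical * d$direction) > 1 - 1e-9))

  # flat geometry, grid-aligned somas in the SP: apical is the sheet normal
  fgeom <- flat_geom()
  flm <- geometry_landmarks(fgeom)
  somas <- data.frame(gid = 1:3, x = c(500, 750, 1000),
                      y = c(250, 500, 750), z = 300)
  fr3 <- suppressWarnings(orient_frames(somas, flm))
  expect_equal(fr3$apical, matrix(rep(c(0, 0, 1), each = 3), 3),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("axonal tubes follow the SO surface within their radius", {
  geom <- flat_geom()
  soma <- c(1000, 600, 300)
  tube <- build_axon_tube(soma, normal = c(1, 0, 0), t_hat = c(0, 1, 0),
                          geom$so_surface, r = 150, n_points = 500,
                          seed = 1)
  cl <- tube$spec$centerline
  # flat limit: straight centreline on the SO plane
  expect_lt(max(abs(cl[, 3] - cl[1, 3])), 1e-3)
  expect_lt(max(abs(cl[, 1] - cl[1, 1])), 1e-3)
  # every tube point within r of the centreline (cylinder in the flat case)
  d_axis <- sqrt((tube$points[, 1] - cl[1, 1])^2 +
                 (tube$points[, 3] - cl[1, 3])^2)
  expect_true(all(d_axis <= 150 + 1e-6))
  # runs from the truncation point to the subiculum side
  expect_lt(max(tube$points[, 2]), 1200 + 150 + 1e-6)
  expect_equal(tube$spec$radius, 150)

  # back extent is capped at 500 um even with an aggressive gain
  tube2 <- build_axon_tube(c(1000, 1100, 300), c(1, 0, 0), c(0, 1, 0),
                           geom$so_surface, r = 150, k_back = 1,
                           n_points = 50, seed = 2)
  expect_lte(tube2$spec$back_extent, 500)

  # curved surface: all points within r of the curved centreline
  cgeom <- tiny_geom()
  fr <- suppressWarnings(orient_frames(
    data.frame(gid = 1, x = 1000, y = 600,
               z = geometry_z(cgeom, 1000, 600, 0.4)),
    geometry_landmarks(cgeom)))
  tube3 <- build_axon_tube(c(1000, 600, geometry_z(cgeom, 1000, 600, 0.4)),
                           as.numeric(fr$normal), as.numeric(fr$t_hat),
                           cgeom$so_surface, r = 150, n_points = 400,
                           seed = 3)
  cl3 <- tube3$spec$centerline
  dmin <- vapply(seq_len(nrow(tube3$points)), function(i) {
    min(sqrt(colSums((t(cl3) - tube3$points[i, ])^2)))
  }, numeric(1))
  # segment sampling means distance to the vertex set slightly exceeds the
  # distance to the polyline; allow half a resampling step
  expect_true(all(dmin <= 150 + 13))

  expect_error(build_axon_tube(c(0, 0, 1e6), c(1, 0, 0), c(0, 1, 0),
                               geom$so_surface[1:2, ], r = 10),
               "sparse")
})

test_that("class parameter sampling scales, truncates and reproduces", {
  params <- default_morphology_params()
  # zero-sd recipe realizes exactly mean * 1.5
  p0 <- default_morphology_params()
  p0$classes$IVY$axon[[1]]$semi_axes["sd", ] <- 0
  r0 <- sample_class_parameters("IVY", p0, seed = 1)
  expect_equal(r0$axon[[1]]$semi_axes,
               p0$classes$IVY$axon[[1]]$semi_axes["mean", ] * 1.5)

  # sample mean within 3 sigma of 1.5 * mean
  hs <- replicate(3000, sample_class_parameters("PC", params)$dendrites[[1]]$height)
  m <- params$classes$PC$dendrites[[1]]$height[["mean"]] * 1.5
  s <- params$classes$PC$dendrites[[1]]$height[["sd"]] * 1.5
  expect_lt(abs(mean(hs) - m), 3 * s / sqrt(3000))

  # dimensions never drop to the floor or below zero
  pwide <- default_morphology_params()
  pwide$classes$NGF$dendrites[[1]]$semi_axes["sd", ] <- 200
  for (sd_seed in 1:20) {
    r <- sample_class_parameters("NGF", pwide, seed = sd_seed)
    expect_true(all(r$dendrites[[1]]$semi_axes > 0))
  }

  expect_identical(sample_class_parameters("OLM", params, seed = 7),
                   sample_class_parameters("OLM", params, seed = 7))
  expect_error(sample_class_parameters("nope", params), "unknown")
})

test_that("morphology assembly follows the class recipes", {
  geom <- tiny_geom()
  lm <- geometry_landmarks(geom)
  pl <- make_toy_placement(geom, 60, seed = 21, config = NULL)
  pl$class <- rep(scaffold_classes(), length.out = 60)
  morph <- suppressWarnings(build_morphologies(pl, lm, seed = 5))

  params <- default_morphology_params()
  for (i in seq_along(morph)) {
    m <- morph[[i]]
    expect_s3_class(m, "morphology_cloud")
    # dendritic point count equals the summed per-shape budgets
    expect_equal(nrow(m$dendrite_points), sum(m$budgets))
    expect_equal(length(m$budgets),
                 length(params$classes[[m$class]]$dendrites))
    expect_gte(nrow(m$hull$normals), 4)
  }
  # PC: tube axon (many more points than an ellipsoid surface sample)
  pc <- morph[[which(pl$class == "PC")[1]]]
  expect_equal(nrow(pc$axon_points), params$tube$points)
  # Perisomatic: one ellipsoid axon, two cone dendrites
  peri_idx <- which(pl$class == "Perisomatic")
  if (length(peri_idx)) {
    pe <- morph[[peri_idx[1]]]
    expect_equal(nrow(pe$axon_points), params$axon_sample_points)
    expect_length(pe$budgets, 2)
  }

  # reproducible bit-for-bit
  morph2 <- suppressWarnings(build_morphologies(pl, lm, seed = 5))
  expect_identical(morph, morph2)

  # doubling the linear scale multiplies dendritic budgets by ~8
  m1 <- suppressWarnings(build_morphologies(pl[1:5, ], lm, seed = 6,
                                            size_scale = 1))
  m8 <- suppressWarnings(build_morphologies(pl[1:5, ], lm, seed = 6,
                                            size_scale = 2))
  for (i in 1:5) {
    expect_lt(abs(sum(m8[[i]]$budgets) / sum(m1[[i]]$budgets) - 8), 1)
  }
})
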
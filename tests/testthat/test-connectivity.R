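test_that("bounding boxes and the closed-interval overlap rule", {
  b1 <- bounding_box(matrix(c(3, 4, 5), 1))
  expect_equal(unname(b1), c(3, 3, 4, 4, 5, 5))

  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(unname(bounding_box(cube)), c(0, 1, 0, 1, 0, 1))
  expect_error(bounding_box(cube[0, ]), "empty")

  set.seed(3)
  for (i in 1:10) {
    pts <- matrix(rnorm(60), ncol = 3)
    bb <- bounding_box(pts)
    expect_true(all(pts[, 1] >= bb["x_min"] & pts[, 1] <= bb["x_max"]))
    expect_true(all(pts[, 3] >= bb["z_min"] & pts[, 3] <= bb["z_max"]))
  }

  a <- bounding_box(cube)
  expect_true(boxes_overlap(a, a))
  # sharing exactly one face still counts (>= in the 1D rule)
  b <- bounding_box(cube + cbind(rep(1, 8), 0, 0))
  expect_true(boxes_overlap(a, b))
  # separation by 1 um on one axis does not
  cc <- bounding_box(cube + cbind(rep(2, 8), 0, 0))
  expect_false(boxes_overlap(a, cc))
})

test_that("convex hull facets agree with the quadratic-programming
           membership oracle", {
  skip_if_not_installed("quadprog")
  set.seed(11)
  for (rep in 1:5) {
    cloud <- matrix(rnorm(150, sd = 50), ncol = 3)
    hull <- ca1scaffold:::.hull3d_cpp(cloud)
    queries <- rbind(matrix(rnorm(150, sd = 50), ncol = 3),
                     cloud[1:10, ])  # include exact hull input points
    inside <- as.logical(
      ca1scaffold:::.points_in_hull_cpp(hull$normals, hull$offsets,
                                        queries, 1e-7))
    for (i in seq_len(nrow(queries))) {
      d <- hull_distance_qp(cloud, queries[i, ])
      if (d < 1e-6) expect_true(inside[i])
      if (d > 1e-4) expect_false(inside[i])
    }
  }
  # all original cloud points are inside their own hull (closed inclusion)
  cloud <- matrix(runif(300, -10, 10), ncol = 3)
  hull <- ca1scaffold:::.hull3d_cpp(cloud)
  expect_true(all(ca1scaffold:::.points_in_hull_cpp(
    hull$normals, hull$offsets, cloud, 1e-7)))
  expect_error(ca1scaffold:::.hull3d_cpp(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

# minimal hand-built morphology: tetrahedral axon, explicit dendrite points
fake_morph <- function(gid, class, axon, dend) {
  structure(list(gid = gid, class = class, axon_points = axon,
                 hull = ca1scaffold:::.hull3d_cpp(axon),
                 axon_box = bounding_box(axon),
                 dendrite_points = dend, dend_box = bounding_box(dend),
                 budgets = nrow(dend)), class = "morphology_cloud")
}

test_that("candidate pairs: hull inclusion with lossless box prefilter", {
  tet <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 100))
  m1 <- fake_morph(1L, "PC", tet, matrix(c(2000, 2000, 2000), 1))
  # dendrite point exactly on a hull vertex: included (closed contract)
  m2 <- fake_morph(2L, "PC", tet + 500, rbind(c(100, 0, 0), c(900, 0, 0)))
  m3 <- fake_morph(3L, "PC", tet - 500, matrix(c(20, 20, 20), 1))
  cs <- find_candidate_pairs(list(m1, m2, m3))
  expect_true(any(cs$pre_gid == 1 & cs$post_gid == 2))
  expect_true(any(cs$pre_gid == 1 & cs$post_gid == 3))
  # m1's dendrite at (2000,2000,2000) is in nobody's hull
  expect_false(any(cs$post_gid == 1))
  # axon hull containing no dendrite point of anyone: no outgoing pairs
  expect_false(any(cs$pre_gid == 3))

  # oracle equivalence on a random fixture: prefilter on == brute force off
  geom <- tiny_geom()
  pl <- make_toy_placement(geom, 80, seed = 31, config = NULL)
  pl$class <- rep(scaffold_classes(), length.out = 80)
  lm <- geometry_landmarks(geom)
  morph <- suppressWarnings(build_morphologies(pl, lm, seed = 32))
  withf <- find_candidate_pairs(morph, prefilter = TRUE)
  without <- find_candidate_pairs(morph, prefilter = FALSE)
  expect_identical(withf$pre_gid, without$pre_gid)
  expect_identical(withf$post_gid, without$post_gid)
  # no self connections, canonical ordering, no duplicates
  expect_false(any(withf$pre_gid == withf$post_gid))
  expect_false(anyDuplicated(withf[, c("pre_gid", "post_gid")]) > 0)
})

test_that("pruning hits class-pair targets exactly and clamps shortfalls", {
  set.seed(5)
  cand <- data.frame(pre_gid = 1:100, post_gid = 101:200,
                     pre_class = "PC", post_class = "PC",
                     stringsAsFactors = FALSE)
  cand <- ca1scaffold:::connection_set(cand$pre_gid, cand$post_gid,
                                       cand$pre_class, cand$post_class,
                                       "candidate")
  tbl <- data.frame(pre_class = "PC", post_class = "PC", p = 0.05)
  # round(0.05 * 20 * 30) = 30 pairs kept
  out <- prune_pairs(cand, tbl, c(PC = 20), seed = 1)
  out <- prune_pairs(cand, tbl, c(PC = 0), seed = 1)  # p*0 -> empty
  expect_equal(nrow(out), 0)
  sizes <- c(PC = 20)
  tbl2 <- data.frame(pre_class = "PC", post_class = "PC", p = 0.05)
  # emulate N_pre = 20, N_post = 30 via asymmetric classes
  cand2 <- ca1scaffold:::connection_set(1:100, 101:200, "PC", "OLM",
                                        "candidate")
  tbl3 <- data.frame(pre_class = "PC", post_class = "OLM", p = 0.05)
  out3 <- prune_pairs(cand2, tbl3, c(PC = 20, OLM = 30), seed = 2)
  expect_equal(nrow(out3), 30)
  expect_true(all(paste(out3$pre_gid, out3$post_gid) %in%
                  paste(cand2$pre_gid, cand2$post_gid)))

  # p = 1 with more target than candidates: clamp, shortfall logged
  cand40 <- ca1scaffold:::connection_set(1:40, 61:100, "PC", "OLM",
                                         "candidate")
  expect_message(
    out4 <- prune_pairs(cand40, data.frame(pre_class = "PC",
                                           post_class = "OLM", p = 1),
                        c(PC = 10, OLM = 10), seed = 3),
    "shortfall 60")
  expect_equal(nrow(out4), 40)
  expect_equal(unname(attr(out4, "shortfall")["PC__OLM"]), 60L)

  expect_error(prune_pairs(cand40, data.frame(pre_class = "PC",
                                              post_class = "OLM", p = -0.1),
                           c(PC = 10, OLM = 10)),
               "\\[0, 1\\]")

  # p = 0: empty
  out0 <- prune_pairs(cand40, data.frame(pre_class = "PC",
                                         post_class = "OLM", p = 0),
                      c(PC = 10, OLM = 10), seed = 4)
  expect_equal(nrow(out0), 0)

  # determinism
  o1 <- prune_pairs(cand2, tbl3, c(PC = 20, OLM = 30), seed = 9)
  o2 <- prune_pairs(cand2, tbl3, c(PC = 20, OLM = 30), seed = 9)
  expect_identical(o1, o2)
})

test_that("random baseline has exact counts, no self loops, binomial
           degrees", {
  pl <- data.frame(gid = 1:3000, x = runif(3000), y = runif(3000),
                   z = runif(3000), class = "PC")
  expect_equal(nrow(random_baseline(pl, 0, seed = 1)), 0)
  for (sd_seed in 1:3) {
    b <- random_baseline(pl, 5000, seed = sd_seed)
    expect_equal(nrow(b), 5000)
    expect_false(any(b$pre_gid == b$post_gid))
    expect_false(anyDuplicated(b[, c("pre_gid", "post_gid")]) > 0)
  }
  expect_error(random_baseline(pl[1:3, ], 100), "distinct directed")

  # outdegree follows Binomial(N-1, p): chi-squared goodness of fit
  b <- random_baseline(pl, 30000, seed = 7)
  outd <- degree_counts(b, pl)$outdegree
  p <- 30000 / (3000 * 2999)
  br <- c(-0.5, 4.5, 6.5, 8.5, 10.5, 12.5, 14.5, Inf)
  obs <- table(cut(outd, br))
  pr <- diff(stats::pbinom(br, 2999, p))
  chi <- suppressWarnings(stats::chisq.test(as.integer(obs), p = pr,
                                            rescale.p = TRUE))
  expect_gt(chi$p.value, 0.001)
})
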
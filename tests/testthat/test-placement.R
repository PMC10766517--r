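test_that("population split follows the inhibitory ratio arithmetic", {
  s <- population_split(110, 0.10)
  expect_equal(s$n_exc, 100)
  expect_equal(s$n_inh, 10)
  # full-scale CA1 numbers
  s2 <- population_split(5280000, 0.10)
  expect_equal(s2$n_exc, 4800000)
  expect_equal(s2$n_inh, 480000)
})

test_that("pruning subsamples uniformly and preserves marginals", {
  geom <- tiny_geom()
  somas <- make_toy_placement(geom, 30000, seed = 2,
                              config = NULL)[, c("gid", "x", "y", "z")]
  pl <- prune_to_population(somas, 10000, seed = 3)
  expect_equal(nrow(pl), 10000)
  expect_true(all(pl$gid %in% somas$gid))
  expect_equal(sum(pl$type == "exc"), round(10000 / 1.1))
  expect_identical(pl, prune_to_population(somas, 10000, seed = 3))
  expect_error(prune_to_population(somas, 40000), "exceeds")

  # Kolmogorov-Smirnov distance of each coordinate marginal below the
  # two-sample bound at alpha ~ 0.001
  for (cc in c("x", "y", "z")) {
    ks <- suppressWarnings(stats::ks.test(pl[[cc]], somas[[cc]]))$statistic
    bound <- 1.95 * sqrt((30000 + 10000) / (30000 * 10000))
    expect_lt(as.numeric(ks), bound)
  }
})

test_that("two-sheet surfaces split into deep and superficial sides", {
  geom <- flat_geom()
  surf <- rbind(geom$so_surface, geom$sr_surface)
  truth_deep <- rep(c(TRUE, FALSE), each = nrow(geom$so_surface))
  sides <- split_ca1_sides(surf, gap = 40)
  expect_identical(sides$deep, truth_deep)
  # partition: every vertex on exactly one side
  expect_equal(length(sides$deep), nrow(surf))

  # seeds swap labels consistently
  lo <- geom$so_surface[1, ] + c(0, 0, -10)
  hi <- geom$sr_surface[1, ] + c(0, 0, 10)
  s1 <- split_ca1_sides(surf, 40, deep_seed = lo, superficial_seed = hi)
  s2 <- split_ca1_sides(surf, 40, deep_seed = hi, superficial_seed = lo)
  expect_identical(s1$deep, !s2$deep)

  # a gap exceeding the sheet offset merges the sheets: not separable
  expect_error(split_ca1_sides(surf, gap = 600), "not separable")
})

test_that("landmark distances match the brute-force scan", {
  set.seed(5)
  cloud <- matrix(runif(3000, 0, 1000), ncol = 3)
  pos <- matrix(runif(300, 0, 1000), ncol = 3)
  ld <- landmark_distances(pos, list(a = cloud))$a
  ref <- nn_brute(pos, cloud)
  expect_equal(ld$index, as.integer(ref[, 1]))
  expect_equal(ld$distance, ref[, 2], tolerance = 1e-9)

  # coincident soma: distance zero
  ld0 <- landmark_distances(cloud[5, , drop = FALSE], list(a = cloud))$a
  expect_equal(ld0$distance, 0)

  # flat landmark plane below the soma
  plane <- as.matrix(expand.grid(x = seq(0, 500, 10), y = seq(0, 500, 10)))
  plane <- cbind(plane, z = 0)
  ld2 <- landmark_distances(matrix(c(250, 250, 250), 1), list(p = plane))$p
  expect_equal(ld2$distance, 250)
  expect_equal(as.numeric(ld2$direction), c(0, 0, -1))
})

test_that("interneuron classes follow the landmark rules", {
  geom <- tiny_geom()
  lm <- geometry_landmarks(geom)
  pl <- make_toy_placement(geom, 3000, seed = 6, config = NULL)
  split <- population_split(3000, 0.10)
  set.seed(1)
  pl$type <- "exc"
  pl$type[sample.int(3000, split$n_inh)] <- "inh"
  pl$class <- ifelse(pl$type == "exc", "PC", NA)

  cfg <- class_config()
  out <- assign_interneuron_classes(pl, lm, cfg, seed = 4)
  inh <- out[out$type == "inh", ]
  expect_false(anyNA(out$class))
  counts <- table(factor(inh$class, levels = interneuron_classes()))
  expect_equal(sum(counts), split$n_inh)
  # quotas: largest-remainder rounding of the proportions
  expect_true(max(abs(as.integer(counts) -
                      split$n_inh * cfg$proportions)) <= 1)

  # every OLM soma is nearer the SO surface than the SR surface
  olm <- inh[inh$class == "OLM", ]
  expect_true(all(olm$d_so < olm$d_sr))

  # SCA/PPA/NGF displaced SLM-ward by gain * d_sr; NGF shift largest for
  # equal SR-border distance (gain strictly larger)
  before <- pl[match(inh$gid, pl$gid), c("x", "y", "z")]
  shift <- unname(sqrt(rowSums((inh[, c("x", "y", "z")] - before)^2)))
  for (cls in c("SCA", "PPA", "NGF")) {
    rows <- inh$class == cls
    expected <- pmin(cfg$shift_gains[[cls]] * inh$d_sr[rows],
                     inh$d_slm[rows])
    expect_equal(shift[rows], unname(expected), tolerance = 1e-9)
  }
  expect_equal(shift[!inh$class %in% c("SCA", "PPA", "NGF")],
               rep(0, sum(!inh$class %in% c("SCA", "PPA", "NGF"))))
  expect_gt(cfg$shift_gains[["NGF"]], cfg$shift_gains[["SCA"]])

  # determinism
  expect_identical(out, assign_interneuron_classes(pl, lm, cfg, seed = 4))
})

test_that("infeasible class quotas are rejected with counts", {
  geom <- tiny_geom()
  lm <- geometry_landmarks(geom)
  # all somas on the SR side: SO-side classes cannot be filled
  pl <- make_toy_placement(geom, 200, seed = 6,
                          profile = density_profile(
                            stratum_weights = c(so = 0, sp = 0, sr = 1,
                                                slm = 0)),
                          config = NULL)
  pl$type <- c(rep("exc", 150), rep("inh", 50))
  pl$class <- ifelse(pl$type == "exc", "PC", NA)
  expect_error(assign_interneuron_classes(pl, lm, seed = 1),
               "exceeds its side subgroup")

  expect_error(class_config(proportions = c(Perisomatic = 1, OLM = 0.5,
                                            IVY = 0, TRI = 0, SCA = 0,
                                            PPA = 0, NGF = 0)),
               "sum to 1")
  expect_error(class_config(shift_gains = c(SCA = 1, PPA = 1, NGF = 1)),
               "strictly the largest")
})

test_that("a pure Perisomatic configuration labels every interneuron", {
  geom <- tiny_geom()
  lm <- geometry_landmarks(geom)
  pl <- make_toy_placement(geom, 400, seed = 17, config = NULL)
  pl$type <- c(rep("exc", 360), rep("inh", 40))
  pl$class <- ifelse(pl$type == "exc", "PC", NA)
  cfg <- class_config(proportions = c(Perisomatic = 1, OLM = 0, IVY = 0,
                                      TRI = 0, SCA = 0, PPA = 0, NGF = 0))
  out <- assign_interneuron_classes(pl, lm, cfg, seed = 2)
  expect_true(all(out$class[out$type == "inh"] == "Perisomatic"))
})
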
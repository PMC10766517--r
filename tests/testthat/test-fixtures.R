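test_that("degenerate amplitude gives a flat, coplanar SO sheet", {
  geom <- flat_geom()
  expect_true(all(geom$so_surface[, 3] == geom$so_surface[1, 3]))
  expect_true(all(geom$slm_surface[, 3] - geom$so_surface[, 3] == 900))
})

test_that("surface heights match the generator's closed form", {
  geom <- make_mini_ca1_landmarks(length_um = 4000, width_um = 2000,
                                  thickness_um = 1200,
                                  gyrification_amplitude = 200,
                                  gyrification_wavelength = 2000,
                                  bend_depth = 500)
  s <- geom$so_surface
  expected <- sheet_z(s[, 1], s[, 2], 0, W = 2000, thickness = 1200,
                      A = 200, lambda = 2000, bend = 500)
  expect_equal(s[, 3], expected, tolerance = 1e-12)
  r <- geom$sr_surface
  expect_equal(r[, 3],
               sheet_z(r[, 1], r[, 2], geom$sr_frac, 2000, 1200, 200,
                       2000, 500),
               tolerance = 1e-12)
})

test_that("geometry generation and rejection of bad parameters", {
  expect_error(make_mini_ca1_landmarks(length_um = -5), "positive")
  expect_error(make_mini_ca1_landmarks(gyrification_wavelength = 0),
               "positive")
  geom <- tiny_geom()
  # sr strictly between so and slm everywhere; landmark patches disjoint
  expect_true(all(geom$sr_surface[, 3] > geom$so_surface[, 3]))
  expect_true(all(geom$sr_surface[, 3] < geom$slm_surface[, 3]))
  expect_true(all(geom$ca2_patch[, 2] == 0))
  expect_true(all(geom$sub_patch[, 2] == 1200))
})

test_that("toy placement stays inside the sheet and respects the profile", {
  geom <- tiny_geom()
  pl <- make_toy_placement(geom, 1000, seed = 3)
  z_lo <- geometry_z(geom, pl$x, pl$y, 0)
  z_hi <- geometry_z(geom, pl$x, pl$y, 1)
  expect_true(all(pl$z >= z_lo - 1e-9 & pl$z <= z_hi + 1e-9))
  expect_true(all(pl$x >= 0 & pl$x <= 2000))
  expect_true(all(pl$class %in% scaffold_classes()))

  # SR weight 3x SO weight: count ratio within 3 sigma of 3
  prof <- density_profile(stratum_weights = c(so = 0.25, sp = 0, sr = 0.75,
                                              slm = 0),
                          sp_gradient = 1, longitudinal_ramp = 1)
  n <- 30000
  pl2 <- make_toy_placement(geom, n, prof, seed = 5, config = NULL)
  t_frac <- (pl2$z - geometry_z(geom, pl2$x, pl2$y, 0)) / 900
  in_sr <- t_frac >= geom$sr_frac & t_frac < geom$slm_frac
  in_so <- t_frac < geom$so_frac
  # binomial bound on the SR count at p = 0.75
  p_hat <- sum(in_sr) / n
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  expect_equal(sum(in_sr) + sum(in_so), n)
})

test_that("single-soma placement and error paths", {
  geom <- tiny_geom()
  pl <- make_toy_placement(geom, 1, seed = 1)
  expect_equal(nrow(pl), 1)
  expect_true(pl$class %in% scaffold_classes())
  expect_error(density_profile(stratum_weights = c(-1, 1, 1, 1)), ">= 0")
  expect_error(make_toy_placement(geom, 0), ">= 1")
})

test_that("placement generation is deterministic under a fixed seed", {
  geom <- tiny_geom()
  a <- make_toy_placement(geom, 500, seed = 42)
  b <- make_toy_placement(geom, 500, seed = 42)
  expect_identical(a, b)
  g2 <- tiny_geom()
  expect_identical(geom, g2)
})

test_that("rendering follows the pixel convention and is deterministic", {
  pl <- data.frame(gid = 1L, x = 100, y = 60, z = 140)
  img <- make_imaging_params(noise_sd = 0)
  st <- render_synthetic_stack(pl, img)
  expect_equal(st$truth$col, 5)
  expect_equal(st$truth$row, 3)
  expect_equal(st$truth$slice, 7)
  expect_equal(st$stack[3 + 1, 5 + 1, 7 + 1], img$soma_intensity)

  # well-separated somas give exactly that many foreground pixels
  pl10 <- data.frame(gid = 1:10, x = seq(100, 1000, by = 100),
                     y = seq(100, 1000, by = 100), z = 100)
  st10 <- render_synthetic_stack(pl10, img)
  expect_equal(sum(st10$stack == img$soma_intensity), 10)

  # identical seed, identical noise
  imgn <- make_imaging_params(noise_sd = 15)
  s1 <- render_synthetic_stack(pl10, imgn, seed = 9)
  s2 <- render_synthetic_stack(pl10, imgn, seed = 9)
  expect_identical(s1$stack, s2$stack)

  expect_error(
    render_synthetic_stack(pl10, img, dims = c(5, 5, 5)),
    "GID 1")
})

test_that("zero-noise render/segment round trip recovers the ground truth", {
  geom <- tiny_geom()
  pl <- make_toy_placement(geom, 500, seed = 8)
  img <- make_imaging_params(noise_sd = 0)
  st <- render_synthetic_stack(pl, img)
  somas <- suppressWarnings(segment_stack(st$stack, img))
  truth_keys <- unique(with(st$truth, paste(row, col, slice)))
  got_keys <- with(somas, paste(round(y / 20), round(x / 20),
                                round(z / 20)))
  recall <- mean(truth_keys %in% got_keys)
  expect_gte(recall, 0.99)
  expect_true(all(got_keys %in% truth_keys))  # zero false positives
})
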
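# small geometries used across tests
tiny_geom <- function(...) {
  make_mini_ca1_landmarks(length_um = 2000, width_um = 1200,
                          thickness_um = 900, gyrification_amplitude = 100,
                          gyrification_wavelength = 1000, bend_depth = 200,
                          grid_spacing = 25, ...)
}

flat_geom <- function(...) {
  make_mini_ca1_landmarks(length_um = 2000, width_um = 1200,
                          thickness_um = 900, gyrification_amplitude = 0,
                          bend_depth = 0, grid_spacing = 25, ...)
}

# independent closed form of the fixture sheet (kept in sync with the
# documented generator contract, evaluated independently of geometry_z)
sheet_z <- function(x, y, t, W, thickness, A, lambda, bend) {
  bend * (2 * y / W - 1)^2 + A * (1 + sin(2 * pi * x / lambda)) +
    t * thickness
}

# brute-force Otsu: scan all 255 cuts, between-class variance from raw
# pixels (no histogram shortcuts)
otsu_brute <- function(pixels) {
  v <- as.integer(round(pmin(pmax(as.vector(pixels), 0), 255)))
  best <- -1
  best_t <- NA_integer_
  n <- length(v)
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# independent point-in-convex-hull oracle: distance from p to the convex
# combination of the cloud, by quadratic programming
hull_distance_qp <- function(cloud, p) {
  X <- as.matrix(cloud)
  n <- nrow(X)
  D <- X %*% t(X) + diag(1e-9, n)
  d <- as.numeric(X %*% p)
  A <- cbind(rep(1, n), diag(n))
  sol <- quadprog::solve.QP(D, d, A, c(1, rep(0, n)), meq = 1)
  lam <- sol$solution
  sqrt(max(sum((as.numeric(t(X) %*% lam) - p)^2), 0))
}

# brute-force nearest neighbour
nn_brute <- function(query, cloud) {
  t(apply(query, 1, function(q) {
    d2 <- colSums((t(cloud) - q)^2)
    i <- which.min(d2)
    c(i, sqrt(d2[i]))
  }))
}

expect_deterministic <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}
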
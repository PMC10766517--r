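#' @useDynLib ca1scaffold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames spline
#' @importFrom utils head tail write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Pipeline stages draw from independent RNG streams derived from the master
#' seed by a fixed offset scheme, so that any stage can be re-run in
#' isolation and reproduce its in-pipeline output.
#'
#' @param master integer master seed.
#' @param stage stage name, one of the documented pipeline stages.
#' @return an integer seed, always below `2^31 - 1`.
#' @export
stage_seed <- function(master, stage) {
  stages <- c(geometry = 1L, placement = 2L, render = 3L, segment = 4L,
              prune = 5L, classes = 6L, density = 7L, morphology = 8L,
              connect = 9L, baseline = 10L, validate = 11L)
  if (!stage %in% names(stages))
    stop("unknown pipeline stage: ", stage)
  (as.integer(master) * 101L + stages[[stage]]) %% 2147483587L
}

# normalize rows of a matrix to unit length; zero rows stay zero
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a positive finite scalar")
}

# largest-remainder apportionment of n into round(n * p) with exact sum
apportion <- function(n, p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1
  }
  as.integer(k)
}
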
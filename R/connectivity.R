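#' Minimal axis-aligned bounding box of a point cloud
#'
#' @param points n x 3 matrix (n >= 1).
#' @return named numeric vector `x_min, x_max, y_min, y_max, z_min, z_max`.
#' @export
bounding_box <- function(points) {
  points <- as.matrix(points)
  if (!nrow(points)) stop("empty point cloud has no bounding box")
  r <- apply(points[, 1:3, drop = FALSE], 2, range)
  setNames(as.vector(r), c("x_min", "x_max", "y_min", "y_max",
                           "z_min", "z_max"))[c(1, 2, 3, 4, 5, 6)]
}

#' Closed-interval overlap of two bounding boxes
#'
#' True iff the boxes overlap on all three axes with the closed-interval
#' rule `max1 >= min2 & max2 >= min1`: boxes sharing exactly one face do
#' overlap.
#'
#' @param a,b bounding boxes from [bounding_box()].
#' @return logical.
#' @export
boxes_overlap <- function(a, b) {
  a[["x_max"]] >= b[["x_min"]] && b[["x_max"]] >= a[["x_min"]] &&
  a[["y_max"]] >= b[["y_min"]] && b[["y_max"]] >= a[["y_min"]] &&
  a[["z_max"]] >= b[["z_min"]] && b[["z_max"]] >= a[["z_min"]]
}

# default absolute inclusion tolerance, relative to coordinate magnitude
hull_tolerance <- function(morphologies) {
  m <- max(abs(unlist(lapply(morphologies, function(x) x$axon_box))), 1)
  1e-9 * m
}

connection_set <- function(pre_gid, post_gid, pre_class, post_class,
                           provenance) {
  df <- data.frame(pre_gid = as.integer(pre_gid),
                   post_gid = as.integer(post_gid),
                   pre_class = pre_class, post_class = post_class,
                   stringsAsFactors = FALSE)
  if (any(df$pre_gid == df$post_gid)) stop("self-connection in pair set")
  # canonical order: class pair, then pre, then post
  df <- df[order(df$pre_class, df$post_class, df$pre_gid, df$post_gid), ]
  rownames(df) <- NULL
  if (anyDuplicated(df[, c("pre_gid", "post_gid")]))
    stop("duplicate pair in connection set")
  attr(df, "provenance") <- provenance
  class(df) <- c("connection_set", "data.frame")
  df
}

#' Candidate synaptic pairs by touch detection
#'
#' A directed pair (pre, post) is a candidate iff the axonal bounding box
#' of the presynaptic neuron overlaps the dendritic bounding box of the
#' postsynaptic neuron (closed intervals) and at least one dendritic point
#' of the postsynaptic neuron lies inside (or on, within tolerance) the
#' convex hull of the presynaptic axonal cloud. The pair is recorded once
#' regardless of how many dendritic points fall inside. The bounding-box
#' prefilter is lossless: disabling it (`prefilter = FALSE`, the
#' brute-force reference mode) returns the identical pair set.
#'
#' @param morphologies list of `morphology_cloud` objects from
#'   [build_morphologies()].
#' @param tol absolute hull-inclusion tolerance in um; defaults to 1e-9
#'   times the coordinate magnitude, so boundary points (for example a
#'   dendritic point exactly on a hull vertex) are always included.
#' @param prefilter apply the bounding-box prefilter (default).
#' @return a `connection_set` with provenance `"candidate"`.
#' @export
find_candidate_pairs <- function(morphologies, tol = NULL,
                                 prefilter = TRUE) {
  gids <- vapply(morphologies, function(m) m$gid, numeric(1))
  classes <- vapply(morphologies, function(m) m$class, character(1))
  if (anyNA(gids) || is.null(gids)) stop("missing morphology GIDs")
  if (is.null(tol)) tol <- hull_tolerance(morphologies)
  axon_A <- lapply(morphologies, function(m) m$hull$normals)
  axon_b <- lapply(morphologies, function(m) m$hull$offsets)
  axon_box <- do.call(rbind, lapply(morphologies, function(m) m$axon_box))
  dend_pts <- lapply(morphologies, function(m) m$dendrite_points)
  dend_box <- do.call(rbind, lapply(morphologies, function(m) m$dend_box))
  pairs <- .candidate_pairs_cpp(axon_A, axon_b, axon_box, dend_pts,
                                dend_box, tol, prefilter)
  connection_set(gids[pairs[, 1]], gids[pairs[, 2]],
                 classes[pairs[, 1]], classes[pairs[, 2]], "candidate")
}

#' Prune candidate pairs to class-pair connection targets
#'
#' For every (presynaptic class, postsynaptic class) group, the target
#' count is the rodent-derived connection probability times the product of
#' the class sizes, `round(p * N_pre * N_post)` (the alternative
#' `"sum"` interpretation uses `round(p * (N_pre + N_post))`). A uniform
#' random subsample of that size is kept; when fewer candidates than the
#' target exist, all are kept and the shortfall is reported via message.
#'
#' @param candidates a `connection_set` of candidates.
#' @param p_conn data frame `pre_class, post_class, p` of per-pair
#'   connection probabilities (see [default_p_conn()]); class pairs absent
#'   from the table are dropped.
#' @param class_sizes named integer vector of neurons per class.
#' @param seed integer seed.
#' @param interpretation `"product"` (default) or `"sum"`.
#' @return a `connection_set` with provenance `"pruned"` and attribute
#'   `"shortfall"` (named per class pair).
#' @export
prune_pairs <- function(candidates, p_conn, class_sizes, seed = 1,
                        interpretation = c("product", "sum")) {
  interpretation <- match.arg(interpretation)
  if (any(p_conn$p < 0 | p_conn$p > 1))
    stop("connection probabilities must be in [0, 1]")
  key <- paste(candidates$pre_class, candidates$post_class, sep = "__")
  tab_key <- paste(p_conn$pre_class, p_conn$post_class, sep = "__")
  keep_rows <- integer(0)
  shortfall <- integer(0)
  with_seed(seed, {
    for (g in unique(key)) {
      rows <- which(key == g)
      ti <- match(g, tab_key)
      if (is.na(ti)) next
      p <- p_conn$p[ti]
      np <- class_sizes[[p_conn$pre_class[ti]]]
      nq <- class_sizes[[p_conn$post_class[ti]]]
      target <- if (interpretation == "product")
        round(p * np * nq) else round(p * (np + nq))
      if (target < length(rows)) {
        keep_rows <- c(keep_rows, rows[sample.int(length(rows), target)])
      } else {
        keep_rows <- c(keep_rows, rows)
        if (target > length(rows)) {
          shortfall[g] <- target - length(rows)
          message("class pair ", g, ": only ", length(rows),
                  " candidates for target ", target,
                  " (shortfall ", target - length(rows), ")")
        }
      }
    }
  })
  out <- connection_set(candidates$pre_gid[keep_rows],
                        candidates$post_gid[keep_rows],
                        candidates$pre_class[keep_rows],
                        candidates$post_class[keep_rows], "pruned")
  attr(out, "shortfall") <- shortfall
  out
}

#' Example connection-probability table
#'
#' Per-pair synaptic connection probabilities by (presynaptic,
#' postsynaptic) class, in the spirit of rodent CA1 compilations. These are
#' documented example values for the desk-scale fixture; quantitative work
#' should substitute measured probabilities.
#'
#' @param p_default probability for class pairs not explicitly listed.
#' @return data frame `pre_class, post_class, p` covering all 64 class
#'   pairs.
#' @export
default_p_conn <- function(p_default = 0.01) {
  g <- expand.grid(pre_class = scaffold_classes(),
                   post_class = scaffold_classes(),
                   stringsAsFactors = FALSE)
  g$p <- p_default
  g$p[g$pre_class == "PC" & g$post_class == "PC"] <- 0.008
  g$p[g$pre_class == "PC" & g$post_class != "PC"] <- 0.02
  g$p[g$pre_class == "Perisomatic" & g$post_class == "PC"] <- 0.04
  g$p[g$pre_class %in% c("OLM", "IVY", "NGF") & g$post_class == "PC"] <- 0.03
  g
}

#' Random connectivity baseline
#'
#' Uniform random distinct directed pairs without self-loops, with an
#' exact connection count, used as the null network against which the
#' morphological connectome's degree distributions are compared.
#'
#' @param placement placement data frame.
#' @param n_connections exact number of pairs (<= N(N-1)).
#' @param seed integer seed.
#' @return a `connection_set` with provenance `"random_baseline"`.
#' @export
random_baseline <- function(placement, n_connections, seed = 1) {
  n <- nrow(placement)
  npairs <- as.numeric(n) * (n - 1)
  if (n_connections > npairs)
    stop("requested ", n_connections, " pairs but only ", npairs,
         " distinct directed pairs exist")
  with_seed(seed, {
    z <- sample(npairs, n_connections)
    pre <- (z - 1) %/% (n - 1) + 1
    r <- (z - 1) %% (n - 1) + 1
    post <- r + (r >= pre)
    connection_set(placement$gid[pre], placement$gid[post],
                   placement$class[pre], placement$class[post],
                   "random_baseline")
  })
}
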
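#' Class configuration for the scaffold population
#'
#' The population is split into excitatory pyramidal cells (PCs) and
#' inhibitory interneurons using a 10% inhibitory-to-excitatory ratio, and
#' the interneurons are further partitioned into seven morphological
#' classes. The per-class proportions and the proportionality constants of
#' the SLM-ward soma shifts are configuration: only the ordering (the
#' neurogliaform shift is the largest) is anatomically constrained.
#'
#' @param inhibitory_ratio inhibitory/excitatory ratio in (0, 1).
#' @param proportions named non-negative weights over the seven interneuron
#'   classes, summing to 1.
#' @param shift_gains proportionality constants (dimensionless multiples of
#'   the soma-to-SR-border distance) of the SLM-ward shifts for SCA, PPA and
#'   NGF somas; the NGF gain must be strictly the largest.
#' @param outer_quantile fraction of a side subgroup counted as its "outer
#'   part" (somas ranked by proximity to that side's surface).
#' @return a validated `class_config` list.
#' @export
class_config <- function(inhibitory_ratio = 0.10,
                         proportions = c(Perisomatic = 0.22, OLM = 0.07,
                                         IVY = 0.15, TRI = 0.04,
                                         SCA = 0.13, PPA = 0.12,
                                         NGF = 0.27),
                         shift_gains = c(SCA = 0.5, PPA = 0.5, NGF = 1.0),
                         outer_quantile = 0.7) {
  if (inhibitory_ratio <= 0 || inhibitory_ratio >= 1)
    stop("inhibitory_ratio must be in (0, 1)")
  if (!setequal(names(proportions), interneuron_classes()))
    stop("proportions must be named with the seven interneuron classes")
  proportions <- proportions[interneuron_classes()]
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be >= 0 and sum to 1")
  if (!all(c("SCA", "PPA", "NGF") %in% names(shift_gains)))
    stop("shift_gains must name SCA, PPA and NGF")
  if (shift_gains[["NGF"]] <= max(shift_gains[["SCA"]], shift_gains[["PPA"]]))
    stop("the NGF shift gain must be strictly the largest")
  if (outer_quantile <= 0 || outer_quantile > 1)
    stop("outer_quantile must be in (0, 1]")
  structure(list(inhibitory_ratio = inhibitory_ratio,
                 proportions = proportions, shift_gains = shift_gains,
                 outer_quantile = outer_quantile), class = "class_config")
}

#' The eight neuron classes of the scaffold
#' @return character vectors of class names.
#' @export
scaffold_classes <- function() c("PC", interneuron_classes())

#' @rdname scaffold_classes
#' @export
interneuron_classes <- function()
  c("Perisomatic", "OLM", "IVY", "TRI", "SCA", "PPA", "NGF")

#' Excitatory/inhibitory split of a target population
#'
#' With inhibitory ratio r, the excitatory count is
#' `round(n_total / (1 + r))` and the inhibitory count is the remainder.
#' At the full CA1 scale (5.28 million neurons, r = 0.10) this yields
#' 4.8 million PCs and 480,000 interneurons.
#'
#' @param n_total total number of neurons.
#' @param inhibitory_ratio inhibitory/excitatory ratio.
#' @return list with integer `n_exc` and `n_inh`.
#' @export
population_split <- function(n_total, inhibitory_ratio = 0.10) {
  n_exc <- round(n_total / (1 + inhibitory_ratio))
  list(n_exc = n_exc, n_inh = n_total - n_exc)
}

#' Randomly prune detected somas to the target population
#'
#' Uniform random subsampling without replacement of the segmented soma
#' cloud down to the putative neuron count, followed by the
#' excitatory/inhibitory split of [population_split()]. Inhibitory somas
#' are drawn uniformly among the pruned set; their interneuron class is
#' assigned later by [assign_interneuron_classes()].
#'
#' @param somas data frame `gid, x, y, z` from segmentation.
#' @param n_total target population size (<= `nrow(somas)`).
#' @param config a [class_config()].
#' @param seed integer seed.
#' @return placement data frame `gid, x, y, z, type, class` where `type`
#'   is `"exc"` or `"inh"`; inhibitory `class` is `NA` until assignment.
#' @export
prune_to_population <- function(somas, n_total, config = class_config(),
                                seed = 1) {
  if (n_total > nrow(somas))
    stop("requested population (", n_total, ") exceeds available somas (",
         nrow(somas), ")")
  with_seed(seed, {
    keep <- sort(sample.int(nrow(somas), n_total))
    placement <- somas[keep, c("gid", "x", "y", "z")]
    rownames(placement) <- NULL
    split <- population_split(n_total, config$inhibitory_ratio)
    placement$type <- "exc"
    placement$class <- "PC"
    if (split$n_inh > 0) {
      inh <- sample.int(n_total, split$n_inh)
      placement$type[inh] <- "inh"
      placement$class[inh] <- NA_character_
    }
    placement
  })
}

#' Split a two-sheet CA1 surface into its deep (SO) and superficial (SR)
#' sides
#'
#' The labelled CA1 surface is one point cloud containing two roughly
#' parallel sheets. A nearest-neighbour single-linkage clustering (vertices
#' closer than `gap` are linked) must produce exactly two connected
#' components; otherwise the sides are not separable at the configured gap
#' and an error is raised. Side identity comes from seed points (the
#' component nearest `deep_seed` is the SO side); without seeds the
#' component with the smaller mean depth (z) is the deep side.
#'
#' @param surface n x 3 point matrix of the combined surface.
#' @param gap linkage distance (um); must exceed the vertex spacing and be
#'   below the sheet offset.
#' @param deep_seed,superficial_seed optional 3-vectors marking the sides.
#' @return list with logical vector `deep` (TRUE for SO-side vertices) and
#'   the integer component labels.
#' @export
split_ca1_sides <- function(surface, gap, deep_seed = NULL,
                            superficial_seed = NULL) {
  surface <- as.matrix(surface)
  n <- nrow(surface)
  k <- min(n, 10L)
  nn <- RANN::nn2(surface, surface, k = k)
  from <- rep(seq_len(n), k)
  to <- as.vector(nn$nn.idx)
  d <- as.vector(nn$nn.dists)
  keep <- d <= gap & from != to
  lab <- .graph_components_cpp(cbind(from[keep], to[keep]), n)
  # component-level single linkage: the k-NN pass can miss links longer
  # than the local vertex spacing, so merge components whose minimum
  # inter-component distance is still within the gap
  repeat {
    comps <- sort(unique(lab))
    if (length(comps) < 2L) break
    merged <- FALSE
    for (a in seq_along(comps)) {
      for (b in seq_len(a - 1L)) {
        pa <- surface[lab == comps[a], , drop = FALSE]
        pb <- surface[lab == comps[b], , drop = FALSE]
        dmin <- min(RANN::nn2(pa, pb, k = 1)$nn.dists)
        if (dmin <= gap) {
          lab[lab == comps[a]] <- comps[b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  if (length(unique(lab)) != 2L)
    stop("surface sides not separable at gap ", gap, ": found ",
         length(unique(lab)), " component(s)")
  if (!is.null(deep_seed) && !is.null(superficial_seed)) {
    nn1 <- RANN::nn2(surface, rbind(deep_seed, superficial_seed), k = 1)
    ld <- lab[nn1$nn.idx[1, 1]]
    ls <- lab[nn1$nn.idx[2, 1]]
    if (ld == ls) stop("side seed points resolve to the same component")
    deep <- lab == ld
  } else {
    mz <- tapply(surface[, 3], lab, mean)
    deep <- lab == as.integer(names(which.min(mz)))
  }
  list(deep = deep, components = lab)
}

#' Minimum Euclidean distances from somas to landmark clouds
#'
#' For each landmark role, the nearest landmark vertex of every soma, the
#' minimum Euclidean distance, and the unit direction vector pointing from
#' the soma towards that vertex. A soma coincident with a vertex gets
#' distance 0 and a zero direction vector.
#'
#' @param positions n x 3 matrix (or placement data frame) of soma
#'   positions.
#' @param landmarks named list of landmark point matrices (e.g. from
#'   [geometry_landmarks()]).
#' @return named list, one entry per landmark role, each with `distance`
#'   (n), `direction` (n x 3) and `index` (nearest vertex row).
#' @export
landmark_distances <- function(positions, landmarks) {
  if (is.data.frame(positions))
    positions <- as.matrix(positions[, c("x", "y", "z")])
  lapply(landmarks, function(cloud) {
    cloud <- as.matrix(cloud)[, 1:3, drop = FALSE]
    if (!nrow(cloud)) stop("empty landmark cloud")
    nn <- RANN::nn2(cloud, positions, k = 1)
    idx <- nn$nn.idx[, 1]
    dirs <- cloud[idx, , drop = FALSE] - positions
    list(distance = nn$nn.dists[, 1], direction = unit_rows(dirs),
         index = idx)
  })
}

#' Assign the seven interneuron classes by landmark geometry
#'
#' Interneuron quotas follow the configured proportions (largest-remainder
#' rounding, so quotas sum to the interneuron count exactly). OLM and TRI
#' come from the SO-side subgroup (somas nearer the SO than the SR
#' surface), with OLM restricted to the outer part (the configured quantile
#' nearest the SO surface); NGF, IVY, SCA and PPA come from the outer part
#' of the SR-side subgroup (the quantile nearest the SR border of the pool
#' remaining at their draw). Perisomatic somas, which are not layer
#' restricted, absorb the remaining somas across the whole volume; this
#' order keeps exact quotas feasible for any realized side split, and a
#' quota that still exceeds its side subgroup raises an error reporting
#' both counts. SCA, PPA and NGF somas are then displaced towards the SLM
#' along the soma-to-SLM direction by `gain * dist(soma, SR border)`, with
#' the NGF gain strictly the largest (neurogliaform somas sit deepest into
#' the SLM).
#'
#' @param placement placement with `type` column (`"exc"`/`"inh"`).
#' @param landmarks named list with at least `so`, `sr` and `slm` clouds.
#' @param config a [class_config()].
#' @param seed integer seed (`NULL` continues the current RNG stream).
#' @return the placement with interneuron `class` filled in, shifted SCA /
#'   PPA / NGF positions (displacements are capped at the SLM surface so
#'   shifted somas stay inside the sheet), and soma-to-landmark distances
#'   in columns `d_so`, `d_sr`, `d_slm` (computed before any shift).
#' @export
assign_interneuron_classes <- function(placement, landmarks,
                                       config = class_config(), seed = 1) {
  inh <- which(placement$type == "inh")
  n_inh <- length(inh)
  ld <- landmark_distances(placement[, c("x", "y", "z")],
                           landmarks[c("so", "sr", "slm")])
  placement$d_so <- ld$so$distance
  placement$d_sr <- ld$sr$distance
  placement$d_slm <- ld$slm$distance
  if (n_inh == 0) return(placement)
  quotas <- apportion(n_inh, config$proportions)
  names(quotas) <- names(config$proportions)
  with_seed(seed, {
    assigned <- rep(NA_character_, n_inh)
    d_so <- placement$d_so[inh]
    d_sr <- placement$d_sr[inh]
    so_side <- d_so < d_sr
    draw_from <- function(pool, k, class) {
      if (length(pool) < k)
        stop("class ", class, " quota (", k, ") exceeds its side subgroup (",
             length(pool), " somas)")
      if (k == 0) return(integer(0))
      pool[sample.int(length(pool), k)]
    }
    # the configured quantile of the pool nearest the reference surface,
    # extended to the quota-nearest somas when the quantile subset is
    # smaller than the quota (still the outermost members; a quota can
    # then only fail against the side subgroup itself)
    outer_part <- function(pool, dist_to_surface, quota) {
      if (!length(pool)) return(pool)
      d <- dist_to_surface[pool]
      q <- stats::quantile(d, config$outer_quantile)
      sub <- pool[d <= q]
      if (length(sub) < quota && length(pool) >= quota)
        sub <- pool[order(d)][seq_len(quota)]
      sub
    }
    # SO-side classes: OLM from the outer part, TRI from the rest
    pool_so <- which(so_side)
    olm <- draw_from(outer_part(pool_so, d_so, quotas[["OLM"]]),
                     quotas[["OLM"]], "OLM")
    assigned[olm] <- "OLM"
    pool_so <- setdiff(pool_so, olm)
    tri <- draw_from(pool_so, quotas[["TRI"]], "TRI")
    assigned[tri] <- "TRI"
    # SR-side classes, each drawn from the outer part (nearest the SR
    # border) of the pool remaining at its turn; NGF first since it is the
    # most abundant and is shifted deepest
    for (cls in c("NGF", "IVY", "SCA", "PPA")) {
      pool_sr <- which(is.na(assigned) & !so_side)
      sel <- draw_from(outer_part(pool_sr, d_sr, quotas[[cls]]),
                       quotas[[cls]], cls)
      assigned[sel] <- cls
    }
    # Perisomatic: the layer-unrestricted class, absorbs the remainder
    rest <- which(is.na(assigned))
    if (length(rest) != quotas[["Perisomatic"]])
      stop("class Perisomatic quota (", quotas[["Perisomatic"]],
           ") does not match the remaining pool (", length(rest), " somas)")
    assigned[rest] <- "Perisomatic"
    placement$class[inh] <- assigned
    # SLM-ward shifts proportional to the soma-to-SR-border distance,
    # capped at the SLM surface so shifted somas stay inside the sheet
    for (cls in c("SCA", "PPA", "NGF")) {
      rows <- inh[assigned == cls]
      if (!length(rows)) next
      gain <- config$shift_gains[[cls]]
      mag <- pmin(gain * placement$d_sr[rows], placement$d_slm[rows])
      shift <- ld$slm$direction[rows, , drop = FALSE] * mag
      placement[rows, c("x", "y", "z")] <-
        placement[rows, c("x", "y", "z")] + shift
    }
    placement
  })
}
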
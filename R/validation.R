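degree_histogram <- function(values, bin_width, kind) {
  stopifnot_scalar_pos(bin_width, "bin_width")
  edges <- seq(0, (max(values) %/% bin_width + 1) * bin_width,
               by = bin_width)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1)
  density <- counts / (sum(counts) * bin_width)
  structure(list(bin_edges = edges, density = density, counts = counts,
                 kind = kind), class = "degree_histogram")
}

#' Per-neuron degree counts
#'
#' Out- and indegrees over all placed neurons: neurons without any
#' connection count with degree zero.
#'
#' @param connections a `connection_set`.
#' @param placement placement data frame (defines the neuron universe).
#' @return list of named integer vectors `outdegree`, `indegree`, `total`.
#' @export
degree_counts <- function(connections, placement) {
  gids <- placement$gid
  outd <- table(factor(connections$pre_gid, levels = gids))
  ind <- table(factor(connections$post_gid, levels = gids))
  out <- setNames(as.integer(outd), gids)
  inn <- setNames(as.integer(ind), gids)
  list(outdegree = out, indegree = inn, total = out + inn)
}

#' Indegree and outdegree probability densities
#'
#' Bins the per-neuron converging-input (indegree) and diverging-output
#' (outdegree) counts, zeros included, into probability densities
#' (`sum(density * bin_width) = 1`).
#'
#' @param connections a `connection_set`.
#' @param placement placement data frame.
#' @param bin_width histogram bin width in connections (default 100).
#' @return list of two `degree_histogram`s, `indegree` and `outdegree`.
#' @export
degree_distributions <- function(connections, placement, bin_width = 100) {
  if (!nrow(connections)) stop("empty connection set")
  deg <- degree_counts(connections, placement)
  list(indegree = degree_histogram(deg$indegree, bin_width, "indegree"),
       outdegree = degree_histogram(deg$outdegree, bin_width, "outdegree"))
}

#' Connection-length probability density
#'
#' The length of a connection is the Euclidean soma-to-soma distance of
#' its pair, in micrometres.
#'
#' @param connections a `connection_set`.
#' @param placement placement data frame with positions for every GID.
#' @param bin_width histogram bin width in um (default 100).
#' @return a `degree_histogram` of kind `"length"`, with the raw lengths
#'   in attribute `"lengths"`.
#' @export
connection_lengths <- function(connections, placement, bin_width = 100) {
  ip <- match(connections$pre_gid, placement$gid)
  iq <- match(connections$post_gid, placement$gid)
  if (anyNA(ip) || anyNA(iq))
    stop("connection references a GID absent from the placement")
  pos <- as.matrix(placement[, c("x", "y", "z")])
  len <- sqrt(rowSums((pos[ip, , drop = FALSE] -
                       pos[iq, , drop = FALSE])^2))
  h <- degree_histogram(len, bin_width, "length")
  attr(h, "lengths") <- len
  h
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' `KL(P || Q) = -sum p * log(q / p)` over the bins (natural log), i.e.
#' the negative sum of the probability of each event in P times the log of
#' the probability of the same event in Q over its probability in P.
#' Q receives additive epsilon smoothing (then renormalization) so that no
#' bin with positive P probability has zero Q probability. Non-negative,
#' zero iff the distributions coincide on the support; asymmetric.
#'
#' @param P,Q `degree_histogram`s on identical bin edges.
#' @param epsilon additive smoothing on Q's bin probabilities.
#' @return the divergence in nats.
#' @export
kl_divergence <- function(P, Q, epsilon = 1e-12) {
  if (length(P$bin_edges) != length(Q$bin_edges) ||
      any(P$bin_edges != Q$bin_edges))
    stop("histograms have mismatched bin edges")
  w <- diff(P$bin_edges)
  p <- P$density * w
  q <- Q$density * w + epsilon
  q <- q / sum(q)
  s <- p > 0
  sum(p[s] * log(p[s] / q[s]))
}

# pad two histograms to common bin edges (same bin width required)
align_histograms <- function(P, Q) {
  w <- unique(c(diff(P$bin_edges), diff(Q$bin_edges)))
  if (length(w) != 1) stop("histograms have different bin widths")
  hi <- max(max(P$bin_edges), max(Q$bin_edges))
  pad <- function(H) {
    edges <- seq(0, hi, by = w)
    density <- c(H$density, rep(0, length(edges) - length(H$bin_edges)))
    counts <- c(H$counts, rep(0L, length(edges) - length(H$bin_edges)))
    structure(list(bin_edges = edges, density = density, counts = counts,
                   kind = H$kind), class = "degree_histogram")
  }
  list(P = pad(P), Q = pad(Q))
}

#' Compare two degree histograms by KL divergence
#'
#' Convenience wrapper aligning the histograms to common edges (zero
#' density in missing bins) before [kl_divergence()].
#'
#' @param P,Q `degree_histogram`s with equal bin width.
#' @param epsilon smoothing for [kl_divergence()].
#' @return the divergence in nats.
#' @export
kl_compare <- function(P, Q, epsilon = 1e-12) {
  a <- align_histograms(P, Q)
  kl_divergence(a$P, a$Q, epsilon)
}

#' Detect hub neurons
#'
#' Hubs are the highly connected elements of the network: neurons whose
#' degree exceeds `mean + k_sd * sd` of the supplied degree vector
#' (strictly; a neuron exactly at the threshold is not a hub).
#'
#' @param degrees named numeric vector of per-neuron degrees (typically
#'   `degree_counts()$total`).
#' @param k_sd threshold in standard deviations above the mean (default 3).
#' @return character vector of hub GIDs (possibly empty).
#' @export
detect_hubs <- function(degrees, k_sd = 3) {
  thr <- mean(degrees) + k_sd * stats::sd(degrees)
  names(degrees)[degrees > thr]
}

#' Export a histogram as CSV
#'
#' @param hist a `degree_histogram`.
#' @param path output path; columns `bin_lo, bin_hi, density, count`.
#' @return the path, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  df <- data.frame(bin_lo = head(hist$bin_edges, -1),
                   bin_hi = tail(hist$bin_edges, -1),
                   density = hist$density, count = hist$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
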
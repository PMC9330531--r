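# Sinusoid network statistics: edge/node ratio, degree law, loop census,
# clustering, centralization, branch angles.

#' Edge-to-node ratio
#'
#' `E / V` of the multigraph, counting multi-edges and self-loops as edges.
#' A tree has ratio `(V - 1) / V < 1`; loop-rich sinusoid networks sit well
#' above 1. By Euler's formula the ratio equals
#' `1 + (cyclomatic - components) / V`.
#'
#' @param g vessel graph with at least one node.
#' @return dimensionless ratio.
#' @export
edge_node_ratio <- function(g) {
  if (nrow(g$nodes) < 1) stop("empty graph")
  nrow(g$edges) / nrow(g$nodes)
}

#' Degree histogram and high-degree fraction
#'
#' @param g vessel graph (degrees of the multigraph; self-loops count
#'   twice).
#' @return list with `histogram` (counts named by degree, summing to V) and
#'   `high_degree_fraction` (fraction of nodes with degree strictly greater
#'   than 3).
#' @export
degree_stats <- function(g) {
  if (nrow(g$nodes) < 1) stop("empty graph")
  deg <- g$nodes$degree
  h <- table(factor(deg, levels = 0:max(deg)))
  list(histogram = setNames(as.integer(h), names(h)),
       high_degree_fraction = mean(deg > 3))
}

#' Maximum-likelihood lognormal fit with Kolmogorov-Smirnov statistic
#'
#' `mu` is the mean of the log sample and `sigma` its population standard
#' deviation (the lognormal MLEs); the KS statistic compares the empirical
#' CDF (ties allowed) with the fitted law. A zero-variance sample yields a
#' degenerate fit, flagged with `degenerate = TRUE` and `ks_stat = NA`.
#'
#' @param samples positive numeric values, at least 8.
#' @return list `(mu, sigma, ks_stat, n, degenerate)`.
#' @export
fit_lognormal <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 8) stop("need at least 8 samples")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("all samples must be positive and finite")
  lx <- log(samples)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma < .Machine$double.eps^0.5)
    return(list(mu = mu, sigma = 0, ks_stat = NA_real_,
                n = length(samples), degenerate = TRUE))
  x <- sort(samples)
  n <- length(x)
  Fx <- plnorm(x, mu, sigma)
  ks <- max(abs(seq_len(n) / n - Fx), abs(Fx - (seq_len(n) - 1) / n))
  list(mu = mu, sigma = sigma, ks_stat = ks, n = n, degenerate = FALSE)
}

#' Mean local clustering coefficient
#'
#' Computed on the simple graph (multi-edges collapsed, self-loops
#' dropped); nodes with degree below 2 contribute 0.
#'
#' @param g vessel graph with V >= 3.
#' @return mean local clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  if (nrow(g$nodes) < 3) stop("need at least 3 nodes")
  sg <- vg_simple(g)
  igraph::transitivity(sg$igraph, type = "localaverage", isolates = "zero")
}

#' Freeman degree centralization
#'
#' `sum(deg_max - deg_i) / ((V - 1) * (V - 2))` on the simple graph: 0 for
#' regular (e.g. cycle) graphs, 1 for a star.
#'
#' @param g vessel graph with V >= 3.
#' @return centralization in `[0, 1]`.
#' @export
degree_centralization <- function(g) {
  nv <- nrow(g$nodes)
  if (nv < 3) stop("need at least 3 nodes")
  sg <- vg_simple(g)
  deg <- igraph::degree(sg$igraph)
  sum(max(deg) - deg) / ((nv - 1) * (nv - 2))
}

#' Loop census by minimum cycle basis
#'
#' Counts independent loops keyed by their edge number. Self-loops count as
#' 1-edge loops and each extra parallel edge as a 2-edge loop; the
#' remaining loops are the elements of a minimum cycle basis of the simple
#' graph (Horton's algorithm), the canonical decomposition into smallest
#' loops. The census total always equals the cyclomatic number
#' `E - V + C` of the multigraph.
#'
#' @param g vessel graph.
#' @return list with `census` (named integer vector, names are edge
#'   counts), `total`, `total_edge_weight` (summed basis cycle sizes over
#'   the simple graph), and `loops` (list of original edge-id vectors, one
#'   per basis loop).
#' @export
loop_census <- function(g) {
  sg <- vg_simple(g)
  sizes <- integer(0)
  loops <- list()
  e <- g$edges
  for (id in e$id[e$from == e$to]) {           # self-loops
    sizes <- c(sizes, 1L); loops[[length(loops) + 1L]] <- id
  }
  if (sg$n_parallel_extra > 0) {               # parallel pairs
    for (id in sg$parallel_extra_ids) {
      twin <- e$id[e$id != id & e$from != e$to &
                     pmin(e$from, e$to) == min(e$from[e$id == id], e$to[e$id == id]) &
                     pmax(e$from, e$to) == max(e$from[e$id == id], e$to[e$id == id])][1]
      sizes <- c(sizes, 2L); loops[[length(loops) + 1L]] <- c(twin, id)
    }
  }
  el <- igraph::as_edgelist(sg$igraph, names = FALSE)
  simple_weight <- 0
  if (nrow(el)) {
    res <- .mcb_cpp(nrow(g$nodes), cbind(el[, 1] - 1L, el[, 2] - 1L),
                    rep(1, nrow(el)))
    for (cyc in res$cycles) {
      sizes <- c(sizes, length(cyc))
      loops[[length(loops) + 1L]] <- sg$edge_rep[cyc]
    }
    simple_weight <- sum(res$weights)
  }
  census <- integer(0)
  if (length(sizes)) {
    tb <- table(sizes)
    census <- setNames(as.integer(tb), names(tb))
  }
  list(census = census, total = length(sizes),
       total_edge_weight = simple_weight, loops = loops)
}

#' Branch angles at graph nodes
#'
#' The direction of each incident edge at a node is the unit vector from
#' the node to the point on that edge's centerline at arc distance
#' `d_tangent_um` (clamped to the edge length); all pairwise angles at
#' nodes with two or more incident edge ends are collected. Reported are
#' the pooled mean angle, the mean over nodes of the per-node mean, and the
#' mean over nodes of the per-node minimum angle, in degrees.
#'
#' @param g vessel graph.
#' @param d_tangent_um arc distance used to define edge directions
#'   (default 5 micrometres).
#' @return list `(mean_angle_deg, node_mean_angle_deg, mean_min_angle_deg,
#'   n_nodes, angles_deg)`.
#' @export
branch_angles <- function(g, d_tangent_um = 5) {
  dirs_at <- vector("list", nrow(g$nodes))
  point_at <- function(p, d) {
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    d <- min(d, s[length(s)])
    if (s[length(s)] <= 0) return(NULL)
    c(approx(s, p[, 1], xout = d)$y, approx(s, p[, 2], xout = d)$y,
      approx(s, p[, 3], xout = d)$y)
  }
  for (e in seq_len(nrow(g$edges))) {
    p <- g$polylines[[e]]
    for (endp in c("from", "to")) {
      nd <- g$edges[[endp]][e]
      q <- if (endp == "from") p else p[nrow(p):1, , drop = FALSE]
      tgt <- point_at(q, d_tangent_um)
      if (is.null(tgt)) next
      v <- tgt - q[1, ]
      nv <- sqrt(sum(v^2))
      if (nv <= 0) next
      dirs_at[[nd]] <- rbind(dirs_at[[nd]], v / nv)
    }
  }
  all_ang <- numeric(0)
  node_mean <- node_min <- numeric(0)
  for (nd in seq_along(dirs_at)) {
    u <- dirs_at[[nd]]
    if (is.null(u) || nrow(u) < 2) next
    cs <- tcrossprod(u)
    ang <- acos(pmin(pmax(cs[upper.tri(cs)], -1), 1)) * 180 / pi
    all_ang <- c(all_ang, ang)
    node_mean <- c(node_mean, mean(ang))
    node_min <- c(node_min, min(ang))
  }
  if (!length(all_ang)) stop("no node with two or more incident edges")
  list(mean_angle_deg = mean(all_ang),
       node_mean_angle_deg = mean(node_mean),
       mean_min_angle_deg = mean(node_min),
       n_nodes = length(node_min), angles_deg = all_ang)
}

#' Convert counts to densities per cubic millimetre
#'
#' @param counts named or unnamed counts (e.g. edges, loops by edge number).
#' @param reference_volume_mm3 positive reference volume.
#' @return counts divided by the reference volume.
#' @export
densities <- function(counts, reference_volume_mm3) {
  if (!is.numeric(reference_volume_mm3) || reference_volume_mm3 <= 0)
    stop("reference volume must be positive")
  counts / reference_volume_mm3
}

#' Full topology report for a sinusoid graph
#'
#' Bundles the ratio, degree law (with lognormal fit of degrees > 0), the
#' clustering coefficient, Freeman centralization, loop census, branch
#' angles and, when a reference volume is given, edge and loop densities.
#'
#' @param g vessel graph.
#' @param reference_volume_mm3 optional lobule volume for densities.
#' @param d_tangent_um tangent distance for branch angles.
#' @return list of class `topology_report`.
#' @export
topology_report <- function(g, reference_volume_mm3 = NULL, d_tangent_um = 5) {
  ds <- degree_stats(g)
  deg <- g$nodes$degree
  fit <- if (sum(deg > 0) >= 8) fit_lognormal(deg[deg > 0]) else NULL
  lc <- loop_census(g)
  rep <- list(
    n_nodes = nrow(g$nodes), n_edges = nrow(g$edges),
    components = g$components,
    edge_node_ratio = edge_node_ratio(g),
    degree_histogram = ds$histogram,
    high_degree_fraction = ds$high_degree_fraction,
    lognormal_fit = fit,
    clustering_coefficient = if (nrow(g$nodes) >= 3) clustering_coefficient(g) else NA_real_,
    degree_centralization = if (nrow(g$nodes) >= 3) degree_centralization(g) else NA_real_,
    loop_census = lc$census,
    loop_total = lc$total,
    angle_stats = tryCatch(branch_angles(g, d_tangent_um)[
      c("mean_angle_deg", "node_mean_angle_deg", "mean_min_angle_deg")],
      error = function(e) NULL)
  )
  if (!is.null(reference_volume_mm3)) {
    rep$edges_per_mm3 <- densities(nrow(g$edges), reference_volume_mm3)
    rep$loops_per_mm3 <- densities(lc$census, reference_volume_mm3)
  }
  class(rep) <- "topology_report"
  rep
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> V=%d E=%d E/V=%.3f loops=%d\n",
              x$n_nodes, x$n_edges, x$edge_node_ratio, x$loop_total))
  cat(sprintf("  clustering %.4f, centralization %.5f, high-degree fraction %.3f\n",
              x$clustering_coefficient, x$degree_centralization,
              x$high_degree_fraction))
  if (length(x$loop_census))
    cat("  loop census:", paste(sprintf("%s-edge: %d", names(x$loop_census),
                                        x$loop_census), collapse = ", "), "\n")
  invisible(x)
}

#' Write loop membership as CSV (edge id -> loop id)
#' @param lc result of [loop_census()].
#' @param path output CSV path.
#' @export
write_loop_membership <- function(lc, path) {
  df <- do.call(rbind, lapply(seq_along(lc$loops), function(i)
    data.frame(loop_id = i, edge_id = lc$loops[[i]])))
  if (is.null(df)) df <- data.frame(loop_id = integer(0), edge_id = integer(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
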
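# Fixture builders and independent oracles shared across tests.

# solid ball mask: radius in um, given spacing
ball_mask <- function(r_um, spacing = c(1, 1, 1), pad = 4) {
  n <- as.integer(ceiling(r_um / spacing) * 2 + 2 * pad + 1)
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n[1], 1:n[2], 1:n[3]))
  d <- sqrt(((co[, 1] - ctr[1]) * spacing[1])^2 +
              ((co[, 2] - ctr[2]) * spacing[2])^2 +
              ((co[, 3] - ctr[3]) * spacing[3])^2)
  arr <- array(FALSE, n)
  arr[co[d <= r_um, , drop = FALSE]] <- TRUE
  arr
}

# solid axis-aligned cuboid mask with padding
box_mask <- function(side_vox, pad = 6) {
  n <- side_vox + 2 * pad
  arr <- array(FALSE, c(n, n, n))
  arr[(pad + 1):(pad + side_vox), (pad + 1):(pad + side_vox),
      (pad + 1):(pad + side_vox)] <- TRUE
  arr
}

# single-edge vessel graph from a polyline (columns z, y, x in um)
polyline_graph <- function(poly) {
  vessel_graph(
    data.frame(z_um = c(poly[1, 1], poly[nrow(poly), 1]),
               y_um = c(poly[1, 2], poly[nrow(poly), 2]),
               x_um = c(poly[1, 3], poly[nrow(poly), 3])),
    data.frame(from = 1, to = 2), list(poly))
}

# abstract graph (no geometry) from an edge list matrix; nodes on a line
abstract_graph <- function(el, nv = max(el)) {
  vessel_graph(data.frame(z_um = rep(0, nv), y_um = rep(0, nv),
                          x_um = seq_len(nv) * 10),
               data.frame(from = el[, 1], to = el[, 2]))
}

# random simple graph with at most max_edges edges
random_simple_graph <- function(max_edges = 12) {
  nv <- sample(4:9, 1)
  pairs <- t(combn(nv, 2))
  m <- sample(3:min(max_edges, nrow(pairs)), 1)
  el <- pairs[sample(nrow(pairs), m), , drop = FALSE]
  list(nv = nv, el = el)
}

# Independent oracle: minimum cycle basis total weight by exhaustive greedy
# over the full GF(2) cycle space (exact by the matroid exchange property).
brute_mcb <- function(nv, el) {
  m <- nrow(el)
  comp <- seq_len(nv)
  tree <- integer(0)
  for (e in seq_len(m)) {
    a <- comp[el[e, 1]]; b <- comp[el[e, 2]]
    if (a != b) { comp[comp == b] <- a; tree <- c(tree, e) }
  }
  k <- m - length(tree)
  if (k == 0) return(list(total = 0, weight = 0))
  nontree <- setdiff(seq_len(m), tree)
  tg <- igraph::graph_from_edgelist(el[tree, , drop = FALSE], directed = FALSE)
  tg <- igraph::add_vertices(tg, max(0, nv - igraph::vcount(tg)))
  fund <- lapply(nontree, function(e) {
    p <- igraph::shortest_paths(tg, el[e, 1], el[e, 2], output = "epath")$epath[[1]]
    v <- rep(FALSE, m)
    v[c(tree[as.integer(p)], e)] <- TRUE
    v
  })
  allvec <- vector("list", 2^k - 1)
  for (s in seq_len(2^k - 1)) {
    v <- rep(FALSE, m)
    for (j in seq_len(k))
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) > 0) v <- xor(v, fund[[j]])
    allvec[[s]] <- v
  }
  wts <- vapply(allvec, sum, numeric(1))
  rows <- list(); piv <- integer(0); tot <- 0
  for (i in order(wts)) {
    v <- allvec[[i]]
    for (j in seq_along(rows)) if (v[piv[j]]) v <- xor(v, rows[[j]])
    p <- which(v)[1]
    if (is.na(p)) next
    rows[[length(rows) + 1]] <- v
    piv <- c(piv, p)
    tot <- tot + wts[i]
    if (length(rows) == k) break
  }
  list(total = k, weight = tot)
}

# moments of log X for X ~ lognormal(mu, sigma) truncated to (0, 1]
# (log X is a normal truncated above at 0); used as the recovery oracle
tlnorm_log_moments <- function(mu, sigma) {
  a <- (0 - mu) / sigma
  lam <- dnorm(a) / pnorm(a)
  m <- mu - sigma * lam
  v <- sigma^2 * (1 - a * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

# standard round-trip recipe: rasterize -> skeletonize -> graph ->
# consolidate junction artifacts -> prune spurs (all radius-scaled)
roundtrip_graph <- function(g, radius_um, spacing = c(1.19, 1.19, 1.19)) {
  vol <- rasterize_graph(g, spacing, radius_um)
  g2 <- build_graph(skeletonize(vol))
  g2 <- consolidate_graph(g2, merge_um = 3 * radius_um,
                          max_loop_perimeter_um = 10 * radius_um)
  g2 <- prune_spurs(g2, 3 * radius_um)
  dissolve_chains(g2)
}

same_topology <- function(ga, gb) {
  nrow(ga$nodes) == nrow(gb$nodes) && nrow(ga$edges) == nrow(gb$edges) &&
    identical(sort(ga$nodes$degree), sort(gb$nodes$degree)) &&
    cyclomatic_number(ga) == cyclomatic_number(gb)
}
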
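# Binary vessel volume -> measured spatial graph.

#' Skeletonize a binary vessel volume
#'
#' Topology-preserving 3D curve thinning: border voxels that are simple
#' points (their deletion changes neither foreground nor background
#' topology) are removed in six directional subiterations until
#' convergence; curve endpoints are protected. Foreground connectivity is
#' 26 throughout. Anisotropic volumes are resampled (nearest neighbour) to
#' isotropic voxels at the finest pitch before thinning, because the
#' simple-point characterization is defined on an isotropic lattice; the
#' returned skeleton lives on that grid with coordinates mapped back to
#' physical micrometres.
#'
#' @param vol `voxel_volume` with logical data.
#' @return `voxel_volume` containing the one-voxel-thick skeleton.
#' @export
skeletonize <- function(vol) {
  mask <- as_mask(vol)
  sp <- vol$spacing
  if (diff(range(sp)) > 1e-9) {
    s <- min(sp)
    dm <- dim(mask)
    nn <- pmax(1L, as.integer(round(dm * sp / s)))
    # nearest-neighbour resample onto the isotropic grid
    iz <- pmin(pmax(round((seq_len(nn[1]) - 1) * s / sp[1]) + 1, 1), dm[1])
    iy <- pmin(pmax(round((seq_len(nn[2]) - 1) * s / sp[2]) + 1, 1), dm[2])
    ix <- pmin(pmax(round((seq_len(nn[3]) - 1) * s / sp[3]) + 1, 1), dm[3])
    mask <- mask[iz, iy, ix, drop = FALSE]
    sp <- c(s, s, s)
  }
  sk <- .thin_cpp(as.logical(mask), as.integer(dim(mask)))
  voxel_volume(array(sk, dim(mask)), sp, vol$origin)
}

# endpoint-preserving 1-2-1 smoothing of a polyline (kills the half-voxel
# staircase of traced skeleton chains without flattening real curvature)
smooth_polyline <- function(p, iterations = 3) {
  n <- nrow(p)
  if (iterations <= 0 || n < 3) return(p)
  for (it in seq_len(iterations)) {
    q <- p
    q[2:(n - 1), ] <- (p[1:(n - 2), , drop = FALSE] +
                         2 * p[2:(n - 1), , drop = FALSE] +
                         p[3:n, , drop = FALSE]) / 4
    p <- q
  }
  p
}

# 26-neighbour table of skeleton voxels: n x 26 integer matrix of voxel ids
# (0 where no neighbour), plus coords and linear indices.
skel_neighbours <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  co <- arrayInd(idx, dm)
  map <- integer(prod(dm))
  map[idx] <- seq_len(n)
  offs <- all_offsets(26)
  nbr <- matrix(0L, n, nrow(offs))
  if (n == 0L) return(list(idx = idx, co = co, nbr = nbr, offs = offs))
  for (r in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (any(ok)) nbr[ok, r] <- map[lin_index(nb[ok, , drop = FALSE], dm)]
  }
  list(idx = idx, co = co, nbr = nbr, offs = offs)
}

#' Build a spatial graph from a skeleton
#'
#' Skeleton voxels with three or more 26-neighbours are clustered (adjacent
#' branch voxels merge into one node at their centroid), voxels with one
#' neighbour become end nodes, and the degree-2 chains between nodes become
#' edges carrying their centerline polyline in physical micrometres.
#' Components without any junction or end voxel (pure cycles) get a single
#' anchor node carrying a self-loop edge.
#'
#' Traced centerlines are lightly smoothed (endpoint-preserving moving
#' average, `smooth_iter` passes) so arc lengths are not inflated by the
#' voxel staircase.
#'
#' @param skel `voxel_volume` holding a one-voxel-thick skeleton.
#' @param smooth_iter centerline smoothing passes (0 disables).
#' @return a `vessel_graph`.
#' @export
build_graph <- function(skel, smooth_iter = 3) {
  mask <- as_mask(skel)
  sn <- skel_neighbours(mask)
  n <- length(sn$idx)
  empty <- vessel_graph(data.frame(z_um = numeric(0), y_um = numeric(0),
                                   x_um = numeric(0)),
                        data.frame(from = integer(0), to = integer(0)),
                        spacing = skel$spacing)
  if (n == 0) return(empty)
  deg <- rowSums(sn$nbr > 0L)
  pos <- index_to_um(skel, sn$co)

  # cluster adjacent branch voxels (deg >= 3)
  node_of <- integer(n)          # node id per voxel (0 = interior chain voxel)
  nxt <- 0L
  br <- which(deg >= 3)
  if (length(br)) {
    sub <- igraph::make_empty_graph(length(br), directed = FALSE)
    pairs <- NULL
    rk <- integer(n); rk[br] <- seq_along(br)
    for (r in seq_len(ncol(sn$nbr))) {
      a <- br; b <- sn$nbr[br, r]
      keep <- b > 0L & deg[pmax(b, 1L)] >= 3 & b > a   # half to avoid dupes
      if (any(keep)) pairs <- cbind(pairs, rbind(rk[a[keep]], rk[b[keep]]))
    }
    if (!is.null(pairs)) sub <- igraph::add_edges(sub, pairs)
    memb <- igraph::components(sub)$membership
    node_of[br] <- memb
    nxt <- max(memb)
  }
  ends <- which(deg <= 1)
  if (length(ends)) {
    node_of[ends] <- nxt + seq_along(ends)
    nxt <- nxt + length(ends)
  }
  # pure-cycle components: anchor at the smallest linear index
  if (any(node_of == 0L)) {
    gall <- igraph::make_empty_graph(n, directed = FALSE)
    pr <- NULL
    for (r in seq_len(ncol(sn$nbr))) {
      b <- sn$nbr[, r]
      keep <- b > seq_len(n)
      if (any(keep)) pr <- cbind(pr, rbind(which(keep), b[keep]))
    }
    if (!is.null(pr)) gall <- igraph::add_edges(gall, pr)
    cm <- igraph::components(gall)$membership
    for (cc in unique(cm)) {
      vs <- which(cm == cc)
      if (all(node_of[vs] == 0L)) {
        nxt <- nxt + 1L
        node_of[vs[which.min(sn$idx[vs])]] <- nxt
      }
    }
  }

  nn <- nxt
  # node positions: centroid of member voxels
  zs <- tapply(pos[node_of > 0, 1], node_of[node_of > 0], mean)
  ys <- tapply(pos[node_of > 0, 2], node_of[node_of > 0], mean)
  xs <- tapply(pos[node_of > 0, 3], node_of[node_of > 0], mean)
  ord <- as.integer(names(zs))
  npos <- matrix(NA_real_, nn, 3)
  npos[ord, ] <- cbind(as.numeric(zs), as.numeric(ys), as.numeric(xs))

  # trace edges: start from every (node voxel, neighbour outside its node)
  used <- matrix(FALSE, n, ncol(sn$nbr))
  rev_off <- match(
    apply(-sn$offs, 1, paste, collapse = ","),
    apply(sn$offs, 1, paste, collapse = ","))
  from <- to <- integer(0)
  poly <- list()
  node_voxels <- which(node_of > 0L)
  node_voxels <- node_voxels[order(sn$idx[node_voxels])]
  for (v in node_voxels) {
    for (r in seq_len(ncol(sn$nbr))) {
      w <- sn$nbr[v, r]
      if (w == 0L || used[v, r]) next
      if (node_of[w] == node_of[v] && node_of[w] > 0L && deg[v] >= 3 && deg[w] >= 3)
        next  # intra-cluster adjacency
      used[v, r] <- TRUE
      path <- integer(0)
      prev <- v; cur <- w
      while (node_of[cur] == 0L) {
        path <- c(path, cur)
        nbrs <- sn$nbr[cur, ]
        nxts <- nbrs[nbrs > 0L & nbrs != prev]
        if (length(nxts) != 1L) {
          # defensive: chain voxel must have exactly one continuation
          nxts <- nxts[1]
        }
        prev <- cur; cur <- nxts
      }
      # mark the arriving directed step used on the far end
      rlast <- which(sn$nbr[cur, ] == prev)
      if (length(rlast)) used[cur, rlast[1]] <- TRUE
      from <- c(from, node_of[v]); to <- c(to, node_of[cur])
      pl <- rbind(npos[node_of[v], , drop = FALSE],
                  pos[path, , drop = FALSE],
                  npos[node_of[cur], , drop = FALSE])
      poly[[length(poly) + 1L]] <- smooth_polyline(pl, smooth_iter)
    }
  }
  vessel_graph(data.frame(z_um = npos[, 1], y_um = npos[, 2], x_um = npos[, 3]),
               data.frame(from = from, to = to), poly,
               spacing = skel$spacing)
}

#' Remove short terminal spurs from a vessel graph
#'
#' Terminal edges (one endpoint of degree 1) shorter than `min_length_um`
#' are removed iteratively; degree-2 nodes created by a removal are
#' dissolved by concatenating their two edges. Loops are never removed, so
#' the cyclomatic number is invariant.
#'
#' @param g vessel graph.
#' @param min_length_um non-negative length threshold in micrometres.
#' @return pruned `vessel_graph`.
#' @export
prune_spurs <- function(g, min_length_um) {
  stopifnot(min_length_um >= 0)
  if (min_length_um == 0 || nrow(g$edges) == 0) return(g)
  nodes <- g$nodes; edges <- g$edges; poly <- g$polylines
  init_deg <- g$nodes$degree
  repeat {
    deg <- integer(nrow(nodes))
    if (nrow(edges)) deg <- tabulate(edges$from, nrow(nodes)) +
        tabulate(edges$to, nrow(nodes))
    terminal <- edges$from != edges$to &
      (deg[edges$from] == 1L | deg[edges$to] == 1L)
    drop <- terminal & edges$length_um < min_length_um
    changed <- FALSE
    if (any(drop)) {
      edges <- edges[!drop, , drop = FALSE]
      poly <- poly[!drop]
      changed <- TRUE
    }
    # dissolve degree-2 nodes formed by removals (two distinct incident edges)
    repeat {
      deg <- integer(nrow(nodes))
      if (nrow(edges)) deg <- tabulate(edges$from, nrow(nodes)) +
          tabulate(edges$to, nrow(nodes))
      cand <- which(deg == 2L & init_deg != 2L)
      done <- TRUE
      for (nd in cand) {
        inc <- which(edges$from == nd | edges$to == nd)
        if (length(inc) != 2L) next   # a self-loop at nd: leave as anchor
        e1 <- inc[1]; e2 <- inc[2]
        p1 <- poly[[e1]]; p2 <- poly[[e2]]
        if (edges$to[e1] != nd) { p1 <- p1[nrow(p1):1, , drop = FALSE]
          tmp <- edges$from[e1]
          edges$from[e1] <- edges$to[e1]; edges$to[e1] <- tmp }
        a <- edges$from[e1]
        if (edges$from[e2] != nd) { p2 <- p2[nrow(p2):1, , drop = FALSE]
          b <- edges$from[e2]
        } else b <- edges$to[e2]
        poly[[e1]] <- rbind(p1, p2[-1, , drop = FALSE])
        edges$from[e1] <- a; edges$to[e1] <- b
        edges <- edges[-e2, , drop = FALSE]
        poly <- poly[-e2]
        done <- FALSE
        changed <- TRUE
        break
      }
      if (done) break
    }
    if (!changed) break
  }
  # drop nodes isolated by pruning (had edges before, none now)
  deg <- integer(nrow(nodes))
  if (nrow(edges)) deg <- tabulate(edges$from, nrow(nodes)) +
      tabulate(edges$to, nrow(nodes))
  keep <- !(deg == 0L & init_deg > 0L)
  remap <- cumsum(keep)
  nodes <- nodes[keep, , drop = FALSE]
  if (nrow(edges)) {
    edges$from <- remap[edges$from]
    edges$to <- remap[edges$to]
  }
  vessel_graph(nodes[, c("z_um", "y_um", "x_um")],
               edges[, c("from", "to")], poly, spacing = attr(g, "spacing"))
}

#' Measure edge geometry and radii against the source mask
#'
#' Lengths are polyline arc lengths, tortuosity is arc length over endpoint
#' chord (undefined for self-loops, reported `NA`), and the mean radius of
#' each edge is the mean of the Euclidean distance to the vessel wall
#' (distance transform of the background) sampled along the centerline,
#' corrected by half a voxel pitch for the centre-to-centre offset of the
#' first background voxel.
#'
#' @param g vessel graph derived from `mask`.
#' @param mask `voxel_volume` the graph was skeletonized from.
#' @return `g` with `mean_radius_um` filled in.
#' @export
measure_edges <- function(g, mask) {
  sp_g <- attr(g, "spacing")
  # the skeleton grid may be the isotropic resample of the mask grid: its
  # finest pitch must match, and the graph must live inside the mask extent
  if (!is.null(sp_g) && abs(min(sp_g) - min(mask$spacing)) > 1e-6)
    stop("mask/graph spacing mismatch")
  allp <- do.call(rbind, g$polylines)
  if (!is.null(allp) && nrow(allp)) {
    hi <- mask$origin + (dim(mask$data) - 1) * mask$spacing + max(mask$spacing)
    if (any(apply(allp, 2, min) < mask$origin - max(mask$spacing)) ||
        any(apply(allp, 2, max) > hi))
      stop("mask/graph spacing mismatch: graph outside the mask grid")
  }
  m <- as_mask(mask)
  dwall <- distance_transform(!m, spacing = mask$spacing)
  half <- 0.5 * min(mask$spacing)
  step <- min(mask$spacing)
  g$edges$mean_radius_um <- vapply(seq_len(nrow(g$edges)), function(e) {
    p <- g$polylines[[e]]
    # resample the polyline at fine arc steps for a stable mean
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    if (s[length(s)] <= 0) return(NA_real_)
    at <- seq(0, s[length(s)], by = step)
    zi <- approx(s, p[, 1], xout = at)$y
    yi <- approx(s, p[, 2], xout = at)$y
    xi <- approx(s, p[, 3], xout = at)$y
    r <- interp3(dwall, mask$spacing, mask$origin, cbind(zi, yi, xi))
    max(mean(r) - half, 0)
  }, numeric(1))
  g
}

#' Label vessel voxels by nearest macro-vessel tree
#'
#' Every mask voxel is assigned to the hepatic-vein tree (label 1, seeded at
#' central-vein voxels) or the portal tree (label 2) by shorter geodesic
#' (within-mask) distance to the respective seed set; ties go to the
#' central-vein tree. Voxels unreachable from both seed sets stay 0.
#'
#' @param mask logical `voxel_volume` of the vasculature.
#' @param cv_seeds,pv_seeds integer matrices of voxel indices (rows of
#'   (z, y, x)) or logical arrays; must be nonempty and inside the mask.
#' @return integer `voxel_volume` of labels (0 = unknown).
#' @export
label_macro_trees <- function(mask, cv_seeds, pv_seeds) {
  m <- as_mask(mask)
  dm <- dim(m)
  out <- voxel_volume(array(0L, dm), mask$spacing, mask$origin)
  idx <- which(m)
  if (!length(idx)) return(out)
  seed_idx <- function(s) {
    if (is.logical(s) || (inherits(s, "voxel_volume") && is.logical(s$data))) {
      if (inherits(s, "voxel_volume")) s <- s$data
      which(s)
    } else {
      s <- matrix(as.integer(s), ncol = 3)
      lin_index(s, dm)
    }
  }
  cv <- seed_idx(cv_seeds); pv <- seed_idx(pv_seeds)
  if (!length(cv) || !length(pv)) stop("seed sets must be nonempty")
  if (!all(m[cv]) || !all(m[pv])) stop("seed outside mask")

  n <- length(idx)
  map <- integer(prod(dm)); map[idx] <- seq_len(n)
  co <- arrayInd(idx, dm)
  offs <- half_offsets(26)
  from <- to <- integer(0); w <- numeric(0)
  sp <- mask$spacing
  for (r in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    tid <- integer(sum(ok))
    tid <- map[lin_index(nb[ok, , drop = FALSE], dm)]
    keep <- tid > 0L
    if (!any(keep)) next
    from <- c(from, which(ok)[keep]); to <- c(to, tid[keep])
    w <- c(w, rep(sqrt(sum((offs[r, ] * sp)^2)), sum(keep)))
  }
  # virtual sources n+1 (cv) and n+2 (pv) at zero cost
  vg <- igraph::make_empty_graph(n + 2L, directed = FALSE)
  ed <- cbind(rbind(from, to),
              rbind(rep(n + 1L, length(cv)), map[cv]),
              rbind(rep(n + 2L, length(pv)), map[pv]))
  wts <- c(w, rep(0, length(cv) + length(pv)))
  vg <- igraph::add_edges(vg, ed)
  d <- igraph::distances(vg, v = c(n + 1L, n + 2L), to = seq_len(n),
                         weights = wts)
  lab <- integer(n)
  reach <- is.finite(d[1, ]) | is.finite(d[2, ])
  lab[reach & d[1, ] <= d[2, ]] <- 1L
  lab[reach & d[1, ] > d[2, ]] <- 2L
  arr <- array(0L, dm); arr[idx] <- lab
  out$data <- arr
  out
}

#' Dissolve all degree-2 nodes of a graph
#'
#' Concatenates the two edges at every degree-2 node (pure-cycle anchors
#' are kept), yielding the branch-point-to-branch-point view of a graph
#' whose chains carry intermediate nodes. Used when comparing a generated
#' graph (whose spanning tree leaves degree-2 nodes) with a graph
#' re-extracted from a skeleton, where chains have no nodes.
#'
#' @param g vessel graph.
#' @return `vessel_graph` without dissolvable degree-2 nodes.
#' @export
dissolve_chains <- function(g) {
  nodes <- g$nodes; edges <- g$edges; poly <- g$polylines
  repeat {
    deg <- integer(nrow(nodes))
    if (nrow(edges)) deg <- tabulate(edges$from, nrow(nodes)) +
        tabulate(edges$to, nrow(nodes))
    done <- TRUE
    for (nd in which(deg == 2L)) {
      inc <- which(edges$from == nd | edges$to == nd)
      if (length(inc) != 2L) next  # self-loop anchor
      e1 <- inc[1]; e2 <- inc[2]
      p1 <- poly[[e1]]; p2 <- poly[[e2]]
      if (edges$to[e1] != nd) { p1 <- p1[nrow(p1):1, , drop = FALSE]
        tmp <- edges$from[e1]
        edges$from[e1] <- edges$to[e1]; edges$to[e1] <- tmp }
      a <- edges$from[e1]
      if (edges$from[e2] != nd) { p2 <- p2[nrow(p2):1, , drop = FALSE]
        b <- edges$from[e2]
      } else b <- edges$to[e2]
      poly[[e1]] <- rbind(p1, p2[-1, , drop = FALSE])
      edges$from[e1] <- a; edges$to[e1] <- b
      edges <- edges[-e2, , drop = FALSE]
      poly <- poly[-e2]
      done <- FALSE
      break
    }
    if (done) break
  }
  deg <- integer(nrow(nodes))
  if (nrow(edges)) deg <- tabulate(edges$from, nrow(nodes)) +
      tabulate(edges$to, nrow(nodes))
  keep <- deg > 0L | g$nodes$degree == 0L
  remap <- cumsum(keep)
  nodes <- nodes[keep, , drop = FALSE]
  if (nrow(edges)) { edges$from <- remap[edges$from]; edges$to <- remap[edges$to] }
  vessel_graph(nodes[, c("z_um", "y_um", "x_um")], edges[, c("from", "to")],
               poly, spacing = attr(g, "spacing"))
}

#' Consolidate junction artifacts of a skeleton-derived graph
#'
#' Thinning a thick junction can split one branch point into a tight
#' cluster of junction nodes joined by voxel-scale edges, occasionally
#' with a micro-loop inside the cluster. This step (i) contracts edges
#' shorter than `merge_um` whose two endpoints are both junctions
#' (degree >= 3), and (ii) collapses independent loops whose perimeter is
#' below `max_loop_perimeter_um` (including voxel-scale self-loops) into a
#' single node. Genuine loops, whose perimeter is at the edge-length
#' scale, are untouched; both thresholds default to off.
#'
#' @param g vessel graph from [build_graph()].
#' @param merge_um junction-junction contraction length (0 = off).
#' @param max_loop_perimeter_um micro-loop collapse perimeter (0 = off).
#' @return consolidated `vessel_graph`.
#' @export
consolidate_graph <- function(g, merge_um = 0, max_loop_perimeter_um = 0) {
  nodes <- as.matrix(g$nodes[, c("z_um", "y_um", "x_um")])
  edges <- g$edges; poly <- g$polylines
  refresh_deg <- function() {
    d <- integer(nrow(nodes))
    if (nrow(edges)) d <- tabulate(edges$from, nrow(nodes)) +
        tabulate(edges$to, nrow(nodes))
    d
  }
  contract <- function(eids) {
    # merge the node set of the given edges into one node
    nds <- sort(unique(c(edges$from[eids], edges$to[eids])))
    tgt <- nds[1]
    nodes[tgt, ] <<- colMeans(nodes[nds, , drop = FALSE])
    sel <- edges$from %in% nds; edges$from[sel] <<- tgt
    sel <- edges$to %in% nds; edges$to[sel] <<- tgt
    drop <- sort(unique(c(which(seq_len(nrow(edges)) %in% eids),
                          which(edges$from == tgt & edges$to == tgt &
                                  seq_len(nrow(edges)) %in% eids))))
    edges <<- edges[-eids, , drop = FALSE]
    poly <<- poly[-eids]
    # re-anchor polylines of surviving edges at the merged node
    for (e in which(edges$from == tgt)) poly[[e]][1, ] <<- nodes[tgt, ]
    for (e in which(edges$to == tgt)) poly[[e]][nrow(poly[[e]]), ] <<- nodes[tgt, ]
  }
  if (merge_um > 0) {
    repeat {
      deg <- refresh_deg()
      len <- vapply(poly, polyline_length, numeric(1))
      cand <- which(edges$from != edges$to & len < merge_um &
                      deg[edges$from] >= 3 & deg[edges$to] >= 3)
      if (!length(cand)) break
      contract(cand[which.min(len[cand])])
    }
  }
  if (max_loop_perimeter_um > 0) {
    repeat {
      len <- vapply(poly, polyline_length, numeric(1))
      tiny_self <- which(edges$from == edges$to & len < max_loop_perimeter_um)
      if (length(tiny_self)) {
        edges <- edges[-tiny_self, , drop = FALSE]
        poly <- poly[-tiny_self]
        next
      }
      gg <- vessel_graph(data.frame(z_um = nodes[, 1], y_um = nodes[, 2],
                                    x_um = nodes[, 3]),
                         edges[, c("from", "to")], poly)
      lc <- loop_census(gg)
      if (!lc$total) break
      per <- vapply(lc$loops, function(ids) sum(gg$edges$length_um[ids]),
                    numeric(1))
      small <- which(per < max_loop_perimeter_um & lengths(lc$loops) > 1)
      if (!length(small)) break
      contract(lc$loops[[small[which.min(per[small])]]])
    }
  }
  # drop nodes isolated by the consolidation
  deg <- refresh_deg()
  keep <- deg > 0L | g$nodes$degree == 0L
  remap <- cumsum(keep)
  nodes <- nodes[keep, , drop = FALSE]
  if (nrow(edges)) { edges$from <- remap[edges$from]; edges$to <- remap[edges$to] }
  vessel_graph(data.frame(z_um = nodes[, 1], y_um = nodes[, 2],
                          x_um = nodes[, 3]),
               edges[, c("from", "to")], poly, spacing = attr(g, "spacing"))
}
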
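# Deterministic synthetic cleared-liver phantoms with exact ground truth.
#
# The phantom emulates the mesoscale features the pipeline quantifies:
# lobules as non-overlapping solid ellipsoids (oblate by default) seeded by
# a central-vein axis and portal spheres on the equatorial boundary; a
# loop-rich sinusoid network on a jittered lattice inside the lobules;
# cells placed so their true distribution index follows a prescribed
# truncated lognormal; and spherical tumor foci with macrophage shells.
# Every random draw flows from the spec seed through fixed per-component
# streams (graph = 1, lobules = 2, cells = 3, metastases = 4), so adding
# one phantom element does not perturb the others.

#' Phantom specification
#'
#' Defaults mirror the acquisition and the healthy-liver measurements the
#' pipeline targets: voxel spacing 2 x 1.19 x 1.19 um (z, y, x), sinusoid
#' edge length 24.91 um, sinusoid radius 2.92 um, a loop excess of 0.37
#' loops per node (edge/node ratio about 1.37), oblate lobules with
#' a = b = 2c, 322 cells per lobule, and a boundary-skewed distribution
#' index law. Grid and lobule radius are desk-scale.
#'
#' @param grid_shape voxels per axis (z, y, x).
#' @param spacing um per voxel per axis (z, y, x).
#' @param n_lobules number of lobules.
#' @param lobule_radius_um volume-equivalent lobule radius (mean).
#' @param lobule_radius_jitter_um +/- uniform jitter on the radius.
#' @param axis_ratios relative semi-axes in (z, y, x); `c(1, 2, 2)` is an
#'   oblate disc in the xy-plane.
#' @param sinusoid_edge_length_um mean sinusoid edge length.
#' @param sinusoid_radius_um sinusoid tube radius.
#' @param loop_excess target cyclomatic number (edges - nodes +
#'   components); `NULL` derives `round(0.37 * n_nodes)`.
#' @param n_nodes node budget; `NULL` fills the lobules at the lattice
#'   pitch.
#' @param edge_bow sagitta of the edge bow as a fraction of edge length
#'   (0 gives straight edges; the default 0.22 yields tortuosity near
#'   1.13).
#' @param cv_radius_um,pv_radius_um central-vein cylinder and portal
#'   sphere radii.
#' @param n_portal_per_lobule portal spheres per lobule boundary.
#' @param rho_lognormal `(mu, sigma)` of the (0,1]-truncated lognormal law
#'   of the cell distribution index.
#' @param n_cells_per_lobule cells per lobule.
#' @param cell_radius_um cell ball radius for rasterization.
#' @param metastasis_spec `NULL` or [metastasis_phantom_spec()].
#' @param seed integer master seed.
#' @return validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 192, 192),
                         spacing = c(2, 1.19, 1.19),
                         n_lobules = 1,
                         lobule_radius_um = 80,
                         lobule_radius_jitter_um = 5,
                         axis_ratios = c(1, 2, 2),
                         sinusoid_edge_length_um = 24.91,
                         sinusoid_radius_um = 2.92,
                         loop_excess = NULL,
                         n_nodes = NULL,
                         edge_bow = 0.22,
                         cv_radius_um = 10,
                         pv_radius_um = 6,
                         n_portal_per_lobule = 6,
                         rho_lognormal = c(mu = -1.7, sigma = 0.8),
                         n_cells_per_lobule = 322,
                         cell_radius_um = 3,
                         metastasis_spec = NULL,
                         seed = 1) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Metastasis block of a phantom specification
#'
#' @param n_foci number of tumor foci.
#' @param diameter_range_um focus diameter range (uniform draw).
#' @param shell_thickness_um macrophage shell thickness outward from the
#'   tumor surface.
#' @param shell_fill fraction of shell voxels carrying macrophage signal.
#' @export
metastasis_phantom_spec <- function(n_foci = 6,
                                    diameter_range_um = c(30, 90),
                                    shell_thickness_um = 30,
                                    shell_fill = 0.5) {
  stopifnot(n_foci >= 1, all(diameter_range_um > 0),
            diameter_range_um[1] <= diameter_range_um[2],
            shell_thickness_um > 0, shell_fill >= 0, shell_fill <= 1)
  list(n_foci = n_foci, diameter_range_um = diameter_range_um,
       shell_thickness_um = shell_thickness_um, shell_fill = shell_fill)
}

validate_phantom_spec <- function(spec) {
  pos <- c("spacing", "lobule_radius_um", "sinusoid_edge_length_um",
           "sinusoid_radius_um", "cv_radius_um", "pv_radius_um")
  for (f in pos)
    if (any(!is.finite(spec[[f]])) || any(spec[[f]] <= 0))
      stop("phantom spec: ", f, " must be strictly positive")
  stopifnot(length(spec$grid_shape) == 3, all(spec$grid_shape >= 8),
            spec$n_lobules >= 1, spec$lobule_radius_jitter_um >= 0,
            all(spec$axis_ratios > 0), spec$edge_bow >= 0,
            length(spec$rho_lognormal) == 2,
            all(is.finite(spec$rho_lognormal)), spec$rho_lognormal[2] > 0,
            spec$n_cells_per_lobule >= 0, spec$cell_radius_um > 0)
  if (!is.null(spec$loop_excess) && spec$loop_excess < 0)
    stop("phantom spec: loop_excess must be non-negative")
  lobule_layout(spec)  # errors if the lobules cannot be packed
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> grid %s, spacing %s um, %d lobule(s) ",
                     "r=%g um, seed %d\n"),
              paste(x$grid_shape, collapse = "x"),
              paste(x$spacing, collapse = "x"),
              x$n_lobules, x$lobule_radius_um, x$seed))
  invisible(x)
}

# Deterministic lobule geometry: centres and semi-axes (z,y,x) in um.
lobule_layout <- function(spec) {
  with_seed(stream_seed(spec$seed, 2), {
    ext <- spec$grid_shape * spec$spacing
    norm <- prod(spec$axis_ratios)^(1 / 3)
    rads <- spec$lobule_radius_um +
      runif(spec$n_lobules, -1, 1) * spec$lobule_radius_jitter_um
    semis <- lapply(rads, function(r) spec$axis_ratios / norm * r)
    marg <- 2 * max(spec$spacing)
    # per-axis bounding semi-extent over all lobules
    rbax <- apply(do.call(rbind, semis), 2, max) + marg
    if (spec$n_lobules == 1) {
      centers <- list(ext / 2)
      if (any(rbax > ext / 2))
        stop("grid too small for the requested lobule")
    } else {
      if (any(2 * rbax > ext))
        stop("grid too small to contain ", spec$n_lobules,
             " non-overlapping lobules")
      ax_seq <- function(a) seq(rbax[a], ext[a] - rbax[a], by = 2 * rbax[a] + marg)
      cand <- as.matrix(expand.grid(z = ax_seq(1), y = ax_seq(2), x = ax_seq(3)))
      if (nrow(cand) < spec$n_lobules)
        stop("grid too small to contain ", spec$n_lobules,
             " non-overlapping lobules")
      centers <- lapply(seq_len(spec$n_lobules), function(i) cand[i, ])
    }
    lapply(seq_len(spec$n_lobules), function(i)
      list(center = as.numeric(centers[[i]]), semi = as.numeric(semis[[i]]),
           radius = rads[i]))
  })
}

# points inside the ellipsoid (optionally shrunk by margin_um)
ellipsoid_quad <- function(pts, lob, margin_um = 0) {
  s <- pmax(lob$semi - margin_um, 1e-6)
  d <- sweep(pts, 2, lob$center, "-")
  (d[, 1] / s[1])^2 + (d[, 2] / s[2])^2 + (d[, 3] / s[3])^2
}

#' Generate the lobule field of a phantom
#'
#' One central-vein cylinder per lobule (along the short axis), portal
#' spheres on the equatorial lobule boundary, and integer lobule labels
#' over the parenchyma (the ellipsoid interiors).
#'
#' @param spec a `phantom_spec`.
#' @return list of `cv_mask`, `pv_mask`, `lobule_labels` (voxel volumes)
#'   and the `layout` geometry.
#' @export
generate_lobule_field <- function(spec) {
  layout <- lobule_layout(spec)
  dm <- spec$grid_shape
  sp <- spec$spacing
  zc <- (seq_len(dm[1]) - 1) * sp[1]
  yc <- (seq_len(dm[2]) - 1) * sp[2]
  xc <- (seq_len(dm[3]) - 1) * sp[3]
  labels <- array(0L, dm)
  cv <- pv <- array(FALSE, dm)
  phase <- with_seed(stream_seed(spec$seed, 2) + 7L,
                     runif(spec$n_lobules, 0, 2 * pi))
  for (i in seq_along(layout)) {
    lob <- layout[[i]]
    lo <- pmax(floor((lob$center - lob$semi) / sp) - 1, 0) + 1
    hi <- pmin(ceiling((lob$center + lob$semi) / sp) + 1, dm)
    gz <- zc[lo[1]:hi[1]]; gy <- yc[lo[2]:hi[2]]; gx <- xc[lo[3]:hi[3]]
    pts <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
    inside <- ellipsoid_quad(pts, lob) <= 1
    sub <- array(inside, c(length(gz), length(gy), length(gx)))
    blk <- labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    blk[sub] <- i
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
    # central vein: cylinder along z through the centre
    dz <- abs(pts[, 1] - lob$center[1])
    rxy <- sqrt((pts[, 2] - lob$center[2])^2 + (pts[, 3] - lob$center[3])^2)
    cvin <- dz <= 0.8 * lob$semi[1] & rxy <= spec$cv_radius_um
    blk <- cv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    blk[array(cvin, dim(sub))] <- TRUE
    cv[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
    # portal spheres on the equatorial boundary
    th <- phase[i] + 2 * pi * (seq_len(spec$n_portal_per_lobule) - 1) /
      spec$n_portal_per_lobule
    for (t in th) {
      ctr <- lob$center + c(0, lob$semi[2] * cos(t), lob$semi[3] * sin(t))
      plo <- pmax(floor((ctr - spec$pv_radius_um) / sp), 0) + 1
      phi <- pmin(ceiling((ctr + spec$pv_radius_um) / sp) + 1, dm)
      if (any(plo > phi)) next
      pz <- zc[plo[1]:phi[1]]; py <- yc[plo[2]:phi[2]]; px <- xc[plo[3]:phi[3]]
      pp <- as.matrix(expand.grid(z = pz, y = py, x = px))
      din <- sqrt(rowSums(sweep(pp, 2, ctr, "-")^2)) <= spec$pv_radius_um
      blk <- pv[plo[1]:phi[1], plo[2]:phi[2], plo[3]:phi[3]]
      blk[array(din, c(length(pz), length(py), length(px)))] <- TRUE
      pv[plo[1]:phi[1], plo[2]:phi[2], plo[3]:phi[3]] <- blk
    }
  }
  list(cv_mask = voxel_volume(cv, sp),
       pv_mask = voxel_volume(pv, sp),
       lobule_labels = voxel_volume(labels, sp),
       layout = layout)
}

#' Generate the sinusoid network of a phantom
#'
#' Nodes are a jittered cubic lattice at the sinusoid edge-length pitch
#' inside the lobules; the edge set is the Euclidean minimum spanning tree
#' of the near-neighbour candidate graph (connected, zero loops) plus the
#' `loop_excess` shortest chords, so the achieved cyclomatic number equals
#' the target exactly. Edge centerlines are bowed quadratic arcs whose
#' sagitta sets the tortuosity.
#'
#' @param spec `phantom_spec`.
#' @param n_nodes,loop_excess override the spec fields.
#' @return a `vessel_graph`.
#' @export
generate_sinusoid_graph <- function(spec, n_nodes = spec$n_nodes,
                                    loop_excess = spec$loop_excess) {
  layout <- lobule_layout(spec)
  delta <- spec$sinusoid_edge_length_um
  margin <- spec$sinusoid_radius_um + spec$edge_bow * delta + 2 * max(spec$spacing)
  with_seed(stream_seed(spec$seed, 1), {
    pts <- NULL
    for (lob in layout) {
      nmax <- ceiling(lob$semi / delta)
      gz <- lob$center[1] + delta * (-nmax[1]:nmax[1])
      gy <- lob$center[2] + delta * (-nmax[2]:nmax[2])
      gx <- lob$center[3] + delta * (-nmax[3]:nmax[3])
      p <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
      p <- p + matrix(runif(length(p), -0.12, 0.12) * delta, nrow(p), 3)
      p <- p[ellipsoid_quad(p, lob, margin) <= 1, , drop = FALSE]
      pts <- rbind(pts, p)
    }
    if (is.null(pts) || nrow(pts) < 2)
      stop("lobules too small for the sinusoid lattice")
    if (!is.null(n_nodes)) {
      if (n_nodes > nrow(pts))
        stop("node budget ", n_nodes, " exceeds lattice capacity ", nrow(pts))
      ctr <- colMeans(pts)
      ord <- order(rowSums(sweep(pts, 2, ctr, "-")^2))
      pts <- pts[sort(ord[seq_len(n_nodes)]), , drop = FALSE]
    }
    nv <- nrow(pts)
    if (nv > 8000) stop("node budget too large for dense candidate search")
    D <- as.matrix(dist(pts))
    cand <- which(upper.tri(D) & D <= 1.45 * delta, arr.ind = TRUE)
    # bridge candidate-graph components so the MST spans everything
    cg <- igraph::graph_from_edgelist(cand, directed = FALSE)
    cg <- igraph::add_vertices(cg, max(0, nv - igraph::vcount(cg)))
    memb <- igraph::components(cg)$membership
    while (max(memb) > 1) {
      a <- which(memb == 1); b <- which(memb != 1)
      sub <- D[a, b, drop = FALSE]
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      cand <- rbind(cand, c(a[ij[1]], b[ij[2]]))
      memb[memb == memb[b[ij[2]]]] <- 1
    }
    w <- D[cand]
    cg <- igraph::graph_from_edgelist(cand, directed = FALSE)
    mstg <- igraph::mst(cg, weights = w)
    mst_el <- igraph::as_edgelist(mstg, names = FALSE)
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    in_mst <- key(cand) %in% key(mst_el)
    if (is.null(loop_excess)) loop_excess <- round(0.37 * nv)
    extra <- which(!in_mst)
    extra <- extra[order(w[extra], extra)]
    if (length(extra) < loop_excess)
      stop("loop_excess ", loop_excess, " infeasible: only ", length(extra),
           " candidate chords for ", nv, " nodes")
    deg <- tabulate(as.vector(mst_el), nv)
    chosen <- integer(0)
    for (pass in 1:2) {
      for (e in extra) {
        if (length(chosen) >= loop_excess) break
        if (e %in% chosen) next
        u <- cand[e, 1]; v <- cand[e, 2]
        if (pass == 1 && (deg[u] >= 4 || deg[v] >= 4)) next
        chosen <- c(chosen, e)
        deg[u] <- deg[u] + 1; deg[v] <- deg[v] + 1
      }
    }
    el <- rbind(mst_el, cand[chosen, , drop = FALSE])
    # bowed centerlines: quadratic arc with sagitta edge_bow * length
    poly <- vector("list", nrow(el))
    for (e in seq_len(nrow(el))) {
      p0 <- pts[el[e, 1], ]; p1 <- pts[el[e, 2], ]
      L <- sqrt(sum((p1 - p0)^2))
      if (spec$edge_bow <= 0 || L <= 0) next
      u <- (p1 - p0) / L
      a <- c(-u[2], u[1], 0)
      if (sum(a^2) < 1e-12) a <- c(0, -u[3], u[2])
      a <- a / sqrt(sum(a^2))
      b <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
             u[1] * a[2] - u[2] * a[1])
      th <- runif(1, 0, 2 * pi)
      perp <- cos(th) * a + sin(th) * b
      tt <- seq(0, 1, length.out = max(7, ceiling(L / 3)))
      sag <- spec$edge_bow * L
      arc <- outer(1 - tt, p0) + outer(tt, p1) +
        outer(4 * tt * (1 - tt) * sag, perp)
      poly[[e]] <- arc
    }
    vessel_graph(data.frame(z_um = pts[, 1], y_um = pts[, 2], x_um = pts[, 3]),
                 data.frame(from = el[, 1], to = el[, 2]), poly,
                 spacing = spec$spacing)
  })
}

#' Rasterize a vessel graph into a boolean tube volume
#'
#' Marks every voxel whose centre lies within `radius_um` of an edge
#' centerline (the centerlines are sampled at half the finest voxel
#' pitch); tube cross-sections respect anisotropic spacing.
#'
#' @param graph `vessel_graph`.
#' @param spacing voxel spacing (z, y, x) um.
#' @param radius_um tube radius.
#' @param grid_shape,origin optional target grid; defaults to the graph
#'   bounding box plus a margin.
#' @return logical `voxel_volume`.
#' @export
rasterize_graph <- function(graph, spacing, radius_um,
                            grid_shape = NULL, origin = NULL) {
  if (radius_um < max(spacing) / 2)
    warning("tube radius below half the largest voxel pitch; ",
            "rasterized tubes may disconnect")
  allp <- do.call(rbind, graph$polylines)
  if (is.null(allp) || nrow(allp) == 0) {
    if (is.null(grid_shape)) grid_shape <- c(8, 8, 8)
    if (is.null(origin)) origin <- c(0, 0, 0)
    return(voxel_volume(array(FALSE, grid_shape), spacing, origin))
  }
  pad <- radius_um + 2 * max(spacing)
  if (is.null(origin)) origin <- apply(allp, 2, min) - pad
  if (is.null(grid_shape))
    grid_shape <- as.integer(ceiling((apply(allp, 2, max) + pad - origin) /
                                       spacing)) + 1L
  dm <- as.integer(grid_shape)
  vol <- array(FALSE, dm)
  # precompute ball offsets in voxel units
  nr <- ceiling(radius_um / spacing)
  offs <- as.matrix(expand.grid(dz = -nr[1]:nr[1], dy = -nr[2]:nr[2],
                                dx = -nr[3]:nr[3]))
  keep <- sqrt(rowSums(sweep(offs, 2, spacing, "*")^2)) <= radius_um
  offs <- offs[keep, , drop = FALSE]
  step <- min(spacing) / 2
  for (p in graph$polylines) {
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    total <- s[length(s)]
    at <- if (total <= 0) 0 else seq(0, total, by = step)
    sz <- approx(s, p[, 1], xout = at)$y
    sy <- approx(s, p[, 2], xout = at)$y
    sx <- approx(s, p[, 3], xout = at)$y
    ijk <- cbind(round((sz - origin[1]) / spacing[1]),
                 round((sy - origin[2]) / spacing[2]),
                 round((sx - origin[3]) / spacing[3])) + 1
    ijk <- unique(ijk)
    for (r in seq_len(nrow(offs))) {
      q <- ijk + matrix(offs[r, ], nrow(ijk), 3, byrow = TRUE)
      ok <- q[, 1] >= 1 & q[, 1] <= dm[1] & q[, 2] >= 1 & q[, 2] <= dm[2] &
        q[, 3] >= 1 & q[, 3] <= dm[3]
      if (any(ok)) vol[q[ok, , drop = FALSE]] <- TRUE
    }
  }
  voxel_volume(vol, spacing, origin)
}

#' Scatter cells with a prescribed distribution-index law
#'
#' For each cell a target rho is drawn from the (0,1]-truncated lognormal;
#' a random ray is cast from a random central-vein voxel of the cell's
#' lobule to the lobule boundary, and the cell is placed at the point on
#' the ray where the measured `D2 / (D1 + D2)` (from the distance maps of
#' the actual masks) equals the target, found by bisection. The stored
#' `D1_um`, `D2_um` and `rho` are therefore self-consistent with the masks
#' by construction. Cells are allocated to lobules proportionally to
#' lobule volume.
#'
#' @param lobule_labels integer `voxel_volume`.
#' @param cv_mask logical `voxel_volume` (a central vein inside every
#'   lobule).
#' @param rho_lognormal `(mu, sigma)` of the target law.
#' @param n total number of cells (>= 1).
#' @param seed RNG seed for this component.
#' @param rho_values optional explicit rho targets (overrides the draw).
#' @return data.frame of cell records with true geometry.
#' @export
scatter_cells <- function(lobule_labels, cv_mask, rho_lognormal, n, seed = 1,
                          rho_values = NULL) {
  if (any(!is.finite(rho_lognormal))) stop("lognormal parameters must be finite")
  if (n < 1) stop("n must be at least 1")
  lab <- lobule_labels$data
  sp <- lobule_labels$spacing
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) stop("no lobule labels present")
  counts <- tabulate(lab[lab > 0L], nbins = max(ids))[ids]
  alloc <- floor(n * counts / sum(counts))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  d1map <- distance_transform(cv_mask)
  dm <- dim(lab)
  out <- list()
  with_seed(stream_seed(seed, 3), {
    rho_all <- if (is.null(rho_values))
      rtlnorm01(n, rho_lognormal[1], rho_lognormal[2]) else rep_len(rho_values, n)
    done <- 0L
    for (li in seq_along(ids)) {
      ni <- alloc[li]
      if (ni == 0) next
      i <- ids[li]
      cvv <- which(cv_mask$data & lab == i)
      if (!length(cvv)) stop("lobule ", i, " has no central-vein voxels")
      d2map <- distance_transform(lab != i, spacing = sp)
      rho_t <- rho_all[done + seq_len(ni)]
      h <- min(sp) / 2
      march <- function(opos, u) {
        # arc distance to the lobule exit along each ray
        k <- nrow(opos)
        tmax <- rep(0, k); alive <- rep(TRUE, k); tcur <- rep(h, k)
        lim <- 4 * max(dm * sp)
        while (any(alive)) {
          pos <- opos[alive, , drop = FALSE] + tcur[alive] * u[alive, , drop = FALSE]
          ijk <- um_to_index(lobule_labels, pos)
          inside <- lab[ijk] == i &
            pos[, 1] >= 0 & pos[, 2] >= 0 & pos[, 3] >= 0 &
            pos[, 1] <= (dm[1] - 1) * sp[1] & pos[, 2] <= (dm[2] - 1) * sp[2] &
            pos[, 3] <= (dm[3] - 1) * sp[3]
          w <- which(alive)
          tmax[w[inside]] <- tcur[w[inside]]
          alive[w[!inside]] <- FALSE
          tcur[w[inside]] <- tcur[w[inside]] + h
          if (any(alive) && all(tcur[alive] > lim)) break
        }
        tmax
      }
      draw_rays <- function(k) {
        ov <- cvv[sample.int(length(cvv), k, replace = TRUE)]
        u <- matrix(rnorm(3 * k), k, 3)
        list(opos = index_to_um(lobule_labels, arrayInd(ov, dm)),
             u = u / sqrt(rowSums(u^2)))
      }
      rays <- draw_rays(ni)
      opos <- rays$opos; u <- rays$u
      rho_at <- function(tt) {
        pos <- opos + tt * u
        d1 <- interp3(d1map, sp, lobule_labels$origin, pos)
        d2 <- interp3(d2map, sp, lobule_labels$origin, pos)
        d2 / pmax(d1 + d2, 1e-9)
      }
      tmax <- march(opos, u)
      # a ray exiting near the central vein (e.g. through the lobule cap)
      # cannot reach a low rho target: redraw such rays
      for (try in 1:60) {
        bad <- rho_at(tmax) > rho_t + 1e-3
        if (!any(bad)) break
        rr <- draw_rays(sum(bad))
        opos[bad, ] <- rr$opos; u[bad, ] <- rr$u
        tmax[bad] <- march(rr$opos, rr$u)
      }
      tlo <- rep(0, ni); thi <- tmax
      for (it in 1:40) {
        mid <- (tlo + thi) / 2
        f <- rho_at(mid)
        up <- f > rho_t
        tlo[up] <- mid[up]
        thi[!up] <- mid[!up]
      }
      tfin <- (tlo + thi) / 2
      pos <- opos + tfin * u
      d1 <- interp3(d1map, sp, lobule_labels$origin, pos)
      d2 <- interp3(d2map, sp, lobule_labels$origin, pos)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = done + seq_len(ni), z_um = pos[, 1], y_um = pos[, 2],
        x_um = pos[, 3], lobule_label = i, D1_um = d1, D2_um = d2,
        rho = distribution_index(d1, d2), rho_target = rho_t)
      done <- done + ni
    }
  })
  do.call(rbind, out)
}

#' Rasterize cell centroids as balls (or prolate ellipsoids)
#'
#' @param cell_table table with centroid columns.
#' @param template `voxel_volume` defining the grid.
#' @param radius_um cell radius (scalar or per cell).
#' @param aspect elongation factor along x (1 = sphere; volume is kept at
#'   the sphere volume), scalar or per cell.
#' @return logical `voxel_volume` cell channel.
#' @export
rasterize_cells <- function(cell_table, template, radius_um = 3, aspect = 1) {
  dm <- dim(template$data)
  sp <- template$spacing
  vol <- array(FALSE, dm)
  n <- nrow(cell_table)
  radius_um <- rep_len(radius_um, n)
  aspect <- rep_len(aspect, n)
  for (i in seq_len(n)) {
    ctr <- as.numeric(cell_table[i, c("z_um", "y_um", "x_um")])
    # semi-axes (z, y, x): elongated along x at constant volume
    k <- aspect[i]^(1 / 3)
    semi <- radius_um[i] * c(1 / k, 1 / k, aspect[i] / k)
    lo <- pmax(floor((ctr - semi - template$origin) / sp), 0) + 1
    hi <- pmin(ceiling((ctr + semi - template$origin) / sp) + 1, dm)
    if (any(lo > hi)) next
    gz <- template$origin[1] + (lo[1]:hi[1] - 1) * sp[1]
    gy <- template$origin[2] + (lo[2]:hi[2] - 1) * sp[2]
    gx <- template$origin[3] + (lo[3]:hi[3] - 1) * sp[3]
    pp <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
    d <- sweep(pp, 2, ctr, "-")
    inb <- (d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2 <= 1
    blk <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    blk[array(inb, c(length(gz), length(gy), length(gx)))] <- TRUE
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
  }
  voxel_volume(vol, sp, template$origin)
}

#' Generate the metastasis phantom
#'
#' Spherical tumor foci with known diameters, alternately placed touching
#' a portal sphere (periportal) and deep inside a lobule (intralobular),
#' each with a macrophage shell of the stated thickness and fill fraction.
#'
#' @param spec `phantom_spec` with a `metastasis_spec` block.
#' @param pv_mask,lobule_labels from [generate_lobule_field()].
#' @param seed RNG seed for this component.
#' @return list of `tumor_mask`, `gfp_mask` (voxel volumes) and
#'   `metastasis_table` with the true volumes, flags, locations and sigma.
#' @export
generate_metastasis_phantom <- function(spec, pv_mask, lobule_labels,
                                        seed = spec$seed) {
  ms <- spec$metastasis_spec
  if (is.null(ms)) stop("phantom spec has no metastasis block")
  lab <- lobule_labels$data
  sp <- lobule_labels$spacing
  dm <- dim(lab)
  layout <- lobule_layout(spec)
  with_seed(stream_seed(seed, 4), {
    diam <- runif(ms$n_foci, ms$diameter_range_um[1], ms$diameter_range_um[2])
    for (d in diam) {
      dlob <- 2 * min(vapply(layout, function(l) min(l$semi), numeric(1)))
      if (d >= dlob) stop("focus diameter ", round(d), " um exceeds lobule diameter")
    }
    pvidx <- which(pv_mask$data)
    if (!length(pvidx)) stop("portal mask is empty")
    pvpos <- index_to_um(pv_mask, arrayInd(pvidx, dm))
    centers <- matrix(NA_real_, ms$n_foci, 3)
    loc <- character(ms$n_foci)
    ext <- (dm - 1) * sp
    for (i in seq_len(ms$n_foci)) {
      lob <- layout[[1 + (i - 1) %% length(layout)]]
      placed <- FALSE
      for (try in 1:200) {
        if (i %% 2 == 1) {  # periportal: touching a portal sphere
          pv1 <- pvpos[sample.int(nrow(pvpos), 1), ]
          u <- lob$center - pv1
          u <- u / sqrt(sum(u^2))
          ctr <- pv1 + u * (diam[i] / 2 + spec$pv_radius_um * 0.5)
        } else {            # intralobular: inside the shrunken lobule
          room <- pmax(lob$semi - diam[i] / 2 - 2 * max(sp), 0)
          ctr <- lob$center + runif(3, -0.8, 0.8) * room
          # keep the focus surface well clear of the portal landmarks so
          # the true location class is unambiguous
          dpv <- sqrt(min(rowSums(sweep(pvpos, 2, ctr, "-")^2)))
          if (dpv - diam[i] / 2 - spec$pv_radius_um < 25) next
        }
        if (any(ctr - diam[i] / 2 < 0) || any(ctr + diam[i] / 2 > ext)) next
        if (i > 1) {
          sep <- sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                    2, ctr, "-")^2))
          if (any(sep < (diam[seq_len(i - 1)] + diam[i]) / 2 + 2 * max(sp)))
            next              # foci must not touch each other
        }
        centers[i, ] <- ctr
        loc[i] <- if (i %% 2 == 1) "periportal" else "intralobular"
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place ", ms$n_foci,
                        " non-overlapping foci; reduce n_foci or diameters")
    }
    zc <- (seq_len(dm[1]) - 1) * sp[1]
    yc <- (seq_len(dm[2]) - 1) * sp[2]
    xc <- (seq_len(dm[3]) - 1) * sp[3]
    crop <- function(i, extra) {
      rs <- diam[i] / 2 + extra
      lo <- pmax(floor((centers[i, ] - rs) / sp) - 1, 0) + 1
      hi <- pmin(ceiling((centers[i, ] + rs) / sp) + 1, dm)
      pp <- as.matrix(expand.grid(z = zc[lo[1]:hi[1]], y = yc[lo[2]:hi[2]],
                                  x = xc[lo[3]:hi[3]]))
      list(lo = lo, hi = hi,
           dims = c(hi[1] - lo[1] + 1, hi[2] - lo[2] + 1, hi[3] - lo[3] + 1),
           dd = sqrt(rowSums(sweep(pp, 2, centers[i, ], "-")^2)))
    }
    # pass 1: stamp all tumor spheres
    tumor <- array(FALSE, dm)
    tvox <- numeric(ms$n_foci)
    for (i in seq_len(ms$n_foci)) {
      cr <- crop(i, 0)
      tin <- array(cr$dd <= diam[i] / 2, cr$dims)
      blk <- tumor[cr$lo[1]:cr$hi[1], cr$lo[2]:cr$hi[2], cr$lo[3]:cr$hi[3]]
      blk[tin] <- TRUE
      tumor[cr$lo[1]:cr$hi[1], cr$lo[2]:cr$hi[2], cr$lo[3]:cr$hi[3]] <- blk
      tvox[i] <- sum(tin)
    }
    # pass 2: fill shells (outside any tumor voxel)
    gfp <- array(FALSE, dm)
    for (i in seq_len(ms$n_foci)) {
      cr <- crop(i, ms$shell_thickness_um)
      tblk <- tumor[cr$lo[1]:cr$hi[1], cr$lo[2]:cr$hi[2], cr$lo[3]:cr$hi[3]]
      sin_ <- array(cr$dd > diam[i] / 2 &
                      cr$dd <= diam[i] / 2 + ms$shell_thickness_um,
                    cr$dims) & !tblk
      fill <- runif(sum(sin_)) < ms$shell_fill
      gin <- array(FALSE, cr$dims)
      gin[sin_] <- fill
      blk <- gfp[cr$lo[1]:cr$hi[1], cr$lo[2]:cr$hi[2], cr$lo[3]:cr$hi[3]]
      blk[gin] <- TRUE
      gfp[cr$lo[1]:cr$hi[1], cr$lo[2]:cr$hi[2], cr$lo[3]:cr$hi[3]] <- blk
    }
    # pass 3: record the true shell and GFP volumes from the final masks
    shell_true <- gfp_true <- numeric(ms$n_foci)
    for (i in seq_len(ms$n_foci)) {
      cr <- crop(i, ms$shell_thickness_um)
      tblk <- tumor[cr$lo[1]:cr$hi[1], cr$lo[2]:cr$hi[2], cr$lo[3]:cr$hi[3]]
      gblk <- gfp[cr$lo[1]:cr$hi[1], cr$lo[2]:cr$hi[2], cr$lo[3]:cr$hi[3]]
      sin_ <- array(cr$dd > diam[i] / 2 &
                      cr$dd <= diam[i] / 2 + ms$shell_thickness_um,
                    cr$dims) & !tblk
      shell_true[i] <- sum(sin_)
      gfp_true[i] <- sum(sin_ & gblk)
    }
    vx <- prod(sp)
    tab <- data.frame(
      met_id = seq_len(ms$n_foci),
      z_um = centers[, 1], y_um = centers[, 2], x_um = centers[, 3],
      diameter_um = diam,
      volume_um3 = tvox * vx,
      volume_analytic_um3 = 4 / 3 * pi * (diam / 2)^3,
      is_micrometastasis = diam < 200,
      location = loc,
      shell_volume_um3 = shell_true * vx,
      shell_gfp_volume_um3 = gfp_true * vx,
      sigma = ifelse(tvox > 0, gfp_true / tvox, 0))
    list(tumor_mask = voxel_volume(tumor, sp),
         gfp_mask = voxel_volume(gfp, sp),
         metastasis_table = tab)
  })
}

#' Generate a complete phantom with ground truth
#'
#' Runs the lobule field, sinusoid graph (rasterized onto the same grid),
#' cell scattering (rasterized cell channel) and, if requested, the
#' metastasis phantom.
#'
#' @param spec `phantom_spec`.
#' @return list with all channels (`voxel_volume`s), the true graph, the
#'   true cell and metastasis tables, and the layout.
#' @export
generate_phantom <- function(spec) {
  field <- generate_lobule_field(spec)
  graph <- generate_sinusoid_graph(spec)
  sinus <- rasterize_graph(graph, spec$spacing, spec$sinusoid_radius_um,
                           grid_shape = spec$grid_shape, origin = c(0, 0, 0))
  n_cells <- spec$n_cells_per_lobule * spec$n_lobules
  cells <- NULL
  cell_mask <- NULL
  if (n_cells > 0) {
    cells <- scatter_cells(field$lobule_labels, field$cv_mask,
                           spec$rho_lognormal, n_cells, seed = spec$seed)
    cell_mask <- rasterize_cells(cells, field$lobule_labels,
                                 spec$cell_radius_um)
  }
  mets <- NULL
  if (!is.null(spec$metastasis_spec))
    mets <- generate_metastasis_phantom(spec, field$pv_mask,
                                        field$lobule_labels)
  c(field[c("cv_mask", "pv_mask", "lobule_labels", "layout")],
    list(graph = graph, sinusoid_mask = sinus, cell_table = cells,
         cell_mask = cell_mask, metastases = mets, spec = spec))
}
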
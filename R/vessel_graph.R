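# Spatial vessel graph: nodes with 3D positions, edges with centerline
# polylines and physical measurements.

#' Construct a vessel graph
#'
#' @param nodes data.frame with columns `z_um`, `y_um`, `x_um` (one row per
#'   node; row order defines node ids 1..V).
#' @param edges data.frame with integer columns `from`, `to` (node ids;
#'   `from == to` is a self-loop). Multi-edges are allowed.
#' @param polylines list (one per edge) of numeric matrices with columns
#'   (z, y, x) in micrometres, running from the `from` node to the `to`
#'   node; `NULL` entries default to the straight segment.
#' @param spacing optional voxel spacing carried along for consistency
#'   checks against masks.
#' @return object of class `vessel_graph` with per-node degrees (self-loops
#'   count twice) and per-edge `length_um`, `chord_um`, `tortuosity`
#'   (`NA` for self-loops, whose chord is zero).
#' @export
vessel_graph <- function(nodes, edges, polylines = NULL, spacing = NULL) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("z_um", "y_um", "x_um") %in% names(nodes)))
  nv <- nrow(nodes)
  nodes$id <- seq_len(nv)
  edges <- as.data.frame(edges)
  ne <- nrow(edges)
  if (ne > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    if (any(edges$from < 1 | edges$from > nv | edges$to < 1 | edges$to > nv))
      stop("edge endpoints out of range")
  } else {
    edges <- data.frame(from = integer(0), to = integer(0))
  }
  edges$id <- seq_len(ne)
  if (is.null(polylines)) polylines <- vector("list", ne)
  if (length(polylines) != ne) stop("one polyline per edge required")
  pos <- as.matrix(nodes[, c("z_um", "y_um", "x_um")])
  for (e in seq_len(ne)) {
    if (is.null(polylines[[e]]))
      polylines[[e]] <- rbind(pos[edges$from[e], ], pos[edges$to[e], ])
    polylines[[e]] <- matrix(as.numeric(polylines[[e]]), ncol = 3)
  }
  g <- structure(list(nodes = nodes, edges = edges, polylines = polylines),
                 class = "vessel_graph")
  attr(g, "spacing") <- spacing
  g$nodes$degree <- node_degrees(g)
  g <- measure_polylines(g)
  g$components <- graph_components(g)
  g
}

node_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  if (nrow(g$edges)) {
    t1 <- tabulate(g$edges$from, nbins = nrow(g$nodes))
    t2 <- tabulate(g$edges$to, nbins = nrow(g$nodes))
    deg <- t1 + t2  # self-loops count twice
  }
  deg
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

measure_polylines <- function(g) {
  ne <- nrow(g$edges)
  len <- chord <- numeric(ne)
  for (e in seq_len(ne)) {
    p <- g$polylines[[e]]
    len[e] <- polyline_length(p)
    chord[e] <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  }
  g$edges$length_um <- len
  g$edges$chord_um <- chord
  g$edges$tortuosity <- ifelse(g$edges$from == g$edges$to | chord <= 0,
                               NA_real_, len / chord)
  if (is.null(g$edges$mean_radius_um))
    g$edges$mean_radius_um <- rep(NA_real_, ne)
  g
}

# igraph view (multigraph, self-loops kept)
vg_igraph <- function(g) {
  ig <- igraph::make_empty_graph(nrow(g$nodes), directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to))
  ig
}

# simple-graph view: self-loops dropped, parallel edges collapsed.
# Returns list(igraph, edge_rep = original edge id of each kept edge,
# n_self, n_parallel_extra)
vg_simple <- function(g) {
  e <- g$edges
  self <- e$from == e$to
  e2 <- e[!self, , drop = FALSE]
  key <- paste(pmin(e2$from, e2$to), pmax(e2$from, e2$to))
  dup <- duplicated(key)
  kept <- e2[!dup, , drop = FALSE]
  ig <- igraph::make_empty_graph(nrow(g$nodes), directed = FALSE)
  if (nrow(kept)) ig <- igraph::add_edges(ig, rbind(kept$from, kept$to))
  list(igraph = ig, edge_rep = kept$id, n_self = sum(self),
       n_parallel_extra = sum(dup),
       parallel_extra_ids = e2$id[dup])
}

graph_components <- function(g) {
  if (nrow(g$nodes) == 0) return(0L)
  igraph::components(vg_igraph(g))$no
}

#' Cyclomatic number of a vessel graph
#'
#' `E - V + C` of the multigraph: the number of independent loops.
#' @param g a `vessel_graph`.
#' @return non-negative integer.
#' @export
cyclomatic_number <- function(g) {
  nrow(g$edges) - nrow(g$nodes) + graph_components(g)
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> V=%d E=%d components=%d cyclomatic=%d\n",
              nrow(x$nodes), nrow(x$edges), x$components, cyclomatic_number(x)))
  if (nrow(x$edges)) {
    cat(sprintf("  edge length %0.2f +/- %0.2f um; tortuosity %0.3f (mean)\n",
                mean(x$edges$length_um), sd(x$edges$length_um),
                mean(x$edges$tortuosity, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
plot.vessel_graph <- function(x, axes = c("x", "y"), ...) {
  pick <- c(z = "z_um", y = "y_um", x = "x_um")[axes]
  plot(x$nodes[[pick[1]]], x$nodes[[pick[2]]], pch = 16, cex = 0.5,
       xlab = paste(axes[1], "(um)"), ylab = paste(axes[2], "(um)"),
       asp = 1, ...)
  for (p in x$polylines) {
    cols <- match(pick, c("z_um", "y_um", "x_um"))
    graphics::lines(p[, cols[1]], p[, cols[2]], col = "grey40")
  }
  invisible(x)
}

#' Write a vessel graph to GraphML and CSV
#'
#' Node positions and edge measurements are stored as attributes; edge
#' centerlines are serialized as `z:y:x;z:y:x;...` strings so the file
#' round-trips through [read_vessel_graph()].
#'
#' @param g vessel graph.
#' @param path output `.graphml` path.
#' @export
write_vessel_graph <- function(g, path) {
  ig <- vg_igraph(g)
  igraph::V(ig)$z_um <- g$nodes$z_um
  igraph::V(ig)$y_um <- g$nodes$y_um
  igraph::V(ig)$x_um <- g$nodes$x_um
  if (nrow(g$edges)) {
    igraph::E(ig)$length_um <- g$edges$length_um
    igraph::E(ig)$chord_um <- g$edges$chord_um
    igraph::E(ig)$tortuosity <- ifelse(is.na(g$edges$tortuosity), -1,
                                       g$edges$tortuosity)
    igraph::E(ig)$mean_radius_um <- ifelse(is.na(g$edges$mean_radius_um), -1,
                                           g$edges$mean_radius_um)
    igraph::E(ig)$polyline <- vapply(g$polylines, function(p)
      paste(apply(p, 1, paste, collapse = ":"), collapse = ";"), character(1))
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Read a vessel graph written by [write_vessel_graph()]
#' @param path `.graphml` path.
#' @return a `vessel_graph`.
#' @export
read_vessel_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(z_um = igraph::V(ig)$z_um, y_um = igraph::V(ig)$y_um,
                      x_um = igraph::V(ig)$x_um)
  el <- igraph::as_edgelist(ig, names = FALSE)
  poly <- NULL
  if (nrow(el)) {
    poly <- lapply(igraph::E(ig)$polyline, function(s) {
      pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
      matrix(as.numeric(unlist(pts)), ncol = 3, byrow = TRUE)
    })
  }
  g <- vessel_graph(nodes, data.frame(from = el[, 1], to = el[, 2]), poly)
  if (nrow(el)) {
    mr <- igraph::E(ig)$mean_radius_um
    g$edges$mean_radius_um <- ifelse(mr < 0, NA_real_, mr)
  }
  g
}

#' Export node and edge tables as CSV
#' @param g vessel graph.
#' @param dir output directory (created if missing).
#' @export
write_graph_tables <- function(g, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(g$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  write.csv(g$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  invisible(dir)
}
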
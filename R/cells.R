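# Per-cell spatial statistics inside lobules: the distribution index rho,
# its lognormal law and boundary fraction, counts, sphericity and
# CV-distance profiles.

#' Detect cells in a binary cell channel
#'
#' 26-connected components at or above the volume cutoff become cell
#' records with physical centroid, voxel volume, meshed surface area and
#' sphericity.
#'
#' @param cell_mask logical `voxel_volume`.
#' @param min_volume_um3 minimum component volume (default 0).
#' @param smooth_um surface-mesh smoothing, see [surface_area()].
#' @return data.frame with one row per cell.
#' @export
detect_cells <- function(cell_mask, min_volume_um3 = 0, smooth_um = NULL) {
  lab <- label_components(cell_mask, 26)
  vx <- voxel_um3(cell_mask)
  k <- max(lab)
  empty <- data.frame(cell_id = integer(0), z_um = numeric(0),
                      y_um = numeric(0), x_um = numeric(0),
                      volume_um3 = numeric(0), surface_area_um2 = numeric(0),
                      sphericity = numeric(0))
  if (k == 0) return(empty)
  dm <- dim(cell_mask$data)
  idx <- which(lab > 0L)
  co <- arrayInd(idx, dm)
  li <- lab[idx]
  pos <- index_to_um(cell_mask, co)
  rows <- lapply(seq_len(k), function(i) {
    sel <- li == i
    nvox <- sum(sel)
    vol <- nvox * vx
    if (vol < min_volume_um3) return(NULL)
    m <- array(FALSE, dm); m[idx[sel]] <- TRUE
    mm <- mesh_measure(m, cell_mask$spacing, smooth_um)
    data.frame(cell_id = i, z_um = mean(pos[sel, 1]), y_um = mean(pos[sel, 2]),
               x_um = mean(pos[sel, 3]), volume_um3 = vol,
               surface_area_um2 = mm[["area_um2"]],
               sphericity = sphericity(vol, mm[["area_um2"]]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$cell_id <- seq_len(nrow(out))
  out
}

#' Distribution index of a cell inside its lobule
#'
#' `rho = D2 / (D1 + D2)` with `D1` the distance to the lobular central
#' vessel and `D2` the distance to the lobule boundary: 1 for a cell on
#' the central vein, 0 for a cell on the lobule boundary.
#'
#' @param D1_um,D2_um non-negative distances (micrometres), vectorized.
#' @return rho in `[0, 1]`.
#' @export
distribution_index <- function(D1_um, D2_um) {
  if (any(D1_um < 0) || any(D2_um < 0)) stop("distances must be non-negative")
  if (any(D1_um + D2_um == 0))
    stop("undefined position: D1 and D2 are both zero")
  D2_um / (D1_um + D2_um)
}

#' Attach lobule membership and rho geometry to a cell table
#'
#' Each cell is assigned to the lobule label at its centroid voxel. `D1` is
#' the anisotropy-respecting Euclidean distance from the centroid to the
#' central-vein mask, `D2` the distance to the nearest voxel outside the
#' cell's lobule label, both interpolated from distance-transform maps.
#' Cells outside every lobule are flagged (`in_lobule = FALSE`, `rho = NA`)
#' and excluded from rho statistics.
#'
#' @param cell_table from [detect_cells()] or the phantom generator.
#' @param cv_mask logical `voxel_volume` of central veins.
#' @param lobule_labels integer `voxel_volume`.
#' @return cell table with `lobule_label`, `D1_um`, `D2_um`, `rho`,
#'   `in_lobule` columns.
#' @export
assign_cell_geometry <- function(cell_table, cv_mask, lobule_labels) {
  if (!identical(dim(cv_mask$data), dim(lobule_labels$data)))
    stop("masks must share one grid")
  lab <- lobule_labels$data
  pts <- as.matrix(cell_table[, c("z_um", "y_um", "x_um")])
  ijk <- um_to_index(lobule_labels, pts)
  lb <- lab[ijk]
  d1map <- distance_transform(cv_mask)
  D1 <- interp3(d1map, cv_mask$spacing, cv_mask$origin, pts)
  D2 <- rep(NA_real_, nrow(cell_table))
  for (i in sort(unique(lb[lb > 0L]))) {
    sel <- lb == i
    d2map <- distance_transform(lab != i, spacing = lobule_labels$spacing)
    D2[sel] <- interp3(d2map, lobule_labels$spacing, lobule_labels$origin,
                       pts[sel, , drop = FALSE])
  }
  cell_table$lobule_label <- lb
  cell_table$in_lobule <- lb > 0L
  cell_table$D1_um <- ifelse(cell_table$in_lobule, D1, NA_real_)
  cell_table$D2_um <- D2
  ok <- cell_table$in_lobule & (D1 + D2) > 0
  cell_table$rho <- NA_real_
  cell_table$rho[ok] <- distribution_index(D1[ok], D2[ok])
  cell_table
}

#' Distribution-index statistics
#'
#' Histogram of rho at the requested bin width, the boundary fraction
#' (rho strictly below the threshold), and a lognormal fit of the positive
#' rho values. Cells with rho exactly 0 sit on the lobule boundary; they
#' count toward the boundary fraction but are excluded from the fit (their
#' log is undefined) and reported in `n_zero`. Because rho is bounded by 1
#' the fitted law is the (0,1]-truncated lognormal; `mu` and `sigma` are
#' the moments of the truncated log sample. The count of cells at exactly
#' rho = 1 and the mass of the top histogram bin are both reported, as the
#' two readings of "cells surrounding the central vein".
#'
#' @param cell_table table with a `rho` column (NA rho rows are dropped).
#' @param boundary_threshold rho threshold for the boundary fraction
#'   (default 0.15).
#' @param bin_width histogram bin width (default 0.04; 0.05 is typical for
#'   fibrosis panels).
#' @return list with `histogram` (counts), `breaks`, `boundary_fraction`,
#'   `lognormal_fit`, `n`, `n_zero`, `n_rho1`, `top_bin_fraction`.
#' @export
rho_statistics <- function(cell_table, boundary_threshold = 0.15,
                           bin_width = 0.04) {
  rho <- cell_table$rho
  rho <- rho[!is.na(rho)]
  if (length(rho) < 8) stop("need at least 8 cells with valid rho")
  breaks <- seq(0, 1 + bin_width, by = bin_width)
  breaks <- breaks[breaks < 1] ; breaks <- c(breaks, 1)
  h <- hist(rho, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  # top bin: [1 - bin_width, 1]
  top <- mean(rho >= 1 - bin_width)
  fit <- if (sum(rho > 0) >= 8) fit_lognormal(rho[rho > 0]) else NULL
  list(histogram = h$counts, breaks = h$breaks,
       boundary_fraction = mean(rho < boundary_threshold),
       lognormal_fit = fit, n = length(rho), n_zero = sum(rho == 0),
       n_rho1 = sum(rho == 1), top_bin_fraction = top)
}

#' Cell counts and densities per lobule
#'
#' @param cell_table assigned cell table (`lobule_label` column).
#' @param lobules data.frame from [measure_lobules()] (columns `label`,
#'   `volume_mm3`).
#' @return data.frame with per-lobule `count` and `count_per_mm3`.
#' @export
cells_per_lobule <- function(cell_table, lobules) {
  cnt <- vapply(lobules$label, function(l)
    sum(cell_table$lobule_label == l, na.rm = TRUE), integer(1))
  data.frame(label = lobules$label, count = cnt,
             count_per_mm3 = cnt / lobules$volume_mm3)
}

#' Central-vein distance profile
#'
#' Summarizes the cell-to-central-vein distances (`D1`): mean, SD and the
#' fraction of cells within the threshold radius.
#'
#' @param cell_table assigned cell table.
#' @param radius_threshold_um threshold (default 120 micrometres).
#' @return list `(mean_um, sd_um, fraction_within, n)`.
#' @export
cv_distance_profile <- function(cell_table, radius_threshold_um = 120) {
  d <- cell_table$D1_um[cell_table$in_lobule]
  d <- d[!is.na(d)]
  list(mean_um = mean(d), sd_um = sd(d),
       fraction_within = mean(d <= radius_threshold_um), n = length(d))
}

#' Cell morphology (sphericity) profile
#'
#' @param cell_table table with a `sphericity` column.
#' @param bin_width histogram bin width (default 0.05).
#' @return list with relative-frequency `histogram`, `breaks` and
#'   `mean_sphericity`.
#' @export
morphology_profile <- function(cell_table, bin_width = 0.05) {
  s <- cell_table$sphericity
  s <- s[!is.na(s)]
  top <- max(1, ceiling(max(s) / bin_width) * bin_width)
  h <- hist(s, breaks = seq(0, top + bin_width, by = bin_width), plot = FALSE,
            right = FALSE, include.lowest = TRUE)
  list(histogram = h$counts / length(s), breaks = h$breaks,
       mean_sphericity = mean(s), n = length(s))
}
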
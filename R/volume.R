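# The universal image carrier: a 3D grid with physical voxel spacing.

#' Voxel volume
#'
#' A 3D scalar, integer or logical grid with per-axis physical spacing.
#' Axis order is fixed as (z, y, x): `data[i, j, k]` is the voxel at depth
#' `i`, row `j`, column `k`, and its centre sits at
#' `origin + (c(i, j, k) - 1) * spacing` micrometres. All physical
#' measurements downstream (distances, volumes, graph coordinates) are in
#' micrometres and respect anisotropic spacing.
#'
#' @param data 3D array (logical, integer or numeric).
#' @param spacing numeric length-3, micrometres per voxel along (z, y, x);
#'   strictly positive.
#' @param origin numeric length-3, physical offset of voxel (1,1,1) in
#'   micrometres.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("data must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (z, y, x)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d (z,y,x), spacing %s um, %s\n",
              dm[1], dm[2], dm[3], paste(signif(x$spacing, 4), collapse = " x "),
              typeof(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

# physical volume of one voxel in um^3
voxel_um3 <- function(vol) prod(vol$spacing)

# physical coordinates (um) of voxel index rows (z,y,x)
index_to_um <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# nearest voxel index of physical points; clamped to the grid
um_to_index <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  dm <- dim(vol$data)
  ijk <- round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")) + 1
  for (a in 1:3) ijk[, a] <- pmin(pmax(ijk[, a], 1), dm[a])
  storage.mode(ijk) <- "integer"
  ijk
}

as_mask <- function(vol) {
  if (inherits(vol, "voxel_volume")) {
    d <- vol$data
  } else d <- vol
  if (!is.logical(d)) stop("expected a logical (boolean) volume")
  d
}

#' Euclidean distance transform of a voxel volume
#'
#' Exact anisotropic Euclidean distance (micrometres) from every voxel
#' centre to the nearest `TRUE` voxel centre, by the separable
#' lower-envelope algorithm. If no voxel is `TRUE` all distances are `Inf`.
#'
#' @param vol `voxel_volume` with logical data, or a logical array (then
#'   `spacing` is required).
#' @param spacing voxel spacing, only when `vol` is a bare array.
#' @return numeric array of distances, same shape as the input.
#' @export
distance_transform <- function(vol, spacing = NULL) {
  if (inherits(vol, "voxel_volume")) {
    spacing <- vol$spacing
    mask <- as_mask(vol)
  } else {
    if (is.null(spacing)) stop("spacing required for a bare array")
    mask <- vol
    if (!is.logical(mask)) stop("expected a logical array")
  }
  dm <- dim(mask)
  d <- .edt_cpp(as.logical(mask), as.integer(dm), as.numeric(spacing))
  array(d, dm)
}

# Mesh-based surface area and volume of a voxel region.
# The binary region is optionally Gaussian-smoothed (sigma in um) and the
# 0.5 iso-surface extracted by marching tetrahedra; returns c(area_um2,
# volume_um3) of the closed mesh. Cropping to the region bounding box (plus
# margin) keeps the cost proportional to the region.
mesh_measure <- function(mask, spacing, smooth_um = NULL) {
  stopifnot(is.logical(mask))
  if (is.null(smooth_um)) smooth_um <- 0.7 * min(spacing)
  idx <- which(mask)
  if (!length(idx)) return(c(area_um2 = 0, volume_um3 = 0))
  co <- arrayInd(idx, dim(mask))
  sigma_vox <- smooth_um / spacing
  marg <- pmax(2L, as.integer(ceiling(3 * sigma_vox)) + 1L)
  lo <- pmax(apply(co, 2, min) - marg, 1L)
  hi <- pmin(apply(co, 2, max) + marg, dim(mask))
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  f <- as.numeric(sub)
  if (smooth_um > 0)
    f <- .smooth3d_cpp(f, as.integer(dim(sub)), as.numeric(sigma_vox))
  m <- .mesh_measure_cpp(f, as.integer(dim(sub)), as.numeric(spacing), 0.5)
  c(area_um2 = m[1], volume_um3 = m[2])
}
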
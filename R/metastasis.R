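# Micrometastasis detection, periportal/intralobular classification,
# macrophage shell quantification and the recruitment coefficient sigma.

#' Detect tumor foci in a binary tumor channel
#'
#' 26-connected components at or above the volume cutoff become metastasis
#' records. The equivalent spherical diameter is `(6 V / pi)^(1/3)`; a
#' focus with equivalent diameter below 200 micrometres (0.2 mm) is
#' flagged as a micrometastasis. Optionally the maximum Feret diameter
#' (largest voxel-centre pairwise distance) is reported as an alternative
#' size reading.
#'
#' @param tumor_mask logical `voxel_volume`.
#' @param min_volume_um3 minimum component volume (default 0).
#' @param feret also compute the maximum Feret diameter (default FALSE).
#' @return data.frame, one row per focus, plus a `voxels` attribute (list
#'   of voxel index vectors) used by the shell and location stages.
#' @export
detect_metastases <- function(tumor_mask, min_volume_um3 = 0, feret = FALSE) {
  lab <- label_components(tumor_mask, 26)
  vx <- voxel_um3(tumor_mask)
  k <- max(lab)
  out <- data.frame(met_id = integer(0), z_um = numeric(0), y_um = numeric(0),
                    x_um = numeric(0), volume_um3 = numeric(0),
                    equivalent_diameter_um = numeric(0),
                    is_micrometastasis = logical(0))
  vox_list <- list()
  if (k > 0) {
    dm <- dim(tumor_mask$data)
    idx <- which(lab > 0L)
    li <- lab[idx]
    co <- arrayInd(idx, dm)
    pos <- index_to_um(tumor_mask, co)
    rows <- list()
    for (i in seq_len(k)) {
      sel <- li == i
      vol <- sum(sel) * vx
      if (vol < min_volume_um3) next
      d_eq <- (6 * vol / pi)^(1 / 3)
      fd <- NA_real_
      if (feret) {
        # boundary voxels suffice for the largest pairwise distance; very
        # large surfaces are subsampled deterministically (estimate)
        p <- pos[sel, , drop = FALSE]
        bidx <- idx[sel]
        m <- array(FALSE, dm); m[bidx] <- TRUE
        cob <- arrayInd(bidx, dm)
        on_b <- rep(FALSE, nrow(cob))
        for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                       c(0,0,1), c(0,0,-1))) {
          nb <- sweep(cob, 2, -o)
          inside <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
            nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
          hit <- rep(FALSE, nrow(cob))
          hit[inside] <- !m[nb[inside, , drop = FALSE]]
          on_b <- on_b | hit | !inside
        }
        pb <- p[on_b, , drop = FALSE]
        if (nrow(pb) > 4000)
          pb <- pb[seq(1, nrow(pb), length.out = 4000), , drop = FALSE]
        fd <- max(dist(pb))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        met_id = NA_integer_, z_um = mean(pos[sel, 1]), y_um = mean(pos[sel, 2]),
        x_um = mean(pos[sel, 3]), volume_um3 = vol,
        equivalent_diameter_um = d_eq,
        is_micrometastasis = d_eq < 200,
        feret_diameter_um = fd)
      vox_list[[length(rows)]] <- idx[sel]
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out$met_id <- seq_len(nrow(out))
    }
  }
  if (!feret) out$feret_diameter_um <- NULL
  attr(out, "voxels") <- vox_list
  attr(out, "grid") <- list(dim = dim(tumor_mask$data),
                            spacing = tumor_mask$spacing,
                            origin = tumor_mask$origin)
  out
}

#' Classify metastases as periportal or intralobular
#'
#' A focus is periportal when its surface lies within
#' `periportal_distance_um` of the portal-vein mask (the minimum over the
#' focus voxels of the Euclidean distance to the PV), else intralobular.
#'
#' @param met_table from [detect_metastases()].
#' @param pv_mask nonempty logical `voxel_volume`.
#' @param periportal_distance_um distance threshold (default 20).
#' @return table with `location` and `pv_distance_um` columns.
#' @export
classify_location <- function(met_table, pv_mask, periportal_distance_um = 20) {
  if (!any(as_mask(pv_mask))) stop("portal mask is empty")
  vox <- attr(met_table, "voxels")
  dpv <- distance_transform(pv_mask)
  met_table$pv_distance_um <- vapply(seq_len(nrow(met_table)), function(i)
    min(dpv[vox[[i]]]), numeric(1))
  met_table$location <- ifelse(met_table$pv_distance_um <= periportal_distance_um,
                               "periportal", "intralobular")
  met_table
}

#' Quantify the macrophage shell around each metastasis
#'
#' The shell of a focus is the set of voxels within `shell_radius_um` of
#' its surface and outside any tumor voxel. The GFP (macrophage) volume
#' inside the shell is reported, and the focus is `surrounded` when the
#' GFP-filled fraction of its shell reaches `surrounded_min_fraction`.
#' The recruitment coefficient `sigma` = shell GFP volume / tumor volume
#' is attached per focus. Foci whose shell is entirely outside the grid
#' are flagged (`shell_ok = FALSE`).
#'
#' @param met_table from [detect_metastases()] (same grid as `gfp_mask`).
#' @param gfp_mask logical `voxel_volume` of the macrophage channel.
#' @param shell_radius_um shell thickness outward from the tumor surface
#'   (default 30).
#' @param surrounded_min_fraction minimum GFP fill of the shell (default
#'   0.05).
#' @return table with `shell_volume_um3`, `shell_gfp_volume_um3`,
#'   `shell_fill`, `surrounded`, `shell_ok` and `sigma` columns.
#' @export
shell_quantification <- function(met_table, gfp_mask, shell_radius_um = 30,
                                 surrounded_min_fraction = 0.05) {
  grid <- attr(met_table, "grid")
  if (!identical(grid$dim, dim(gfp_mask$data)))
    stop("masks must share one grid")
  vox <- attr(met_table, "voxels")
  dm <- grid$dim
  vx <- prod(grid$spacing)
  gfp <- as_mask(gfp_mask)
  tumor_any <- array(FALSE, dm)
  for (v in vox) tumor_any[v] <- TRUE
  n <- nrow(met_table)
  sv <- sg <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    m <- array(FALSE, dm); m[vox[[i]]] <- TRUE
    # crop to the focus bounding box extended by the shell
    co <- arrayInd(vox[[i]], dm)
    marg <- as.integer(ceiling(shell_radius_um / grid$spacing)) + 1L
    lo <- pmax(apply(co, 2, min) - marg, 1L)
    hi <- pmin(apply(co, 2, max) + marg, dm)
    sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    d <- distance_transform(sub, spacing = grid$spacing)
    shell <- d > 0 & d <= shell_radius_um &
      !tumor_any[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    sv[i] <- sum(shell) * vx
    sg[i] <- sum(shell & gfp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]) * vx
    ok[i] <- sv[i] > 0
  }
  met_table$shell_volume_um3 <- sv
  met_table$shell_gfp_volume_um3 <- sg
  met_table$shell_fill <- ifelse(ok, sg / sv, NA_real_)
  met_table$surrounded <- ok & met_table$shell_fill >= surrounded_min_fraction
  met_table$shell_ok <- ok
  met_table$sigma <- recruitment_coefficient(sg, met_table$volume_um3)
  met_table
}

#' Recruitment coefficient
#'
#' `sigma = GFP volume / tumor volume`: the macrophage volume recruited
#' around a focus per unit tumor volume. Scale-invariant: rescaling both
#' volumes jointly leaves sigma unchanged.
#'
#' @param gfp_volume_um3 macrophage (GFP) volume around the focus.
#' @param tumor_volume_um3 positive tumor volume.
#' @return sigma (dimensionless), vectorized.
#' @export
recruitment_coefficient <- function(gfp_volume_um3, tumor_volume_um3) {
  if (any(tumor_volume_um3 <= 0)) stop("tumor volume must be positive")
  gfp_volume_um3 / tumor_volume_um3
}

#' Summary of a metastasis table
#'
#' @param met_table fully annotated table (location + shell columns).
#' @return list with counts, micrometastasis counts, mean volumes and
#'   surrounded percentages by location, and the sigma distribution
#'   summary.
#' @export
summarize_metastases <- function(met_table) {
  by_loc <- split(met_table, met_table$location)
  list(
    n = nrow(met_table),
    n_micrometastases = sum(met_table$is_micrometastasis),
    mean_volume_um3 = mean(met_table$volume_um3),
    by_location = lapply(by_loc, function(d) list(
      n = nrow(d), percent = 100 * nrow(d) / nrow(met_table),
      mean_volume_um3 = mean(d$volume_um3),
      percent_surrounded = 100 * mean(d$surrounded))),
    sigma = list(mean = mean(met_table$sigma), sd = sd(met_table$sigma),
                 quartiles = unname(quantile(met_table$sigma,
                                             c(0.25, 0.5, 0.75))))
  )
}
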
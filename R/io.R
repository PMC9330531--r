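# TIFF stack reading/writing and pipeline configuration.

#' Read a multi-page TIFF stack as a voxel volume
#'
#' Pages are z-slices of (y, x) images; the array is returned in (z, y, x)
#' axis order. Spacing always comes from the caller (config); if the file
#' carries resolution tags that disagree, the config wins and a message is
#' logged. Single-page (2D) files are rejected: the pipeline is inherently
#' 3D.
#'
#' @param path TIFF file path.
#' @param spacing um per voxel (z, y, x).
#' @param type `"mask"` (logical, stored 8-bit), `"label"` (integer,
#'   stored 16-bit) or `"float"`.
#' @return `voxel_volume`.
#' @export
read_stack <- function(path, spacing, type = c("mask", "label", "float")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("expected a 3D stack (>= 2 pages), got ", length(pages),
         " page(s): ", path)
  info <- attr(pages[[1]], "info")
  if (!is.null(info) && !is.null(info$x.resolution) && info$x.resolution > 0) {
    tag_um <- 1e4 / info$x.resolution  # resolution tags are per cm
    if (abs(tag_um - spacing[3]) > 1e-3 * spacing[3])
      message("read_stack: TIFF resolution tag (", signif(tag_um, 4),
              " um) overridden by config spacing (", spacing[3], " um)")
  }
  arr <- aperm(simplify2array(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of RGB pages
    p
  })), c(3, 1, 2))
  data <- switch(type,
    mask = arr > 0.5,
    label = array(as.integer(round(arr * 65535)), dim(arr)),
    float = arr)
  voxel_volume(data, spacing)
}

#' Write a voxel volume as a multi-page TIFF
#'
#' Logical data is stored 8-bit (0/255), integer labels 16-bit (values up
#' to 65535), numeric data 32-bit float (values must lie in `[0, 1]`).
#'
#' @param vol `voxel_volume`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stack <- function(vol, path) {
  d <- vol$data
  if (is.logical(d)) {
    pages <- lapply(seq_len(dim(d)[1]), function(z) (d[z, , ] * 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else if (is.integer(d)) {
    if (max(d) > 65535L) stop("label values exceed 16-bit range")
    pages <- lapply(seq_len(dim(d)[1]), function(z) d[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    pages <- lapply(seq_len(dim(d)[1]), function(z) d[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: spur-prune threshold (1.5 x
#' the largest voxel pitch unless set), branch-angle tangent distance 5 um,
#' shape-classifier tolerance 0.01, rho boundary threshold 0.15 with
#' histogram bin 0.04, periportal distance 20 um, shell radius 30 um with
#' surrounded fraction 0.05.
#'
#' @param ... overrides of the default fields (unknown names are an
#'   error).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    spacing = c(2, 1.19, 1.19),
    seed = 1,
    prune_um = NULL,          # default 1.5 * max(spacing), resolved at run
    d_tangent_um = 5,
    shape_tol = 0.01,
    boundary_threshold = 0.15,
    rho_bin_width = 0.04,
    sphericity_bin_width = 0.05,
    cv_distance_threshold_um = 120,
    min_cell_volume_um3 = 20,
    min_met_volume_um3 = 100,
    periportal_distance_um = 20,
    shell_radius_um = 30,
    surrounded_min_fraction = 0.05,
    lobule_mode = "classical",
    phantom = NULL,           # list of phantom_spec() overrides
    inputs = NULL,            # named TIFF paths for real data
    stages = c("phantom", "graph", "topology", "lobules", "cells", "mets")
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected before any computation.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}
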
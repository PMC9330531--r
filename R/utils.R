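# Internal helpers: seeded RNG streams, component labelling, interpolation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so phantom generation does not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a per-component stream seed from the master seed. Streams are fixed
# small integers (graph = 1, lobules = 2, cells = 3, metastases = 4, ...), so
# adding one phantom element never perturbs the draws of another. Result is
# kept below 2^31.
stream_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 101L
}

# Half-neighbourhood integer offsets for connectivity 26 or 6 (rows: dz,dy,dx)
half_offsets <- function(connectivity = 26) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
    # keep lexicographically positive half
    keep <- off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
      (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0)
    off[keep, , drop = FALSE]
  }
}

all_offsets <- function(connectivity = 26) {
  h <- half_offsets(connectivity)
  rbind(h, -h)
}

# Linear index of voxel coordinates (1-based, dim order z,y,x)
lin_index <- function(co, dm) {
  co[, 1] + dm[1] * ((co[, 2] - 1) + dm[2] * (co[, 3] - 1))
}

#' Label connected components of a 3D logical array
#'
#' @param mask 3D logical array (axis order z, y, x).
#' @param connectivity 26 (default) or 6.
#' @return integer array of the same shape; 0 is background, components are
#'   numbered 1..k in order of their smallest linear index.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (inherits(mask, "voxel_volume")) mask <- mask$data
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  map <- integer(prod(dm))
  map[idx] <- seq_len(n)
  co <- arrayInd(idx, dm)
  offs <- half_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    tid <- map[lin_index(nb[ok, , drop = FALSE], dm)]
    keep <- tid > 0L
    from <- c(from, which(ok)[keep])
    to <- c(to, tid[keep])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber components by smallest linear index for determinism
  first <- tapply(seq_len(n), memb, min)
  ord <- order(idx[first])
  renum <- integer(length(first))
  renum[ord] <- seq_along(ord)
  lab[idx] <- renum[memb]
  lab
}

# Trilinear interpolation of a 3D array at physical points.
# pts: matrix with columns (z, y, x) in micrometres.
interp3 <- function(arr, spacing, origin, pts) {
  dm <- dim(arr)
  # fractional 1-based index
  fz <- (pts[, 1] - origin[1]) / spacing[1] + 1
  fy <- (pts[, 2] - origin[2]) / spacing[2] + 1
  fx <- (pts[, 3] - origin[3]) / spacing[3] + 1
  fz <- pmin(pmax(fz, 1), dm[1]); fy <- pmin(pmax(fy, 1), dm[2]); fx <- pmin(pmax(fx, 1), dm[3])
  z0 <- pmin(floor(fz), dm[1] - 1L); y0 <- pmin(floor(fy), dm[2] - 1L); x0 <- pmin(floor(fx), dm[3] - 1L)
  if (dm[1] == 1) z0 <- rep(1, length(fz))
  if (dm[2] == 1) y0 <- rep(1, length(fy))
  if (dm[3] == 1) x0 <- rep(1, length(fx))
  tz <- fz - z0; ty <- fy - y0; tx <- fx - x0
  g <- function(z, y, x) arr[cbind(z, y, x)]
  z1 <- pmin(z0 + 1, dm[1]); y1 <- pmin(y0 + 1, dm[2]); x1 <- pmin(x0 + 1, dm[3])
  v000 <- g(z0, y0, x0); v100 <- g(z1, y0, x0)
  v010 <- g(z0, y1, x0); v110 <- g(z1, y1, x0)
  v001 <- g(z0, y0, x1); v101 <- g(z1, y0, x1)
  v011 <- g(z0, y1, x1); v111 <- g(z1, y1, x1)
  v00 <- v000 * (1 - tz) + v100 * tz
  v10 <- v010 * (1 - tz) + v110 * tz
  v01 <- v001 * (1 - tz) + v101 * tz
  v11 <- v011 * (1 - tz) + v111 * tz
  v0 <- v00 * (1 - ty) + v10 * ty
  v1 <- v01 * (1 - ty) + v11 * ty
  v0 * (1 - tx) + v1 * tx
}

# Truncated-lognormal helpers (law of the distribution index rho, truncated
# to (0, 1]).
tlnorm_mass <- function(mu, sigma) plnorm(1, mu, sigma)

#' Draw from a lognormal truncated to (0, 1]
#' @keywords internal
rtlnorm01 <- function(n, mu, sigma) {
  u <- runif(n, 0, tlnorm_mass(mu, sigma))
  qlnorm(u, mu, sigma)
}

#' Mean of the (0,1]-truncated lognormal by numerical integration
#' @keywords internal
tlnorm_mean <- function(mu, sigma) {
  integrate(function(x) x * dlnorm(x, mu, sigma), 0, 1)$value / tlnorm_mass(mu, sigma)
}

#' CDF at q of the (0,1]-truncated lognormal
#' @keywords internal
ptlnorm01 <- function(q, mu, sigma) plnorm(q, mu, sigma) / tlnorm_mass(mu, sigma)
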
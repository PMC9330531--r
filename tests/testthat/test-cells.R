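test_that("cell detection separates components and measures sphericity", {
  dm <- c(24, 40, 40)
  arr <- array(FALSE, dm)
  arr[4:6, 4:6, 4:6] <- TRUE          # ~27-voxel blob
  arr[15:17, 30:32, 30:32] <- TRUE
  v <- voxel_volume(arr, c(1, 1, 1))
  tab <- detect_cells(v)
  expect_equal(nrow(tab), 2)
  # blobs below the volume cutoff are dropped
  expect_equal(nrow(detect_cells(v, min_volume_um3 = 100)), 0)
  arr[20, 10, 10] <- TRUE             # 1-voxel speck
  tab <- detect_cells(voxel_volume(arr, c(1, 1, 1)), min_volume_um3 = 5)
  expect_equal(nrow(tab), 2)
  # empty mask: empty table
  expect_equal(nrow(detect_cells(voxel_volume(array(FALSE, dm), c(1, 1, 1)))), 0)
  # a voxelized 5-um ball is nearly spherical
  b <- ball_mask(5, spacing = c(0.5, 0.5, 0.5))
  tab <- detect_cells(voxel_volume(b, c(0.5, 0.5, 0.5)))
  expect_lt(abs(tab$sphericity - 1), 0.05)
})

test_that("the distribution index is D2 / (D1 + D2) with exact bounds", {
  expect_equal(distribution_index(0, 40), 1)     # on the central vein
  expect_equal(distribution_index(120, 0), 0)    # on the lobule boundary
  expect_equal(distribution_index(35, 35), 0.5)  # symmetry
  expect_equal(distribution_index(c(0, 10), c(5, 0)), c(1, 0))
  expect_error(distribution_index(0, 0), "undefined")
  expect_error(distribution_index(-1, 5), "non-negative")
})

test_that("cell geometry assignment flags cells outside lobules", {
  spec <- phantom_spec(seed = 81)
  f <- generate_lobule_field(spec)
  cells <- scatter_cells(f$lobule_labels, f$cv_mask, spec$rho_lognormal, 60,
                         seed = 81)
  out <- data.frame(cell_id = 61, z_um = 1, y_um = 1, x_um = 1)
  tab <- assign_cell_geometry(rbind(cells[, names(out)], out),
                              f$cv_mask, f$lobule_labels)
  expect_true(all(tab$in_lobule[1:60]))
  expect_false(tab$in_lobule[61])
  expect_true(is.na(tab$rho[61]))
  expect_true(all(tab$rho[1:60] >= 0 & tab$rho[1:60] <= 1))
})

test_that("rho increases monotonically along a boundary-to-CV ray", {
  spec <- phantom_spec(seed = 82)
  f <- generate_lobule_field(spec)
  lob <- f$layout[[1]]
  # ray of probe cells from the lobule equator to just outside the CV
  off <- seq(lob$semi[2] - 3, spec$cv_radius_um + 4, length.out = 25)
  probe <- data.frame(cell_id = seq_along(off),
                      z_um = lob$center[1],
                      y_um = lob$center[2] + off,
                      x_um = lob$center[3])
  tab <- assign_cell_geometry(probe, f$cv_mask, f$lobule_labels)
  expect_true(all(diff(tab$rho) > 0))
})

test_that("rho statistics report boundary fraction, fit and top bin", {
  rho <- c(rep(1, 10), rep(0.5, 4))
  rs <- rho_statistics(data.frame(rho = rho), bin_width = 0.04)
  expect_equal(rs$boundary_fraction, 0)
  expect_equal(rs$n_rho1, 10)
  expect_equal(rs$top_bin_fraction, 10 / 14)
  expect_equal(sum(rs$histogram), 14)
  # cells at exactly rho = 0 count toward the boundary but not the fit
  rho <- c(rep(0, 3), runif(12, 0.05, 0.9))
  rs <- rho_statistics(data.frame(rho = rho), boundary_threshold = 0.15)
  expect_equal(rs$n_zero, 3)
  expect_gte(rs$boundary_fraction, 3 / 15)
  expect_equal(rs$lognormal_fit$n, 12)
  # threshold 0 counts nothing (strictly-below comparison)
  expect_equal(rho_statistics(data.frame(rho = rho),
                              boundary_threshold = 0)$boundary_fraction, 0)
  expect_error(rho_statistics(data.frame(rho = c(0.5, 0.2))), "at least 8")
})

test_that("scattered phantom cells recover the truncated lognormal law", {
  spec <- phantom_spec(seed = 83)
  f <- generate_lobule_field(spec)
  n <- 4000
  mu <- -1.9; sg <- 0.8
  cells <- scatter_cells(f$lobule_labels, f$cv_mask, c(mu, sg), n, seed = 83)
  tab <- assign_cell_geometry(cells[, c("cell_id", "z_um", "y_um", "x_um")],
                              f$cv_mask, f$lobule_labels)
  rs <- rho_statistics(tab, boundary_threshold = 0.15)
  ref <- tlnorm_log_moments(mu, sg)
  se_mu <- ref[["sd"]] / sqrt(n)
  expect_lt(abs(rs$lognormal_fit$mu - ref[["mean"]]), 4 * se_mu)
  expect_lt(abs(rs$lognormal_fit$sigma - ref[["sd"]]), 4 * se_mu)
  bf_ref <- hepatograph:::ptlnorm01(0.15, mu, sg)
  expect_lt(abs(rs$boundary_fraction - bf_ref), 0.02)
})

test_that("per-lobule counts conserve the total and scale as densities", {
  cell_tab <- data.frame(lobule_label = c(1, 1, 1, 2, NA))
  lob <- data.frame(label = c(1, 2), volume_mm3 = c(0.2, 0.1))
  cp <- cells_per_lobule(cell_tab, lob)
  expect_equal(cp$count, c(3, 1))
  expect_equal(sum(cp$count), sum(!is.na(cell_tab$lobule_label)))
  expect_equal(cp$count_per_mm3, c(15, 10))
  # halving the volume doubles the density at fixed count
  lob2 <- lob; lob2$volume_mm3 <- lob$volume_mm3 / 2
  expect_equal(cells_per_lobule(cell_tab, lob2)$count_per_mm3,
               cp$count_per_mm3 * 2)
  # empty lobule: zero count, zero density
  lob3 <- data.frame(label = 3, volume_mm3 = 0.1)
  expect_equal(cells_per_lobule(cell_tab, lob3)$count, 0)
})

test_that("the CV distance profile summarizes D1", {
  tab <- data.frame(D1_um = c(rep(0, 5), rep(1e-9, 3)),
                    in_lobule = rep(TRUE, 8))
  p <- cv_distance_profile(tab)
  expect_lt(p$mean_um, 1e-6)
  expect_equal(p$fraction_within, 1)
  # cells on a 200-um shell: none within the 120-um threshold
  tab <- data.frame(D1_um = rep(200, 10), in_lobule = TRUE)
  expect_equal(cv_distance_profile(tab, 120)$fraction_within, 0)
  # phantom: profile equals the stored D1 exactly
  spec <- phantom_spec(seed = 84)
  f <- generate_lobule_field(spec)
  cells <- scatter_cells(f$lobule_labels, f$cv_mask, spec$rho_lognormal, 100,
                         seed = 84)
  cells$in_lobule <- TRUE
  p <- cv_distance_profile(cells, 40)
  expect_equal(p$mean_um, mean(cells$D1_um))
  expect_equal(p$fraction_within, mean(cells$D1_um <= 40))
})

test_that("morphology profiles separate spheres from elongated cells", {
  spec <- phantom_spec(seed = 85, grid_shape = c(60, 120, 120),
                       lobule_radius_um = 50, n_cells_per_lobule = 0)
  f <- generate_lobule_field(spec)
  ctrs <- as.matrix(expand.grid(z = c(40, 60, 80),
                                y = c(50, 90, 130), x = c(50, 90, 130)))
  tab0 <- data.frame(cell_id = 1:27, z_um = ctrs[, 1], y_um = ctrs[, 2],
                     x_um = ctrs[, 3])
  aspect <- rep(c(1, 4), length.out = 27)
  cm <- rasterize_cells(tab0, f$lobule_labels, radius_um = 4, aspect = aspect)
  det <- detect_cells(cm, min_volume_um3 = 30)
  expect_equal(nrow(det), 27)
  mp <- morphology_profile(det, bin_width = 0.05)
  sph_mean <- mean(det$sphericity[aspect[order(ctrs[, 1])] == 1])
  # spheres only: mean sphericity near 1
  sph <- detect_cells(rasterize_cells(tab0[1:8, ], f$lobule_labels, 4, 1))
  expect_gt(morphology_profile(sph)$mean_sphericity, 0.9)
  elo <- detect_cells(rasterize_cells(tab0[1:8, ], f$lobule_labels, 4, 4))
  m_elo <- morphology_profile(elo)$mean_sphericity
  m_sph <- morphology_profile(sph)$mean_sphericity
  expect_lt(m_elo, m_sph)
  # the mixture mean lies strictly between the two class means
  expect_true(mp$mean_sphericity > m_elo && mp$mean_sphericity < m_sph)
  # single cell: all mass in one bin
  one <- morphology_profile(det[1, ], bin_width = 0.05)
  expect_equal(sum(one$histogram > 0), 1)
  expect_equal(sum(one$histogram), 1)
})
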
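test_that("a zero-loop phantom network is a spanning tree", {
  spec <- phantom_spec(seed = 21)
  g <- generate_sinusoid_graph(spec, loop_excess = 0)
  expect_equal(nrow(g$edges), nrow(g$nodes) - g$components)
  expect_equal(cyclomatic_number(g), 0)
  big <- phantom_spec(grid_shape = c(128, 288, 288), lobule_radius_um = 130,
                      lobule_radius_jitter_um = 0, seed = 21)
  gt <- generate_sinusoid_graph(big, n_nodes = 255, loop_excess = 0)
  expect_equal(nrow(gt$nodes), 255)
  expect_equal(gt$components, 1)
  expect_equal(edge_node_ratio(gt), 254 / 255)
})

test_that("the achieved cyclomatic number equals the requested loop excess", {
  spec <- phantom_spec(seed = 22)
  for (lx in c(5, 20, 33)) {
    g <- generate_sinusoid_graph(spec, loop_excess = lx)
    expect_equal(cyclomatic_number(g), lx)
  }
  expect_error(generate_sinusoid_graph(spec, loop_excess = 10000),
               "infeasible")
})

test_that("phantom generation is deterministic in the seed", {
  spec <- phantom_spec(seed = 7)
  g1 <- generate_sinusoid_graph(spec)
  g2 <- generate_sinusoid_graph(spec)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$nodes, g2$nodes)
  spec2 <- phantom_spec(n_lobules = 2, grid_shape = c(72, 300, 160),
                        lobule_radius_um = 55, seed = 7)
  f1 <- generate_lobule_field(spec2)
  f2 <- generate_lobule_field(spec2)
  expect_identical(f1$lobule_labels$data, f2$lobule_labels$data)
  expect_identical(f1$cv_mask$data, f2$cv_mask$data)
})

test_that("rasterized tubes have the analytic cylinder volume", {
  L <- 100
  g <- polyline_graph(cbind(20, 20, seq(10, 10 + L, by = 1)))
  vol <- rasterize_graph(g, c(1, 1, 1), 3)
  measured <- sum(vol$data) * voxel_um3(vol)
  expect_lt(abs(measured / (pi * 9 * L) - 1), 0.10)
  # empty graph rasterizes to an all-false volume
  g0 <- vessel_graph(data.frame(z_um = numeric(0), y_um = numeric(0),
                                x_um = numeric(0)),
                     data.frame(from = integer(0), to = integer(0)))
  expect_false(any(rasterize_graph(g0, c(1, 1, 1), 3)$data))
  # Y-shaped graph rasterizes to one connected component
  gy <- vessel_graph(
    data.frame(z_um = c(20, 20, 20, 20), y_um = c(40, 10, 70, 40),
               x_um = c(40, 40, 20, 80)),
    data.frame(from = c(1, 1, 1), to = c(2, 3, 4)))
  voly <- rasterize_graph(gy, c(1, 1, 1), 3)
  expect_equal(max(label_components(voly$data)), 1)
  expect_warning(rasterize_graph(g, c(4, 4, 4), 1), "radius")
})

test_that("lobule fields have one central vein per labeled lobule", {
  spec <- phantom_spec(seed = 5)
  f <- generate_lobule_field(spec)
  expect_equal(max(f$lobule_labels$data), 1)
  expect_equal(max(label_components(f$cv_mask$data)), 1)
  # constructed oblate ratios classify as oblate downstream
  axes <- fit_ellipsoid(voxel_volume(f$lobule_labels$data == 1L,
                                     spec$spacing))
  expect_equal(classify_shape(axes), "oblate")
  # every CV voxel lies inside its lobule
  expect_true(all(f$lobule_labels$data[f$cv_mask$data] == 1L))
})

test_that("scattered cells realize the requested distribution-index law", {
  spec <- phantom_spec(seed = 31)
  f <- generate_lobule_field(spec)
  n <- 3000
  cells <- scatter_cells(f$lobule_labels, f$cv_mask, c(-1.5, 0.7), n,
                         seed = 31)
  expect_equal(nrow(cells), n)
  expect_true(all(cells$rho >= 0 & cells$rho <= 1))
  # achieved rho equals the drawn target (construction is exact)
  expect_lt(stats::quantile(abs(cells$rho - cells$rho_target), 0.99), 1e-6)
  # sample mean within 3 standard errors of the truncated-law mean
  mu_ref <- hepatograph:::tlnorm_mean(-1.5, 0.7)
  se <- sd(cells$rho) / sqrt(n)
  expect_lt(abs(mean(cells$rho) - mu_ref), 3 * se)
  expect_error(scatter_cells(f$lobule_labels, f$cv_mask, c(-1.5, 0.7), 0),
               "at least 1")
  expect_error(scatter_cells(f$lobule_labels, f$cv_mask, c(NA, 0.7), 5),
               "finite")
})

test_that("cells forced to rho = 1 sit on the central vein", {
  spec <- phantom_spec(seed = 32)
  f <- generate_lobule_field(spec)
  cells <- scatter_cells(f$lobule_labels, f$cv_mask, spec$rho_lognormal, 25,
                         seed = 32, rho_values = 1)
  expect_lt(max(cells$D1_um), 1e-6)
  expect_equal(cells$rho, rep(1, 25))
})

test_that("stored cell distances are reproducible from the masks", {
  spec <- phantom_spec(seed = 33)
  f <- generate_lobule_field(spec)
  cells <- scatter_cells(f$lobule_labels, f$cv_mask, spec$rho_lognormal, 400,
                         seed = 33)
  tab <- assign_cell_geometry(cells[, c("cell_id", "z_um", "y_um", "x_um")],
                              f$cv_mask, f$lobule_labels)
  diag_um <- sqrt(sum(spec$spacing^2))
  expect_lt(max(abs(tab$D1_um - cells$D1_um)), diag_um)
  expect_lt(max(abs(tab$D2_um - cells$D2_um)), diag_um)
})

test_that("metastasis phantoms record exact ground truth", {
  spec <- phantom_spec(seed = 6, metastasis_spec =
                         metastasis_phantom_spec(n_foci = 4,
                                                 diameter_range_um = c(25, 45),
                                                 shell_fill = 0))
  f <- generate_lobule_field(spec)
  mp <- generate_metastasis_phantom(spec, f$pv_mask, f$lobule_labels)
  expect_false(any(mp$gfp_mask$data))          # fill 0: no macrophage signal
  expect_equal(mp$metastasis_table$sigma, rep(0, 4))
  # a 100 um focus is a micrometastasis (100 < 200)
  spec2 <- phantom_spec(seed = 6, grid_shape = c(110, 220, 220),
                        lobule_radius_um = 95, axis_ratios = c(1, 1, 1),
                        metastasis_spec = metastasis_phantom_spec(
                          n_foci = 1, diameter_range_um = c(100, 100)))
  f2 <- generate_lobule_field(spec2)
  mp2 <- generate_metastasis_phantom(spec2, f2$pv_mask, f2$lobule_labels)
  expect_true(mp2$metastasis_table$is_micrometastasis)
  # focus 150 um, shell 20 um, fill 1: shell volume near analytic
  spec3 <- phantom_spec(seed = 8, grid_shape = c(150, 260, 260),
                        lobule_radius_um = 110, axis_ratios = c(1, 1, 1),
                        metastasis_spec = metastasis_phantom_spec(
                          n_foci = 1, diameter_range_um = c(150, 150),
                          shell_thickness_um = 20, shell_fill = 1))
  f3 <- generate_lobule_field(spec3)
  mp3 <- generate_metastasis_phantom(spec3, f3$pv_mask, f3$lobule_labels)
  an <- 4 / 3 * pi * (95^3 - 75^3)
  expect_lt(abs(mp3$metastasis_table$shell_volume_um3 / an - 1), 0.10)
  # an oversized focus is rejected
  spec4 <- phantom_spec(seed = 8, metastasis_spec = metastasis_phantom_spec(
    n_foci = 1, diameter_range_um = c(150, 150)))
  f4 <- generate_lobule_field(spec4)
  expect_error(generate_metastasis_phantom(spec4, f4$pv_mask,
                                           f4$lobule_labels),
               "exceeds lobule diameter")
})

test_that("phantom specs are validated", {
  expect_error(phantom_spec(spacing = c(0, 1, 1)), "positive")
  expect_error(phantom_spec(lobule_radius_um = -5), "positive")
  expect_error(phantom_spec(grid_shape = c(16, 16, 16)), "too small")
  expect_error(phantom_spec(n_lobules = 50), "too small")
})
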
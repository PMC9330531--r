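test_that("skeletonization reduces tubes to centerlines and preserves topology", {
  # solid straight cylinder -> a single voxel chain between the ends
  arr <- array(FALSE, c(21, 21, 60))
  co <- as.matrix(expand.grid(1:21, 1:21, 1:60))
  arr[co[sqrt((co[, 1] - 11)^2 + (co[, 2] - 11)^2) <= 5, , drop = FALSE]] <- TRUE
  g <- build_graph(skeletonize(voxel_volume(arr, c(1, 1, 1))))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sort(g$nodes$degree), c(1, 1))

  # solid torus -> one component with one independent loop
  arr <- array(FALSE, c(15, 41, 41))
  co <- as.matrix(expand.grid(1:15, 1:41, 1:41))
  dd <- sqrt((sqrt((co[, 2] - 21)^2 + (co[, 3] - 21)^2) - 12)^2 + (co[, 1] - 8)^2)
  arr[co[dd <= 4, , drop = FALSE]] <- TRUE
  g <- build_graph(skeletonize(voxel_volume(arr, c(1, 1, 1))))
  expect_equal(g$components, 1)
  expect_equal(cyclomatic_number(g), 1)
  g <- prune_spurs(g, 9)
  expect_equal(nrow(g$nodes), 1)  # anchor node with a self-loop
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$nodes$degree, 2)

  # empty volume -> empty skeleton, empty graph
  sk <- skeletonize(voxel_volume(array(FALSE, c(6, 6, 6)), c(1, 1, 1)))
  expect_false(any(sk$data))
  expect_equal(nrow(build_graph(sk)$nodes), 0)

  expect_error(skeletonize(voxel_volume(array(1, c(4, 4, 4)), c(1, 1, 1))),
               "logical")
})

test_that("graphs are built correctly from constructed skeletons", {
  # straight chain of 50 voxels
  arr <- array(FALSE, c(5, 5, 54))
  arr[3, 3, 3:52] <- TRUE
  g <- build_graph(voxel_volume(arr, c(1, 1, 1)))
  expect_equal(c(nrow(g$nodes), nrow(g$edges)), c(2, 1))
  expect_equal(sort(g$nodes$degree), c(1, 1))
  expect_equal(g$edges$length_um, 49)

  # symmetric Y: three arms from one junction voxel
  arr <- array(FALSE, c(5, 41, 41))
  arr[3, 21, 21:35] <- TRUE
  for (k in 1:14) {
    arr[3, 21 - k, 21 - k] <- TRUE
    arr[3, 21 + k, 21 - k] <- TRUE
  }
  g <- build_graph(voxel_volume(arr, c(1, 1, 1)), smooth_iter = 0)
  expect_equal(c(nrow(g$nodes), nrow(g$edges)), c(4, 3))
  expect_equal(sort(g$nodes$degree), c(1, 1, 1, 3))

  # closed loop with no junction -> one anchor node with a self-loop
  # (a diamond: every voxel has exactly two 26-neighbours)
  arr <- array(FALSE, c(5, 21, 21))
  r <- 8; ctr <- 11
  for (k in 0:(r - 1)) {
    arr[3, ctr - r + k, ctr + k] <- TRUE
    arr[3, ctr + k, ctr + r - k] <- TRUE
    arr[3, ctr + r - k, ctr - k] <- TRUE
    arr[3, ctr - k, ctr - r + k] <- TRUE
  }
  g <- build_graph(voxel_volume(arr, c(1, 1, 1)))
  expect_equal(c(nrow(g$nodes), nrow(g$edges)), c(1, 1))
  expect_equal(g$nodes$degree, 2)
  expect_equal(cyclomatic_number(g), 1)  # Euler: E - V + C = 1
})

test_that("spur pruning removes short hairs and never removes loops", {
  y <- vessel_graph(
    data.frame(z_um = c(0, 0, 0, 0), y_um = c(0, 30, -30, 0),
               x_um = c(0, 30, 30, -2)),
    data.frame(from = c(1, 1, 1), to = c(2, 3, 4)))
  expect_identical(prune_spurs(y, 0), y)    # threshold 0: identity
  p <- prune_spurs(y, 5)                    # drop the 2-um hair, dissolve
  expect_equal(c(nrow(p$nodes), nrow(p$edges)), c(2, 1))
  expect_equal(p$edges$length_um, 2 * sqrt(2 * 30^2))

  ring <- abstract_graph(cbind(1:6, c(2:6, 1)))
  p2 <- prune_spurs(ring, 1e6)              # cycles have no terminal edges
  expect_equal(nrow(p2$edges), 6)
  expect_equal(cyclomatic_number(p2), 1)

  # cyclomatic number is invariant under pruning of a hairy loop
  hairy <- vessel_graph(
    data.frame(z_um = rep(0, 4), y_um = c(0, 10, 5, 5), x_um = c(0, 0, 8, 9)),
    data.frame(from = c(1, 1, 2, 3), to = c(2, 2, 3, 4)))
  expect_equal(cyclomatic_number(prune_spurs(hairy, 3)),
               cyclomatic_number(hairy))
})

test_that("edge measurements match analytic geometry", {
  # straight tube through the full pipeline: tortuosity exactly 1
  g <- polyline_graph(cbind(10, 10, seq(5, 95, by = 1)))
  vol <- rasterize_graph(g, c(0.5, 0.5, 0.5), 3)
  m <- measure_edges(build_graph(skeletonize(vol)), vol)
  expect_equal(m$edges$tortuosity, 1, tolerance = 1e-9)
  # radius from the distance transform: within 0.5 um of the true 3 um
  expect_lt(abs(m$edges$mean_radius_um - 3), 0.5)

  # semicircular tube: tortuosity = pi/2 within 2%
  th <- seq(0, pi, length.out = 400)
  g <- polyline_graph(cbind(10, 40 * sin(th) + 50, 40 * cos(th) + 50))
  vol <- rasterize_graph(g, c(1, 1, 1), 3)
  m <- measure_edges(prune_spurs(build_graph(skeletonize(vol)), 9), vol)
  expect_equal(nrow(m$edges), 1)
  expect_lt(abs(m$edges$tortuosity / (pi / 2) - 1), 0.02)

  # tortuosity >= 1 wherever defined
  spec <- phantom_spec(seed = 41)
  gph <- generate_sinusoid_graph(spec)
  expect_true(all(gph$edges$tortuosity >= 1 - 1e-9, na.rm = TRUE))
  # self-loops report tortuosity as missing
  loop <- vessel_graph(data.frame(z_um = 0, y_um = 0, x_um = 0),
                       data.frame(from = 1, to = 1),
                       list(cbind(c(0, 0, 5, 5, 0), c(0, 5, 5, 0, 0), 0)))
  expect_true(is.na(loop$edges$tortuosity))
})

test_that("macro-vessel labelling follows geodesic distance", {
  # two disjoint tubes, one seed in each: uniform labels
  arr <- array(FALSE, c(7, 20, 40))
  arr[3:5, 4:6, 3:38] <- TRUE
  arr[3:5, 14:16, 3:38] <- TRUE
  v <- voxel_volume(arr, c(1, 1, 1))
  lab <- label_macro_trees(v, cv_seeds = matrix(c(4, 5, 5), 1),
                           pv_seeds = matrix(c(4, 15, 5), 1))
  expect_true(all(lab$data[arr[, , , drop = FALSE] &
                             slice.index(arr, 2) <= 10] %in% 1L))
  expect_true(all(lab$data[arr & slice.index(arr, 2) > 10] %in% 2L))

  # one tube, seeds at the two ends: boundary at the geodesic midpoint +/- 1
  arr <- array(FALSE, c(9, 9, 61))
  arr[4:6, 4:6, 1:61] <- TRUE
  v <- voxel_volume(arr, c(1, 1, 1))
  lab <- label_macro_trees(v, cv_seeds = matrix(c(5, 5, 1), 1),
                           pv_seeds = matrix(c(5, 5, 61), 1))
  cv_extent <- max(which(apply(lab$data == 1L, 3, any)))
  expect_lt(abs(cv_extent - 31), 1.5)

  # empty mask: error-free all-unknown output
  lab0 <- label_macro_trees(voxel_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
                            cv_seeds = matrix(c(1, 1, 1), 1),
                            pv_seeds = matrix(c(2, 2, 2), 1))
  expect_true(all(lab0$data == 0L))

  expect_error(label_macro_trees(v, cv_seeds = matrix(c(1, 1, 1), 1),
                                 pv_seeds = matrix(c(5, 5, 61), 1)),
               "seed outside mask")
})

test_that("rasterize/skeletonize/build recovers the generated graph", {
  for (seed in c(51, 52, 53)) {
    spec <- phantom_spec(seed = seed, edge_bow = 0.12)
    g <- generate_sinusoid_graph(spec)
    rec <- roundtrip_graph(g, spec$sinusoid_radius_um)
    expect_true(same_topology(dissolve_chains(g), rec),
                label = paste("round trip seed", seed))
  }
})

test_that("edge lengths are stable under sub-voxel perturbations", {
  spec <- phantom_spec(seed = 54, edge_bow = 0.12)
  g <- generate_sinusoid_graph(spec)
  total <- sum(g$edges$length_um)
  set.seed(1)
  g2 <- g
  g2$polylines <- lapply(g$polylines, function(p)
    p + matrix(runif(length(p), -0.05, 0.05), nrow(p), 3))
  g2 <- hepatograph:::measure_polylines(g2)
  expect_lt(abs(sum(g2$edges$length_um) - total) / total, 0.01)
})

test_that("graphs survive a GraphML round trip", {
  spec <- phantom_spec(seed = 55)
  g <- generate_sinusoid_graph(spec, n_nodes = 40, loop_excess = 8)
  f <- tempfile(fileext = ".graphml")
  write_vessel_graph(g, f)
  g2 <- read_vessel_graph(f)
  expect_equal(nrow(g2$nodes), nrow(g$nodes))
  expect_equal(nrow(g2$edges), nrow(g$edges))
  expect_equal(sort(g2$nodes$degree), sort(g$nodes$degree))
  expect_equal(sum(g2$edges$length_um), sum(g$edges$length_um),
               tolerance = 1e-6)
  unlink(f)
})
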
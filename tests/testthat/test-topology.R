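test_that("edge/node ratio counts multi-edges and satisfies Euler's identity", {
  tree <- abstract_graph(cbind(2:255, sapply(2:255, function(i) i %/% 2)),
                         nv = 255)
  expect_equal(edge_node_ratio(tree), 254 / 255)
  ring <- abstract_graph(cbind(1:7, c(2:7, 1)))
  expect_equal(edge_node_ratio(ring), 1)
  empty <- vessel_graph(data.frame(z_um = numeric(0), y_um = numeric(0),
                                   x_um = numeric(0)),
                        data.frame(from = integer(0), to = integer(0)))
  expect_error(edge_node_ratio(empty), "empty")
  # identity ratio = 1 + (cyclomatic - components) / V on random graphs
  set.seed(3)
  for (i in 1:20) {
    rg <- random_simple_graph()
    g <- abstract_graph(rg$el, rg$nv)
    expect_equal(edge_node_ratio(g),
                 1 + (cyclomatic_number(g) - g$components) / nrow(g$nodes))
  }
})

test_that("degree statistics count self-loops twice and flag degree > 3", {
  ring <- abstract_graph(cbind(1:6, c(2:6, 1)))
  ds <- degree_stats(ring)
  expect_equal(unname(ds$histogram[["2"]]), 6)
  expect_equal(ds$high_degree_fraction, 0)
  star <- abstract_graph(cbind(rep(1, 5), 2:6))
  ds <- degree_stats(star)
  expect_equal(unname(ds$histogram[["5"]]), 1)
  expect_equal(ds$high_degree_fraction, 1 / 6)
  withloop <- abstract_graph(rbind(c(1, 1), c(1, 2)))
  expect_equal(max(withloop$nodes$degree), 3)  # self-loop counts twice
  # phantom: histogram equals the generator's ground-truth degrees
  spec <- phantom_spec(seed = 61)
  g <- generate_sinusoid_graph(spec)
  ds <- degree_stats(g)
  expect_equal(sum(ds$histogram), nrow(g$nodes))
  expect_equal(as.integer(ds$histogram[as.character(sort(unique(g$nodes$degree)))]),
               as.integer(table(g$nodes$degree)))
})

test_that("the lognormal fit recovers parameters and flags degeneracy", {
  f <- fit_lognormal(rep(exp(1), 10))
  expect_equal(f$mu, 1)
  expect_equal(f$sigma, 0)
  expect_true(f$degenerate)
  set.seed(99)
  x <- rlnorm(10000, 0.5, 0.25)
  f <- fit_lognormal(x)
  expect_lt(abs(f$mu - 0.5), 4 * 0.25 / sqrt(10000))
  expect_lt(abs(f$sigma - 0.25), 4 * 0.25 / sqrt(2 * 10000))
  # an exponential sample fits worse than a matched lognormal sample
  set.seed(100)
  e <- stats::rexp(2000, 1)
  l <- rlnorm(2000, 0, 0.5)
  expect_gt(fit_lognormal(e)$ks_stat, fit_lognormal(l)$ks_stat)
  expect_error(fit_lognormal(c(1, 2, 3)), "at least 8")
  expect_error(fit_lognormal(c(rep(1, 8), -1)), "positive")
})

test_that("clustering coefficient and centralization match closed forms", {
  tri <- abstract_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clustering_coefficient(tri), 1)
  tree <- abstract_graph(cbind(2:8, c(1, 1, 2, 2, 3, 3, 4)))
  expect_equal(clustering_coefficient(tree), 0)
  sq <- abstract_graph(cbind(1:4, c(2:4, 1)))
  expect_equal(clustering_coefficient(sq), 0)   # 4-cycle has no triangles
  star <- abstract_graph(cbind(rep(1, 5), 2:6))
  expect_equal(degree_centralization(star), 1)
  ring <- abstract_graph(cbind(1:6, c(2:6, 1)))
  expect_equal(degree_centralization(ring), 0)
  k4 <- abstract_graph(t(combn(4, 2)))          # 3-regular
  expect_equal(degree_centralization(k4), 0)
})

test_that("the loop census is a minimum cycle basis", {
  hexagon <- abstract_graph(cbind(1:6, c(2:6, 1)))
  lc <- loop_census(hexagon)
  expect_equal(lc$census, c("6" = 1L))
  two_tri <- abstract_graph(rbind(c(1, 2), c(2, 3), c(1, 3), c(2, 4), c(3, 4)))
  lc <- loop_census(two_tri)
  expect_equal(lc$census, c("3" = 2L))          # both triangles, not the 4-cycle
  acyclic <- abstract_graph(cbind(2:6, rep(1, 5)))
  expect_equal(loop_census(acyclic)$total, 0)
  # self-loops and parallel edges census as 1- and 2-edge loops
  multi <- abstract_graph(rbind(c(1, 1), c(1, 2), c(1, 2), c(2, 3)))
  lc <- loop_census(multi)
  expect_equal(lc$census, c("1" = 1L, "2" = 1L))
  expect_equal(lc$total, cyclomatic_number(multi))
  # brute-force oracle over the cycle space on random graphs
  set.seed(7)
  for (i in 1:40) {
    rg <- random_simple_graph()
    lc <- loop_census(abstract_graph(rg$el, rg$nv))
    oracle <- brute_mcb(rg$nv, rg$el)
    expect_equal(lc$total, oracle$total)
    expect_equal(lc$total_edge_weight, oracle$weight)
  }
})

test_that("the census total always equals the cyclomatic number", {
  set.seed(8)
  for (i in 1:15) {
    rg <- random_simple_graph()
    g <- abstract_graph(rg$el, rg$nv)
    expect_equal(loop_census(g)$total, cyclomatic_number(g))
  }
  spec <- phantom_spec(seed = 62)
  g <- generate_sinusoid_graph(spec)
  expect_equal(loop_census(g)$total, cyclomatic_number(g))
})

test_that("branch angles match constructed junction geometry", {
  # straight chain through a degree-2 node: a single 180-degree angle
  chain <- vessel_graph(data.frame(z_um = c(0, 0, 0), y_um = c(0, 0, 0),
                                   x_um = c(0, 10, 20)),
                        data.frame(from = c(1, 2), to = c(2, 3)))
  a <- branch_angles(chain)
  expect_equal(a$mean_angle_deg, 180, tolerance = 1e-9)
  # planar symmetric trivalent node: all angles 120
  tri <- vessel_graph(
    data.frame(z_um = c(0, 0, 0, 0),
               y_um = c(0, 0, sin(2 * pi / 3), -sin(2 * pi / 3)) * 20,
               x_um = c(0, 20, 20 * cos(2 * pi / 3), 20 * cos(2 * pi / 3))),
    data.frame(from = c(1, 1, 1), to = c(2, 3, 4)))
  a <- branch_angles(tri)
  expect_equal(a$mean_angle_deg, 120, tolerance = 1e-9)
  expect_equal(a$mean_min_angle_deg, 120, tolerance = 1e-9)
  # orthogonal T-junction: angles {90, 90, 180}, minimum 90
  tj <- vessel_graph(
    data.frame(z_um = c(0, 0, 0, 0), y_um = c(0, 0, 0, 15),
               x_um = c(0, -15, 15, 0)),
    data.frame(from = c(1, 1, 1), to = c(2, 3, 4)))
  a <- branch_angles(tj)
  expect_equal(sort(a$angles_deg), c(90, 90, 180), tolerance = 1e-9)
  expect_equal(a$mean_min_angle_deg, 90, tolerance = 1e-9)
  expect_error(branch_angles(abstract_graph(cbind(1, 2))), "two or more")
})

test_that("angle statistics are invariant under global rotation", {
  spec <- phantom_spec(seed = 63)
  g <- generate_sinusoid_graph(spec, n_nodes = 60, loop_excess = 12)
  a1 <- branch_angles(g)
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  g2 <- g
  g2$polylines <- lapply(g$polylines, function(p) p %*% t(R))
  pos <- as.matrix(g$nodes[, c("z_um", "y_um", "x_um")]) %*% t(R)
  g2$nodes$z_um <- pos[, 1]; g2$nodes$y_um <- pos[, 2]; g2$nodes$x_um <- pos[, 3]
  a2 <- branch_angles(g2)
  expect_equal(a1$mean_angle_deg, a2$mean_angle_deg, tolerance = 1e-6)
  expect_equal(a1$mean_min_angle_deg, a2$mean_min_angle_deg, tolerance = 1e-6)
})

test_that("densities scale counts by the reference volume", {
  expect_equal(densities(100, 0.2), 500)
  expect_equal(densities(c(`4` = 0, `5` = 0), 0.5), c(`4` = 0, `5` = 0))
  x <- densities(c(10, 20), 0.1)
  expect_equal(densities(c(10, 20), 0.2), x / 2)  # doubling volume halves
  expect_error(densities(10, 0), "positive")
})

test_that("the topology report assembles all statistics", {
  spec <- phantom_spec(seed = 64)
  g <- generate_sinusoid_graph(spec)
  rep <- topology_report(g, reference_volume_mm3 = 0.002)
  expect_equal(rep$edge_node_ratio, nrow(g$edges) / nrow(g$nodes))
  expect_equal(sum(rep$loop_census), cyclomatic_number(g))
  expect_equal(rep$edges_per_mm3, nrow(g$edges) / 0.002)
  expect_true(rep$clustering_coefficient >= 0 && rep$clustering_coefficient <= 1)
  expect_true(rep$degree_centralization >= 0 && rep$degree_centralization <= 1)
})
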
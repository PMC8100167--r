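test_that("graph index complexity vanishes at both connectivity extremes", {
  for (n in c(4, 7, 10)) {
    expect_equal(graph_index_complexity(path_net(n)), 0, tolerance = 1e-9)
    expect_equal(graph_index_complexity(complete_net(n)), 0, tolerance = 1e-9)
  }
  # C5: lambda_max = 2, closed form c_r = (2 - sqrt(3)) / (4 - sqrt(3))
  cr5 <- (2 - sqrt(3)) / (4 - sqrt(3))
  expect_equal(graph_index_complexity(cycle_net(5)), 4 * cr5 * (1 - cr5),
               tolerance = 1e-9)
  expect_error(graph_index_complexity(path_net(2)), "n >= 3")
})

test_that("medium articulation peaks at medium density, not at the extremes", {
  # I + R = log(2m) identically, so check via the normalised split
  medium <- two_triangles_bridge()
  expect_gt(medium_articulation(medium), medium_articulation(path_net(6)))
  expect_gt(medium_articulation(medium), medium_articulation(complete_net(6)))
  expect_equal(medium_articulation(path_net(2)), 0)   # K2: I = log(2m), R = 0
  for (seed in 1:5) {
    net <- random_connected_net(6 + seed, seed = 600 + seed)
    v <- medium_articulation(net)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("efficiency complexity vanishes on paths and complete graphs", {
  for (n in c(3, 5, 9)) {
    expect_equal(efficiency_complexity(path_net(n)), 0, tolerance = 1e-12)
    expect_equal(efficiency_complexity(complete_net(n)), 0, tolerance = 1e-12)
  }
  # C5 oracle: E = mean over ordered pairs of 1/d, distances 1,1,2,2 per node
  e_c5 <- mean(c(1, 1, 1 / 2, 1 / 2))
  e_p5 <- bf_efficiency(path_net(5))
  ce <- (e_c5 - e_p5) / (1 - e_p5)
  expect_equal(efficiency_complexity(cycle_net(5)), 4 * ce * (1 - ce),
               tolerance = 1e-12)
})

test_that("offdiagonal complexity is zero for regular and single-pair graphs", {
  expect_equal(offdiagonal_complexity(cycle_net(6)), 0)   # 2-regular
  expect_equal(offdiagonal_complexity(complete_net(5)), 0)
  expect_equal(offdiagonal_complexity(star_net(4)), 0)    # one (1,4) cell
  # P4 oracle: edges at degree pairs (1,2),(2,2),(2,1): diagonals d=1,0,1
  # -> distribution (1/3, 2/3) over populated, D = 2 possible offdiagonals
  p <- c(1 / 3, 2 / 3)
  expect_equal(offdiagonal_complexity(path_net(4)),
               -sum(p * log(p)) / log(2), tolerance = 1e-12)
})

test_that("spanning tree counts match closed forms and brute enumeration", {
  expect_equal(spanning_tree_count(path_net(6)), 1)       # any tree
  expect_equal(spanning_tree_count(star_net(5)), 1)
  for (n in c(3, 5, 8)) expect_equal(spanning_tree_count(cycle_net(n)), n)
  expect_equal(spanning_tree_count(complete_net(4)), 16)  # Cayley 4^2
  expect_equal(spanning_tree_count(complete_net(5)), 125)
  for (seed in 1:8) {
    net <- random_connected_net(n = 5 + seed %% 3, seed = 700 + seed)
    expect_equal(spanning_tree_count(net), bf_spanning_trees(net))
  }
  disc <- net_from_edges(rbind(c(1, 2), c(3, 4)), require_connected = FALSE)
  expect_equal(spanning_tree_count(disc), 0)
  expect_equal(spanning_tree_count(disc, log = TRUE), -Inf)
})

test_that("log-domain spanning tree count is consistent with exact count", {
  net <- random_connected_net(12, p = 0.4, seed = 99)
  expect_equal(spanning_tree_count(net, log = TRUE),
               log(spanning_tree_count(net)), tolerance = 1e-9)
})

test_that("spanning tree sensitivity: edge-transitive graphs have STSD = 0", {
  c5 <- spanning_tree_sensitivity(cycle_net(5))
  expect_equal(c5$STSD, 0)
  expect_equal(c5$STS, 1 - 1 / 5)          # each deletion leaves one tree
  k4 <- spanning_tree_sensitivity(complete_net(4))
  expect_equal(k4$STSD, 0)                 # all ST(K4 - e) equal
  # oracle: ST(K4 - e) = 8 by enumeration
  k4e <- net_from_edges(rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(bf_spanning_trees(k4e), 8L)
  expect_equal(k4$STS, 1 - 8 / 16)
  # trees: every edge is a bridge -> maximal sensitivity
  expect_equal(spanning_tree_sensitivity(star_net(4))$STS, 1)
})

test_that("one-edge-deleted complexity counts distinct subgraphs", {
  for (n in c(4, 6, 9)) {
    res <- one_edge_deleted_complexity(cycle_net(n))
    expect_equal(res$C1e_ST, 1 / n)
    expect_equal(res$C1e_spec, 1 / n)
  }
  k4 <- one_edge_deleted_complexity(complete_net(4))
  expect_equal(k4$C1e_ST, 1 / 6)
  expect_equal(k4$C1e_spec, 1 / 6)
})

test_that("the full panel stays in [0,1] on random connected graphs", {
  for (seed in 1:150) {
    net <- random_connected_net(n = 4 + seed %% 9, seed = 800 + seed)
    panel <- complexity_panel(net)
    expect_true(all(panel >= 0 & panel <= 1),
                info = paste("seed", seed, ":",
                             paste(names(panel), round(panel, 4),
                                   collapse = " ")))
    # determinism
    expect_identical(panel, complexity_panel(net))
  }
})
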
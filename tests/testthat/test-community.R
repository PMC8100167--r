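test_that("modularity_q matches hand-derived values on the bridged triangles", {
  net <- two_triangles_bridge()
  triangles <- stats::setNames(c(1, 1, 1, 2, 2, 2), net$labels)
  # within = 6 of 7 edges; both modules have total degree 7:
  # Q = 6/7 - 2*(7/14)^2 = 5/14
  expect_equal(modularity_q(net, triangles), 5 / 14)

  expect_equal(modularity_q(net, rep(1, 6)), 0)           # single community
  k <- igraph::degree(net$graph)
  singletons <- stats::setNames(1:6, net$labels)
  expect_equal(modularity_q(net, singletons), -sum((k / 14)^2))
  expect_lt(modularity_q(net, singletons), 0)

  expect_error(modularity_q(net, stats::setNames(1:6, letters[1:6])),
               "unknown node")
  expect_error(modularity_q(net, 1:4), "cover")
})

test_that("modularity_q agrees with igraph's implementation (dual route)", {
  for (seed in 1:15) {
    net <- random_connected_net(n = 6 + seed %% 6, seed = 200 + seed)
    withr::local_seed(seed)
    memb <- sample(1:3, net$n, replace = TRUE)
    expect_equal(modularity_q(net, stats::setNames(memb, net$labels)),
                 igraph::modularity(net$graph, memb),
                 tolerance = 1e-12)
  }
})

test_that("detect_modules recovers the exhaustive maximum on tiny graphs", {
  nets <- list(two_triangles_bridge(), cycle_net(7), star_net(5),
               random_connected_net(7, seed = 42),
               random_connected_net(8, seed = 43))
  for (net in nets) {
    found <- detect_modules(net, seed = 7, restarts = 30)
    oracle <- max_modularity_exhaustive(net)
    expect_equal(found$q_value, oracle$q_value, tolerance = 1e-9)
    expect_equal(modularity_q(net, found$assignment), found$q_value,
                 tolerance = 1e-12)
  }
})

test_that("detect_modules on the bridged triangles finds the 2-module optimum", {
  part <- detect_modules(two_triangles_bridge(), seed = 1, restarts = 20)
  expect_equal(part$q_value, 5 / 14, tolerance = 1e-9)
  expect_equal(part$n_modules, 2L)
  expect_gte(part$q_value, 0)          # never worse than one community
  expect_error(detect_modules(morph_network(matrix(0, 1, 1))), "degenerate")
})

test_that("zp_roles computes z and P with the documented conventions", {
  net <- two_triangles_bridge()
  part <- detect_modules(net, seed = 1, restarts = 10)
  roles <- zp_roles(net, part)
  # nodes 1,2,5,6 have all links inside their module -> P = 0
  expect_equal(roles$P[roles$label %in% c("n001", "n002", "n005", "n006")],
               rep(0, 4))
  # bridge endpoints: 2 of 3 links internal -> P = 1 - (2/3)^2 - (1/3)^2
  expect_equal(roles$P[roles$label == "n003"], 1 - 4 / 9 - 1 / 9)
  expect_true(all(roles$P < 1))
  # z averages to zero within modules that have degree spread
  for (mod in unique(roles$module)) {
    zs <- roles$z[roles$module == mod]
    if (any(zs != 0)) expect_equal(mean(zs), 0, tolerance = 1e-12)
  }
})

test_that("z is zero in degree-uniform modules and regions use paper bounds", {
  net <- cycle_net(6)                      # all degrees equal
  roles <- zp_roles(net, stats::setNames(rep(1, 6), net$labels))
  expect_equal(roles$z, rep(0, 6))
  expect_equal(roles$P, rep(0, 6))
  expect_equal(as.character(unique(roles$region)), "peripheral")

  # boundary inclusivity: z >= 2.75 is super-hub, P >= 0.4 connector
  expect_equal(morphonet:::zp_region(2.75, 0.4), "connector super-hub")
  expect_equal(morphonet:::zp_region(2.75, 0.39), "local super-hub")
  expect_equal(morphonet:::zp_region(1, 0.75), "connector hub")
  expect_equal(morphonet:::zp_region(0.99, 0.75), "non-hub hyper-connector")
  expect_equal(morphonet:::zp_region(0.99, 0.4), "non-hub connector")
  expect_equal(morphonet:::zp_region(0.99, 0.399), "peripheral")
})

test_that("region_census counts every node once and sums to 100%", {
  series <- phase_series(1)
  for (net in series) {
    part <- detect_modules(net, seed = 3, restarts = 20)
    cen <- region_census(zp_roles(net, part))
    expect_equal(sum(cen$count), net$n)
    expect_equal(sum(cen$percent), 100)
  }
})

test_that("a degree-uniform single-module graph is 100% one region", {
  net <- complete_net(4)                   # Louvain: one community
  part <- detect_modules(net, seed = 1, restarts = 10)
  cen <- region_census(zp_roles(net, part))
  expect_equal(max(cen$percent), 100)
  expect_equal(cen$region[which.max(cen$percent)], "peripheral")
})
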
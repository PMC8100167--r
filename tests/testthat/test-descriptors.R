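test_that("distance descriptors match hand evaluations", {
  p4 <- distance_descriptors(path_net(4))
  expect_equal(p4$wiener, 10)
  # DS = (6,4,4,6); J = (3/1) * (1/sqrt(24) + 1/sqrt(16) + 1/sqrt(24))
  expect_equal(p4$balaban_j, 3 * (2 / sqrt(24) + 1 / 4), tolerance = 1e-12)
  expect_equal(p4$compactness, 10 / 6)     # mean distance over 6 pairs

  k3 <- distance_descriptors(complete_net(3))
  expect_equal(k3$wiener, 3)
  expect_equal(k3$harary, 3)
  expect_equal(k3$centralization, 0)       # degree-uniform

  s4 <- distance_descriptors(star_net(4))
  expect_equal(s4$centralization, 4 * 3)   # hub degree 4, leaves degree 1
})

test_that("invariant descriptors match closed forms", {
  s3 <- invariant_descriptors(star_net(3))
  expect_equal(s3$zagreb_m1, 9 + 3)
  expect_equal(s3$randic, 3 / sqrt(3))
  for (n in c(3, 5, 8)) {
    expect_equal(invariant_descriptors(complete_net(n))$normalized_edge_complexity,
                 (n - 1) / n)
  }
})

test_that("entropy descriptors: orbits, eccentricity and edge classes", {
  # vertex-transitive cycle: a single orbit, zero information content
  c6 <- entropy_descriptors(cycle_net(6))
  expect_equal(c6$topological_info_content, 0)
  expect_equal(c6$radial_centric, 0)
  expect_equal(c6$edge_equality, 0)

  # star K1,4: orbit classes {centre} and {4 leaves}
  s4 <- entropy_descriptors(star_net(4))
  expect_equal(s4$topological_info_content,
               -(1 / 5) * log2(1 / 5) - (4 / 5) * log2(4 / 5),
               tolerance = 1e-12)

  # bonchev on K3: W = 3, all distances 1 -> 3*log2(3)
  expect_equal(entropy_descriptors(complete_net(3))$bonchev, 3 * log2(3))
})

test_that("colour-refinement orbits agree with automorphism orbits (n<=7)", {
  nets <- list(path_net(5), star_net(4), cycle_net(6), two_triangles_bridge(),
               random_connected_net(6, seed = 11),
               random_connected_net(7, seed = 12))
  for (net in nets) {
    wl <- vertex_orbits(net)
    exact <- automorphism_orbits(net)
    # same partition: class co-membership matrices must coincide
    expect_equal(outer(wl, wl, "=="), outer(exact, exact, "=="))
  }
})

test_that("spectral descriptors match the K2 spectra", {
  k2 <- spectral_descriptors(path_net(2))
  expect_equal(k2$estrada, exp(1) + exp(-1))
  expect_equal(k2$energy, 2)
  expect_equal(k2$laplacian_estrada, 1 + exp(2))
  expect_equal(k2$laplacian_energy, 2)
  one <- spectral_descriptors(morph_network(matrix(0, 1, 1)))
  expect_equal(one$estrada, 1)
  expect_equal(one$energy, 0)
})

test_that("spectral identities hold on random graphs", {
  for (seed in 1:10) {
    net <- random_connected_net(n = 5 + seed %% 7, seed = 900 + seed)
    a <- adjacency_matrix(net)
    lam <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    mu <- eigen(diag(rowSums(a)) - a, symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(sum(lam), 0, tolerance = 1e-9)
    expect_equal(sum(mu), 2 * net$m, tolerance = 1e-9)
    d <- spectral_descriptors(net)
    expect_gte(d$estrada, net$n)
    expect_gte(d$energy, 0)
  }
})

test_that("descriptors agree with straight-from-formula reimplementations", {
  for (seed in 1:25) {
    net <- random_connected_net(n = 5 + seed %% 8, seed = 1000 + seed)
    d <- bf_distances(net)
    ds <- rowSums(d)
    k <- igraph::degree(net$graph)[net$labels]
    ep <- edge_pairs(net)
    mu <- net$m - net$n + 1

    got <- c(distance_descriptors(net), invariant_descriptors(net),
             entropy_descriptors(net))
    expect_equal(got$wiener, sum(d) / 2)
    expect_equal(got$harary, sum(1 / d[upper.tri(d)]))
    expect_equal(got$balaban_j,
                 net$m / (mu + 1) * sum(1 / sqrt(ds[ep[, 1]] * ds[ep[, 2]])))
    expect_equal(got$compactness, mean(d[upper.tri(d)]))
    expect_equal(got$centralization, sum(max(k) - k))
    expect_equal(got$zagreb_m1, sum(k^2))
    expect_equal(got$randic, sum(1 / sqrt(k[ep[, 1]] * k[ep[, 2]])))
    expect_equal(got$complexity_index_b, sum(k / ds))
    expect_equal(got$normalized_edge_complexity, 2 * net$m / net$n^2)
    dv <- d[upper.tri(d)]
    expect_equal(got$bonchev,
                 sum(dv) * log2(sum(dv)) - sum(dv * log2(dv)))
    expect_equal(got$bertz,
                 2 * net$m * log2(2 * net$m) - sum(k * log2(k)))
  }
})

test_that("wiener ties back to the netio average path length", {
  s <- phase_series(1)
  for (net in s) {
    p <- basic_parameters(net)
    w <- distance_descriptors(net)$wiener
    expect_equal(w, p$avg_path_length * net$n * (net$n - 1) / 2,
                 tolerance = 1e-9)
  }
})
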
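test_that("read_adjacency handles delimiters, headers and label columns", {
  a <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  labels <- c("head", "thorax", "abdomen")

  plain <- withr::local_tempfile(fileext = ".csv")
  writeLines(apply(a, 1, paste, collapse = ","), plain)
  net <- read_adjacency(plain)
  expect_equal(net$n, 3L)
  expect_equal(net$m, 2L)
  expect_equal(net$labels, c("n001", "n002", "n003"))  # synthesized

  labelled <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(c("", labels), collapse = ","),
               paste(labels, apply(a, 1, paste, collapse = ","), sep = ",")),
             labelled)
  net2 <- read_adjacency(labelled)
  expect_equal(net2$labels, labels)
  expect_equal(edge_pairs(net2),
               rbind(c("head", "thorax"), c("abdomen", "head")))

  tabbed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(apply(a, 1, paste, collapse = "\t"), tabbed)
  expect_equal(read_adjacency(tabbed)$m, 2L)

  semi <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste(labels, collapse = ";"),
               apply(a, 1, paste, collapse = ";")), semi)
  expect_equal(read_adjacency(semi)$labels, labels)
})

test_that("read_adjacency rejects malformed matrices with specific errors", {
  bad_square <- withr::local_tempfile()
  writeLines(c("0,1,0", "1,0,1"), bad_square)
  expect_error(read_adjacency(bad_square), "square")

  bad_binary <- withr::local_tempfile()
  writeLines(c("0,2", "2,0"), bad_binary)
  expect_error(read_adjacency(bad_binary), "not binary")

  bad_sym <- withr::local_tempfile()
  writeLines(c("0,1", "0,0"), bad_sym)
  expect_error(read_adjacency(bad_sym), "not symmetric")

  bad_diag <- withr::local_tempfile()
  writeLines(c("1,1", "1,0"), bad_diag)
  expect_error(read_adjacency(bad_diag), "diagonal")

  disc <- withr::local_tempfile()
  writeLines(c("0,1,0,0", "1,0,0,0", "0,0,0,1", "0,0,1,0"), disc)
  expect_error(read_adjacency(disc), "2 components of sizes 2, 2")
  expect_equal(read_adjacency(disc, require_connected = FALSE)$m, 2L)
})

test_that("smallest valid input: single edge on two nodes", {
  two <- withr::local_tempfile()
  writeLines(c("0,1", "1,0"), two)
  net <- read_adjacency(two)
  expect_equal(c(net$n, net$m), c(2L, 1L))
})

test_that("basic_parameters matches closed forms on K4 and P5", {
  k4 <- basic_parameters(complete_net(4))
  expect_equal(k4$diameter, 1L)
  expect_equal(k4$radius, 1L)
  expect_equal(k4$density, 1)
  expect_equal(k4$avg_clustering, 1)
  expect_equal(k4$avg_path_length, 1)

  p5 <- basic_parameters(path_net(5))
  expect_equal(p5$avg_path_length, 2)        # pair-distance sum 20 / 10 pairs
  expect_equal(p5$diameter, 4L)
  expect_equal(p5$radius, 2L)
  expect_equal(p5$avg_degree, 8 / 5)

  expect_error(basic_parameters(morph_network(matrix(0, 1, 1))),
               "avg_path_length undefined")
})

test_that("clustering conventions differ exactly on degree<2 nodes", {
  # triangle with a pendant: local C = 1,1,1/3 defined; pendant undefined
  net <- net_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  expect_equal(avg_clustering_coef(net, "exclude"), (1 + 1 + 1 / 3) / 3)
  expect_equal(avg_clustering_coef(net, "zero"), (1 + 1 + 1 / 3) / 4)
  expect_equal(basic_parameters(net, clustering = "zero")$avg_clustering,
               (1 + 1 + 1 / 3) / 4)
})

test_that("parameter invariants hold on random connected graphs", {
  for (seed in 1:20) {
    net <- random_connected_net(n = 5 + seed %% 8, seed = seed)
    p <- basic_parameters(net)
    expect_lte(p$radius, p$diameter)
    expect_lte(p$diameter, 2 * p$radius)
    expect_equal(p$density * net$n * (net$n - 1) / 2, net$m)
    expect_equal(p$avg_degree, 2 * net$m / net$n)
    expect_gte(p$avg_path_length, 1)
  }
})

test_that("igraph distances agree with Floyd-Warshall oracle on n <= 12", {
  for (seed in 1:10) {
    net <- random_connected_net(n = 6 + seed %% 7, seed = 100 + seed)
    expect_equal(igraph::distances(net$graph)[net$labels, net$labels],
                 bf_distances(net))
  }
})

test_that("write_network round-trips through all three formats", {
  net <- two_triangles_bridge()

  mat <- withr::local_tempfile(fileext = ".csv")
  write_network(net, mat, "matrix")
  expect_same_edges(read_adjacency(mat), net)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), net$n)
  expect_equal(igraph::ecount(back), net$m)

  el <- withr::local_tempfile(fileext = ".txt")
  write_network(path_net(3), el, "edgelist")
  expect_length(readLines(el), 2L)

  expect_error(write_network(net, mat, "dot"), "arg")
})

test_that("synthetic megalopa stand-in round-trips with labels intact", {
  net <- phase_series(1)$megalopa
  f <- withr::local_tempfile(fileext = ".csv")
  write_network(net, f, "matrix")
  expect_same_edges(read_adjacency(f), net)
})
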
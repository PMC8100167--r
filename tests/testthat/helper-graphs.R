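# small-graph constructors and brute-force oracles used across the suite

net_from_edges <- function(edges, n = max(edges), labels = NULL,
                           require_connected = TRUE) {
  a <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- a[edges[r, 2], edges[r, 1]] <- 1L
  }
  morph_network(a, labels = labels, require_connected = require_connected)
}

path_net <- function(n) {
  net_from_edges(cbind(seq_len(n - 1), 2:n), n = n)
}

cycle_net <- function(n) {
  net_from_edges(rbind(cbind(seq_len(n - 1), 2:n), c(n, 1)), n = n)
}

complete_net <- function(n) {
  morph_network(matrix(1L, n, n) - diag(n))
}

star_net <- function(leaves) {
  net_from_edges(cbind(1L, 1L + seq_len(leaves)), n = leaves + 1L)
}

# two triangles joined by one bridge edge (nodes 1:3 and 4:6)
two_triangles_bridge <- function() {
  net_from_edges(rbind(c(1, 2), c(2, 3), c(1, 3),
                       c(4, 5), c(5, 6), c(4, 6), c(3, 4)))
}

random_connected_net <- function(n, p = 2.2 / n, seed = 1) {
  withr::local_seed(seed)
  for (try in 1:200) {
    a <- matrix(0L, n, n)
    up <- which(upper.tri(a))
    a[up] <- stats::rbinom(length(up), 1, p)
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::is_connected(g)) return(morph_network(a))
    p <- min(1, p * 1.2)
  }
  stop("could not draw a connected graph")
}

# --- oracles ---------------------------------------------------------------

# all-pairs shortest paths by Floyd-Warshall
bf_distances <- function(net) {
  a <- adjacency_matrix(net)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  dimnames(d) <- dimnames(a)
  d
}

# spanning trees by exhaustive enumeration of (n-1)-edge subsets
bf_spanning_trees <- function(net) {
  n <- net$n
  ep <- edge_pairs(net)
  m <- nrow(ep)
  if (n == 1) return(1L)
  if (m < n - 1) return(0L)
  count <- 0L
  idx <- utils::combn(m, n - 1)
  for (c in seq_len(ncol(idx))) {
    sub <- ep[idx[, c], , drop = FALSE]
    g <- igraph::graph_from_edgelist(sub, directed = FALSE)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) count <- count + 1L
  }
  count
}

# betweenness: unordered pairs once, endpoints excluded (path-count BFS)
bf_betweenness <- function(net) {
  g <- net$graph
  n <- net$n
  btw <- stats::setNames(numeric(n), net$labels)
  d <- igraph::distances(g)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- igraph::all_shortest_paths(g, from = s, to = t)$vpaths
      inner <- unlist(lapply(paths, function(p) names(p)[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner) / length(paths)
        btw[names(tab)] <- btw[names(tab)] + tab
      }
    }
  }
  btw
}

bf_efficiency <- function(net) {
  d <- bf_distances(net)
  inv <- 1 / d
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

expect_same_edges <- function(a, b) {
  expect_identical(a$labels, b$labels)
  expect_identical(edge_pairs(a), edge_pairs(b))
}
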
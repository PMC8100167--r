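#' Graph index complexity (Cr)
#'
#' Rescales the largest adjacency eigenvalue between its extremes over
#' connected graphs — `2*cos(pi/(n+1))` for the path and `n - 1` for the
#' complete graph — and folds the rescaled value `c_r` through
#' `Cr = 4 * c_r * (1 - c_r)`, so both the path and the complete graph score
#' 0 and medium-density graphs score high.
#'
#' @param net a connected [morph_network()] with `n >= 3`.
#' @return `Cr` in `[0, 1]`.
#' @export
graph_index_complexity <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "graph_index_complexity")
  n <- net$n
  if (n < 3L) stop("graph index complexity needs n >= 3")
  lam <- max(eigen(adjacency_matrix(net), symmetric = TRUE,
                   only.values = TRUE)$values)
  lo <- 2 * cos(pi / (n + 1))
  cr <- (lam - lo) / (n - 1 - lo)
  cr <- min(max(cr, 0), 1)
  4 * cr * (1 - cr)
}

#' Medium articulation (MAg)
#'
#' Product measure built on the edge-endpoint degree distribution: drawing a
#' directed edge uniformly (probability `1/2m` each), endpoint marginals are
#' `k_i/2m`.  Mutual information `I = (1/m) * sum_edges log(2m/(k_i k_j))`
#' measures transmission, redundancy `R = (1/m) * sum_edges log(k_i k_j)`
#' measures wiring cost, and `I + R = log(2m)` identically.  The raw product
#' `I * R` is highest for medium-density, degree-heterogeneous graphs; it is
#' normalised against the joint-entropy budget of the complete graph on the
#' same nodes, `MAg = 4 * I * R / log(n(n-1))^2`, which keeps the value in
#' `[0, 1]` and places both sparse trees and the complete graph below
#' medium-density graphs of the same size (see the methods vignette for why
#' the naive balance normalisation `4*I*R/(I+R)^2` fails this ordering).
#' The logarithm base cancels.
#'
#' @param net a connected [morph_network()] with `m >= 1`.
#' @return `MAg` in `[0, 1]`.
#' @export
medium_articulation <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "medium_articulation")
  m <- net$m
  if (m < 1L) stop("medium articulation needs at least one edge")
  k <- degrees(net)[net$labels]
  ep <- edge_pairs(net)
  lkk <- log(k[ep[, 1]] * k[ep[, 2]])
  R <- sum(lkk) / m
  I <- log(2 * m) - R
  if (net$n < 2L) return(0)
  min(1, max(0, 4 * I * R / log(net$n * (net$n - 1))^2))
}

#' Efficiency complexity (Ce)
#'
#' Rescales global efficiency between the path graph (the least efficient
#' connected topology) and the complete graph:
#' `c_e = (E(g) - E(P_n)) / (1 - E(P_n))`, then `Ce = 4 * c_e * (1 - c_e)`.
#'
#' @param net a connected [morph_network()] with `n >= 3`.
#' @return `Ce` in `[0, 1]`.
#' @export
efficiency_complexity <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "efficiency_complexity")
  n <- net$n
  if (n < 3L) stop("efficiency complexity needs n >= 3")
  e <- global_efficiency(net)
  ep <- path_graph_efficiency(n)
  ce <- (e - ep) / (1 - ep)
  ce <- min(max(ce, 0), 1)
  4 * ce * (1 - ce)
}

# closed form: sum over distances d = 1..n-1, (n-d) ordered pairs each way
path_graph_efficiency <- function(n) {
  d <- seq_len(n - 1)
  2 * sum((n - d) / d) / (n * (n - 1))
}

#' Offdiagonal complexity (OdC)
#'
#' Builds the node-degree / neighbour-degree edge count matrix `c_kl`
#' (`k <= l`), sums it along offdiagonals `d = l - k`, normalises the
#' offdiagonal sums to a distribution and returns its entropy divided by
#' `log(D)` where `D = k_max - k_min + 1` is the number of possible
#' offdiagonals.  Regular graphs (all edges on the main diagonal) and graphs
#' with a single populated degree pair score 0.
#'
#' @param net a connected [morph_network()].
#' @return `OdC` in `[0, 1]`.
#' @export
offdiagonal_complexity <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "offdiagonal_complexity")
  k <- degrees(net)[net$labels]
  ep <- edge_pairs(net)
  if (!nrow(ep)) return(0)
  dpair <- abs(k[ep[, 1]] - k[ep[, 2]])   # offdiagonal index per edge
  D <- max(k) - min(k) + 1
  a <- tapply(rep(1, length(dpair)), dpair, sum)
  if (length(a) < 2L || D < 2L) return(0)
  p <- a / sum(a)
  min(1, max(0, -sum(p * log(p)) / log(D)))
}

#' Number of spanning trees (matrix-tree theorem)
#'
#' Determinant of an `(n-1) x (n-1)` principal minor of the graph Laplacian.
#' Counts are exact integers for `n <= 50`; above that the computation moves
#' to the log domain (`log = TRUE` always returns the natural logarithm).
#'
#' @param net a [morph_network()]; a disconnected graph has 0 spanning trees.
#' @param log return the natural log of the count instead of the count.
#' @return spanning-tree count (or its log; `-Inf` when disconnected).
#' @export
spanning_tree_count <- function(net, log = FALSE) {
  stopifnot(inherits(net, "morph_network"))
  if (net$n == 1L) return(if (log) 0 else 1)
  if (!igraph::is_connected(net$graph)) return(if (log) -Inf else 0)
  lst <- log_spanning_trees(adjacency_matrix(net))
  if (log) lst else if (net$n <= 50L) round(exp(lst)) else exp(lst)
}

log_spanning_trees <- function(a) {
  n <- nrow(a)
  if (n == 1L) return(0)
  lap <- diag(rowSums(a)) - a
  minor <- lap[-1, -1, drop = FALSE]
  d <- determinant(minor, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)          # numerically singular: no trees
  as.numeric(d$modulus)
}

# ST(g - e) for every edge, as natural logs (-Inf when e is a bridge)
edge_deleted_log_st <- function(net) {
  a <- adjacency_matrix(net)
  ep <- edge_pairs(net)
  vapply(seq_len(nrow(ep)), function(r) {
    b <- a
    b[ep[r, 1], ep[r, 2]] <- 0
    b[ep[r, 2], ep[r, 1]] <- 0
    if (!connected_from_adjacency(b)) return(-Inf)
    log_spanning_trees(b)
  }, 0)
}

connected_from_adjacency <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(a[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Spanning tree sensitivity (STS, STSD)
#'
#' Let `s_e = ST(g - e)` be the spanning-tree count after deleting edge `e`
#' (0 when `e` is a bridge) and `ST(g)` the count for the intact graph.  Since
#' every spanning tree of `g - e` is one of `g`, `s_e/ST(g)` lies in `[0, 1]`.
#' The package defines
#' `STS  = 1 - mean_e(s_e / ST(g))` (mean relative loss of spanning trees) and
#' `STSD = (max_e s_e - min_e s_e) / ST(g)` (normalised spread).  Both lie in
#' `[0, 1]`; edge-transitive graphs, where all `s_e` coincide, have
#' `STSD = 0`.  The exact published normalisation of these two statistics is
#' not stated; these are the package's documented variants (see the methods
#' vignette).
#'
#' @param net a connected [morph_network()].
#' @return named list with `STS` and `STSD`.
#' @export
spanning_tree_sensitivity <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "spanning_tree_sensitivity")
  if (net$m < 1L) return(list(STS = 0, STSD = 0))
  lst <- log_spanning_trees(adjacency_matrix(net))
  ratios <- exp(edge_deleted_log_st(net) - lst)   # s_e / ST(g), bridges -> 0
  ratios <- pmin(pmax(ratios, 0), 1)
  list(STS = 1 - mean(ratios), STSD = max(ratios) - min(ratios))
}

#' One-edge-deleted subgraph complexity (C1e_ST, C1e_spec)
#'
#' Counts how many *different* one-edge-deleted subgraphs a graph has, either
#' by their spanning-tree counts (`C1e_ST`) or by their Laplacian spectra
#' (`C1e_spec`, eigenvalues rounded to 1e-8 before multiset comparison), in
#' both cases divided by the number of edges.  A graph whose one-edge-deleted
#' subgraphs are all isomorphic (e.g. a cycle) scores `1/m`.
#'
#' @param net a connected [morph_network()] with `m >= 1`.
#' @return named list with `C1e_ST` and `C1e_spec`, each in `(0, 1]`.
#' @export
one_edge_deleted_complexity <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "one_edge_deleted_complexity")
  m <- net$m
  if (m < 1L) stop("one-edge-deleted complexity needs at least one edge")
  lst_e <- edge_deleted_log_st(net)
  n_st <- length(unique(round(lst_e, 9)))
  a <- adjacency_matrix(net)
  ep <- edge_pairs(net)
  sigs <- vapply(seq_len(m), function(r) {
    b <- a
    b[ep[r, 1], ep[r, 2]] <- 0
    b[ep[r, 2], ep[r, 1]] <- 0
    lap <- diag(rowSums(b)) - b
    ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
    paste(round(ev, 8), collapse = ",")
  }, "")
  list(C1e_ST = n_st / m, C1e_spec = length(unique(sigs)) / m)
}

#' Full normalised complexity panel
#'
#' Runs the whole battery — MAg, Ce, Cr, OdC, STS, STSD, C1e_ST, C1e_spec —
#' on one network.  All values lie in `[0, 1]`.
#'
#' @param net a connected [morph_network()] with `n >= 3`.
#' @return named numeric vector of the eight measures.
#' @export
complexity_panel <- function(net) {
  sts <- spanning_tree_sensitivity(net)
  c1e <- one_edge_deleted_complexity(net)
  c(MAg = medium_articulation(net),
    Ce = efficiency_complexity(net),
    Cr = graph_index_complexity(net),
    OdC = offdiagonal_complexity(net),
    STS = sts$STS,
    STSD = sts$STSD,
    C1e_ST = c1e$C1e_ST,
    C1e_spec = c1e$C1e_spec)
}
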
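#' Anatomical morphology networks
#'
#' A `morph_network` is a labelled, simple, undirected, binary graph whose
#' nodes are externally identifiable morphological units (segments, articles,
#' endites, exites, epipods, flagella, ...) and whose edges are physical
#' connections between them.  Internally the object wraps an
#' \pkg{igraph} graph; node labels are the node identity and the matrix /
#' input order is preserved so that downstream tie-breaks are reproducible.
#'
#' @param adjacency square numeric 0/1 matrix, symmetric with zero diagonal.
#' @param labels character vector of unique node names; when `NULL`, labels
#'   `"n001"`, `"n002"`, ... are synthesized.
#' @param require_connected if `TRUE` (default) a disconnected graph is an
#'   error; set `FALSE` to allow multiple components (some analyses then
#'   refuse to run).
#' @return an object of class `morph_network` with elements `graph`
#'   (the igraph), `labels`, `n` (nodes) and `m` (edges).
#' @export
morph_network <- function(adjacency, labels = NULL, require_connected = TRUE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("format error: adjacency matrix must be square, got ",
         nrow(adjacency), "x", ncol(adjacency))
  }
  n <- nrow(adjacency)
  if (n < 1L) stop("adjacency matrix must have at least one node")
  storage.mode(adjacency) <- "double"
  bad <- which(!(adjacency %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% n) + 1
    j <- ((bad[1] - 1) %/% n) + 1
    stop(sprintf(
      "validation error: entry [%d,%d] = %s is not binary (0/1)",
      i, j, format(adjacency[bad[1]])))
  }
  asym <- which(adjacency != t(adjacency), arr.ind = TRUE)
  if (nrow(asym)) {
    stop(sprintf(
      "validation error: matrix not symmetric at [%d,%d] vs [%d,%d]",
      asym[1, 1], asym[1, 2], asym[1, 2], asym[1, 1]))
  }
  dg <- which(diag(adjacency) != 0)
  if (length(dg)) {
    stop(sprintf("validation error: nonzero diagonal at [%d,%d] (self-loop)",
                 dg[1], dg[1]))
  }
  if (is.null(labels)) {
    labels <- dimnames(adjacency)[[1]]
    if (is.null(labels)) labels <- sprintf("n%03d", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must equal number of nodes")
  if (anyDuplicated(labels)) {
    stop("validation error: duplicated node label '",
         labels[duplicated(labels)][1], "'")
  }
  dimnames(adjacency) <- list(labels, labels)
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  net <- structure(
    list(graph = g, labels = labels,
         n = n, m = as.integer(sum(adjacency) / 2)),
    class = "morph_network")
  if (require_connected && !igraph::is_connected(g)) {
    comp <- igraph::components(g)
    stop("connectivity error: graph has ", comp$no,
         " components of sizes ", paste(comp$csize, collapse = ", "))
  }
  net
}

#' Build a morph_network from an igraph graph
#'
#' @param g an undirected simple igraph graph; vertex `name` attributes become
#'   the labels.
#' @inheritParams morph_network
#' @export
as_morph_network <- function(g, require_connected = TRUE) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("graph must be undirected")
  if (!igraph::is_simple(g)) stop("graph must be simple (no loops/multi-edges)")
  labels <- igraph::vertex_attr(g, "name")
  if (is.null(labels)) {
    labels <- sprintf("n%03d", seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- labels
  }
  net <- structure(
    list(graph = g, labels = labels,
         n = igraph::vcount(g), m = igraph::ecount(g)),
    class = "morph_network")
  if (require_connected && !igraph::is_connected(g)) {
    comp <- igraph::components(g)
    stop("connectivity error: graph has ", comp$no,
         " components of sizes ", paste(comp$csize, collapse = ", "))
  }
  net
}

#' @export
print.morph_network <- function(x, ...) {
  cat(sprintf("<morph_network> %d nodes, %d edges%s\n", x$n, x$m,
              if (igraph::is_connected(x$graph)) "" else " (disconnected)"))
  show <- utils::head(x$labels, 6)
  cat("  labels: ", paste(show, collapse = ", "),
      if (x$n > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Adjacency matrix of a morph_network
#' @param net a `morph_network`.
#' @return dense numeric 0/1 matrix with label dimnames, input node order.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  a <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  a[net$labels, net$labels, drop = FALSE]
}

#' Edge list of a morph_network as unordered label pairs
#' @param net a `morph_network`.
#' @return two-column character matrix, one row per edge.
#' @export
edge_pairs <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  e <- igraph::as_edgelist(net$graph)
  if (!nrow(e)) return(matrix(character(), 0L, 2L))
  t(apply(e, 1L, sort))
}

degrees <- function(net) igraph::degree(net$graph)

stop_if_disconnected <- function(net, what) {
  if (!igraph::is_connected(net$graph)) {
    stop(what, " requires a connected network")
  }
}
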
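#' Topological overlap matrix
#'
#' Normalised shared-neighbourhood similarity: for distinct nodes i, j,
#' `O_T(i,j) = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where `l_ij` is the
#' number of common neighbours and `a_ij` the adjacency indicator; the
#' diagonal is 1.  Two non-adjacent nodes with identical neighbourhoods score
#' 1, two nodes sharing no neighbours (and no edge) score 0.
#'
#' @param net a connected [morph_network()] with `n >= 2`.
#' @return symmetric numeric matrix in `[0, 1]` with label dimnames.
#' @export
topological_overlap_matrix <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  if (net$n < 2L) stop("topological overlap needs at least 2 nodes")
  a <- adjacency_matrix(net)
  k <- rowSums(a)
  l <- a %*% a                         # common-neighbour counts
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Hierarchy tree from a topological overlap matrix
#'
#' Agglomerative clustering of the dissimilarity `1 - O_T`.  The number of
#' hierarchical "levels" is counted as the number of distinct merge heights
#' after rounding to 1e-9 (the published counting rule is not stated; this is
#' the package's documented choice).
#'
#' @param tom a TOM from [topological_overlap_matrix()].
#' @param linkage `"average"` (default, the WGCNA convention), `"complete"`
#'   or `"single"`.
#' @return a `hierarchy_tree`: list with `hclust` (the merge tree),
#'   `level_count`, and `linkage`.
#' @export
hierarchy_tree <- function(tom, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  if (nrow(tom) < 2L) stop("hierarchy tree needs at least 2 nodes")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = linkage)
  structure(
    list(hclust = hc,
         level_count = length(unique(round(hc$height, 9))),
         linkage = linkage),
    class = "hierarchy_tree")
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  cat(sprintf("<hierarchy_tree> %d leaves, %d levels (%s linkage)\n",
              length(x$hclust$order), x$level_count, x$linkage))
  invisible(x)
}

#' Newick representation of a hierarchy tree
#'
#' @param tree a `hierarchy_tree`.
#' @return a Newick string (requires the \pkg{ape} package).
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "hierarchy_tree"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(tree$hclust))
}
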
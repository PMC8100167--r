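#' Global efficiency
#'
#' `E = (1/(n(n-1))) * sum_{i != j} 1/d_ij`, with `1/Inf = 0` for pairs in
#' different components.  `E = 1` exactly for complete graphs and 0 for an
#' edgeless graph.
#'
#' @param net a [morph_network()] with `n >= 2` (need not be connected).
#' @return efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  if (net$n < 2L) stop("global efficiency needs n >= 2")
  d <- igraph::distances(net$graph)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (net$n * (net$n - 1))
}

#' Node vulnerability
#'
#' Relative drop in global efficiency caused by removing one node:
#' `V = (E(g) - E(g - v)) / E(g)`, where `E(g - v)` is computed over the
#' residual graph on its remaining `n - 1` nodes (not padded back to `n`).
#' Can be negative when a removal raises efficiency.
#'
#' @param net a [morph_network()] with `n >= 3`.
#' @param node node label (or index).
#' @return the vulnerability of `node`.
#' @export
node_vulnerability <- function(net, node) {
  stopifnot(inherits(net, "morph_network"))
  if (net$n < 3L) stop("node vulnerability needs n >= 3")
  if (is.numeric(node)) node <- net$labels[node]
  if (!node %in% net$labels) stop("node absent from network: ", node)
  e0 <- global_efficiency(net)
  g1 <- igraph::delete_vertices(net$graph, node)
  e1 <- as_morph_network(g1, require_connected = FALSE)
  (e0 - global_efficiency(e1)) / e0
}

#' Vulnerability of every node
#'
#' @param net a [morph_network()] with `n >= 3`.
#' @return `data.frame` with `label` and `vulnerability`, input node order.
#' @export
vulnerability_table <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  data.frame(
    label = net$labels,
    vulnerability = vapply(net$labels, node_vulnerability, 0, net = net),
    row.names = NULL)
}

#' Rich core
#'
#' Nodes are ranked by degree (descending, stable input-order tie-break).
#' For the node of rank `r`, `k_r_plus` counts its links to higher-ranked
#' nodes; the core boundary `r*` is the rank at which `k_r_plus` attains its
#' (first) maximum, and the core is the set of ranks `1..r*`.
#'
#' @param net a connected [morph_network()].
#' @return a `rich_core` list: `ranked` (labels in rank order), `k_plus`
#'   (per-rank links to higher ranks), `boundary` (`r*`), `core` (labels),
#'   `proportion` (`r*/n`).
#' @export
rich_core <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "rich_core")
  k <- degrees(net)[net$labels]
  ord <- order(-k)                        # stable: ties keep input order
  ranked <- net$labels[ord]
  rank_of <- stats::setNames(seq_along(ranked), ranked)
  ep <- edge_pairs(net)
  k_plus <- integer(net$n)
  for (r in seq_len(nrow(ep))) {
    ri <- rank_of[ep[r, 1]]
    rj <- rank_of[ep[r, 2]]
    k_plus[max(ri, rj)] <- k_plus[max(ri, rj)] + 1L
  }
  boundary <- which.max(k_plus)
  structure(
    list(ranked = ranked, k_plus = k_plus, boundary = boundary,
         core = ranked[seq_len(boundary)], proportion = boundary / net$n),
    class = "rich_core")
}

#' @export
print.rich_core <- function(x, ...) {
  cat(sprintf("<rich_core> %d of %d nodes (proportion %.2f)\n",
              x$boundary, length(x$ranked), x$proportion))
  invisible(x)
}

#' Error and attack tolerance curve
#'
#' Removes nodes one at a time and records, after each removal, the
#' connectivity loss `1 - (connected ordered pairs among survivors) /
#' (n0 * (n0 - 1))`, relative to the original node count `n0`.  Strategies:
#' `"degree"` and `"betweenness"` remove in decreasing order of the initial
#' ranking; `"cascading"` recomputes betweenness after every removal;
#' `"random"` averages `n_reps` uniformly random removal orders.
#' Ties are broken by stable input order; betweenness is undirected,
#' unnormalised, each unordered pair counted once, endpoints excluded.
#'
#' @param net a connected [morph_network()].
#' @param strategy one of `"degree"`, `"betweenness"`, `"cascading"`,
#'   `"random"`.
#' @param seed seed for the random strategy.
#' @param n_reps replicates for the random strategy (default 50).
#' @return a `connectivity_loss_curve` data.frame with columns
#'   `fraction_removed` and `loss` (plus attribute `strategy`).
#' @export
attack_curve <- function(net, strategy = c("degree", "betweenness",
                                           "cascading", "random"),
                         seed = 1L, n_reps = 50L) {
  stopifnot(inherits(net, "morph_network"))
  strategy <- match.arg(strategy)
  stop_if_disconnected(net, "attack_curve")
  n0 <- net$n
  loss <- switch(strategy,
    degree = removal_losses(net, order(-degrees(net)[net$labels])),
    betweenness = removal_losses(
      net, order(-igraph::betweenness(net$graph)[net$labels])),
    cascading = cascading_losses(net),
    random = {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      reps <- replicate(n_reps, removal_losses(net, sample.int(n0)))
      rowMeans(reps)
    })
  structure(
    data.frame(fraction_removed = seq_len(n0) / n0, loss = loss),
    strategy = strategy, class = c("connectivity_loss_curve", "data.frame"))
}

# loss series for a fixed removal order (vector of vertex indices)
removal_losses <- function(net, ord) {
  n0 <- net$n
  g <- net$graph
  vapply(seq_len(n0), function(i) {
    surv <- net$labels[-ord[seq_len(i)]]
    if (!length(surv)) return(1)
    comp <- igraph::components(igraph::induced_subgraph(g, surv))
    1 - sum(comp$csize * (comp$csize - 1)) / (n0 * (n0 - 1))
  }, 0)
}

cascading_losses <- function(net) {
  n0 <- net$n
  g <- net$graph
  loss <- numeric(n0)
  for (i in seq_len(n0)) {
    nv <- igraph::vcount(g)
    if (nv > 1L) {
      b <- igraph::betweenness(g)
      drop <- which.max(b)                # stable: which.max takes first
    } else {
      drop <- 1L
    }
    g <- igraph::delete_vertices(g, drop)
    comp <- igraph::components(g)
    loss[i] <- 1 - sum(comp$csize * (comp$csize - 1)) / (n0 * (n0 - 1))
  }
  loss
}
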
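#' Newman-Girvan modularity of a node partition
#'
#' Direct evaluation of
#' `Q = (1/2m) * sum_ij (a_ij - k_i k_j / 2m) * delta(c_i, c_j)`,
#' implemented from the degree sequence and edge list (independently of any
#' library modularity routine, so the two can cross-check each other).
#'
#' @param net a [morph_network()].
#' @param assignment named integer vector (names = node labels) or unnamed
#'   vector in node order, giving each node's module id.
#' @return the modularity Q, a number in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, assignment) {
  stopifnot(inherits(net, "morph_network"))
  memb <- align_assignment(net, assignment)
  m <- net$m
  if (m == 0) return(0)
  k <- degrees(net)[net$labels]
  ep <- edge_pairs(net)
  within <- sum(memb[ep[, 1]] == memb[ep[, 2]])
  # expected within-module edge fraction from degrees
  expected <- sum(vapply(split(k, memb), sum, 0)^2) / (2 * m)^2
  within / m - expected
}

align_assignment <- function(net, assignment) {
  if (is.null(names(assignment))) {
    if (length(assignment) != net$n) {
      stop("assignment must cover all ", net$n, " nodes")
    }
    names(assignment) <- net$labels
  }
  unknown <- setdiff(names(assignment), net$labels)
  if (length(unknown)) stop("unknown node in assignment: ", unknown[1])
  missing <- setdiff(net$labels, names(assignment))
  if (length(missing)) stop("assignment missing node: ", missing[1])
  assignment[net$labels]
}

#' Module detection by multi-level (Louvain) modularity optimisation
#'
#' The multi-level algorithm is order-sensitive, so the graph is presented in
#' `restarts` random vertex orders (seeded) and the partition with the highest
#' Q is kept.  Q is recomputed with [modularity_q()] on the original network.
#'
#' @param net a connected [morph_network()] with at least 2 nodes.
#' @param seed integer seed controlling the restart permutations.
#' @param restarts number of randomised runs (default 100).
#' @return a `module_partition`: list with `assignment` (named integer vector,
#'   module ids contiguous from 1 in order of first appearance), `q_value`,
#'   and `n_modules`.
#' @export
detect_modules <- function(net, seed = 1L, restarts = 100L) {
  stopifnot(inherits(net, "morph_network"))
  if (net$n < 2L) stop("degenerate input: module detection needs >= 2 nodes")
  stop_if_disconnected(net, "detect_modules")
  best_q <- -Inf
  best <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    perm <- sample.int(net$n)
    gp <- igraph::permute(net$graph, perm)
    cl <- igraph::cluster_louvain(gp)
    memb <- igraph::membership(cl)[net$labels]
    q <- modularity_q(net, memb)
    if (q > best_q + 1e-15) {
      best_q <- q
      best <- memb
    }
  }
  new_module_partition(net, best)
}

new_module_partition <- function(net, memb) {
  memb <- align_assignment(net, memb)
  ids <- unique(memb)                       # order of first appearance
  assignment <- match(memb, ids)
  names(assignment) <- net$labels
  structure(
    list(assignment = assignment,
         q_value = modularity_q(net, assignment),
         n_modules = length(ids)),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, Q = %.4f\n",
              x$n_modules, x$q_value))
  invisible(x)
}

#' Exhaustive maximum-modularity partition (oracle, tiny graphs only)
#'
#' Enumerates every partition of the node set (Bell-number growth) and returns
#' the one maximising Q.  Usable up to about 10 nodes; intended as an
#' independent check on [detect_modules()].
#'
#' @inheritParams detect_modules
#' @export
max_modularity_exhaustive <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  n <- net$n
  if (n > 10L) stop("exhaustive search limited to n <= 10")
  best_q <- -Inf
  best <- NULL
  m <- net$m
  k <- degrees(net)[net$labels]
  ep <- edge_pairs(net)
  ei <- match(ep[, 1], net$labels)
  ej <- match(ep[, 2], net$labels)
  # enumerate set partitions via restricted growth strings
  rgs <- integer(n)
  recurse <- function(i, maxid) {
    if (i > n) {
      within <- sum(rgs[ei] == rgs[ej])
      expected <- sum(vapply(split(k, rgs), sum, 0)^2) / (2 * m)^2
      q <- within / m - expected
      if (q > best_q) {
        best_q <<- q
        best <<- rgs + 1L
      }
      return(invisible())
    }
    for (v in 0:(maxid + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxid, v))
    }
  }
  recurse(1L, -1L)
  new_module_partition(net, stats::setNames(best, net$labels))
}

#' Node roles in ZP space
#'
#' For each node computes the within-module degree z-score
#' `z_i = (kappa_i - mean(kappa | module)) / sd_pop(kappa | module)`
#' (population standard deviation; `z = 0` when the module is degree-uniform)
#' and the participation coefficient
#' `P_i = 1 - sum_s (kappa_is / k_i)^2`, then classifies each node into one of
#' seven regions: non-connectors have `P < 0.4`, connectors `P >= 0.4`,
#' hyper-connectors `P >= 0.75`; non-hubs have `z < 1`, hubs `z >= 1`,
#' super-hubs `z >= 2.75`.
#'
#' @param net a [morph_network()].
#' @param partition a `module_partition` (or named assignment vector).
#' @return a `data.frame` with columns `label`, `module`, `degree`, `z`, `P`,
#'   `region` (factor with the seven region levels).
#' @export
zp_roles <- function(net, partition) {
  stopifnot(inherits(net, "morph_network"))
  memb <- if (inherits(partition, "module_partition")) {
    partition$assignment
  } else {
    align_assignment(net, partition)
  }
  k <- degrees(net)[net$labels]
  ep <- edge_pairs(net)
  # kappa[i, s]: links of node i into module s
  mods <- sort(unique(memb))
  kappa <- matrix(0L, nrow = net$n, ncol = length(mods),
                  dimnames = list(net$labels, as.character(mods)))
  for (r in seq_len(nrow(ep))) {
    u <- ep[r, 1]; v <- ep[r, 2]
    kappa[u, as.character(memb[v])] <- kappa[u, as.character(memb[v])] + 1L
    kappa[v, as.character(memb[u])] <- kappa[v, as.character(memb[u])] + 1L
  }
  kin <- kappa[cbind(seq_len(net$n), match(memb, mods))]
  z <- numeric(net$n)
  for (s in mods) {
    idx <- which(memb == s)
    mu <- mean(kin[idx])
    sdp <- sqrt(mean((kin[idx] - mu)^2))   # population sd
    z[idx] <- if (sdp > 0) (kin[idx] - mu) / sdp else 0
  }
  P <- ifelse(k > 0, 1 - rowSums((kappa / pmax(k, 1))^2), 0)
  data.frame(
    label = net$labels,
    module = as.integer(memb),
    degree = as.integer(k),
    z = z,
    P = as.numeric(P),
    region = factor(zp_region(z, P), levels = zp_region_levels()),
    row.names = NULL)
}

zp_region_levels <- function() {
  c("peripheral", "local hub", "local super-hub",
    "non-hub connector", "non-hub hyper-connector",
    "connector hub", "connector super-hub")
}

zp_region <- function(z, P) {
  ifelse(z >= 2.75,
         ifelse(P >= 0.4, "connector super-hub", "local super-hub"),
  ifelse(z >= 1,
         ifelse(P >= 0.4, "connector hub", "local hub"),
  # non-hubs
  ifelse(P >= 0.75, "non-hub hyper-connector",
  ifelse(P >= 0.4, "non-hub connector", "peripheral"))))
}

#' Census of ZP regions
#'
#' @param roles a role table from [zp_roles()].
#' @return `data.frame` with `region`, `count`, `percent`; percentages sum
#'   to 100 up to rounding.
#' @export
region_census <- function(roles) {
  stopifnot(is.data.frame(roles), nrow(roles) > 0)
  counts <- table(factor(roles$region, levels = zp_region_levels()))
  data.frame(
    region = names(counts),
    count = as.integer(counts),
    percent = 100 * as.integer(counts) / nrow(roles),
    row.names = NULL)
}
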
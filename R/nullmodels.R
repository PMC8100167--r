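#' Connected random graph with a prescribed degree sequence
#'
#' Three-stage generator: (1) a simple realization of the degree sequence by
#' the Havel-Hakimi construction (error when the sequence fails the
#' Erdos-Gallai condition); (2) connectivity repair by degree-preserving
#' double-edge swaps across components (each swap merges components and can
#' never create loops or multi-edges); (3) randomisation by a Monte-Carlo
#' chain of connectivity-preserving double-edge swaps, run until
#' `swaps_per_edge * m` proposals have been accepted.
#'
#' @param degree_sequence integer vector; must be graphical and admit a
#'   connected realization (all degrees >= 1, `sum(k) >= 2(n-1)`, even sum).
#' @param seed integer seed for the swap chain.
#' @param swaps_per_edge accepted swaps per edge (default 10).
#' @return a connected [morph_network()] with exactly the given degrees.
#' @export
generate_null <- function(degree_sequence, seed = 1L, swaps_per_edge = 10) {
  k <- as.integer(degree_sequence)
  n <- length(k)
  if (n < 1L) stop("empty degree sequence")
  if (sum(k) %% 2L != 0L) stop("non-graphical sequence: odd degree sum")
  if (!is_graphical_sequence(k)) {
    stop("non-graphical sequence (fails Erdos-Gallai)")
  }
  if (n > 1L && (any(k < 1L) || sum(k) < 2L * (n - 1L))) {
    stop("sequence admits no connected realization")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  a <- havel_hakimi(k)
  a <- repair_connectivity(a)
  a <- randomize_connected(a, ceiling(swaps_per_edge * sum(a) / 2))
  morph_network(a, labels = sprintf("n%03d", seq_len(n)))
}

is_graphical_sequence <- function(k) {
  k <- sort(as.integer(k), decreasing = TRUE)
  n <- length(k)
  if (any(k < 0L) || any(k > n - 1L) && n > 1L) return(FALSE)
  if (n == 1L) return(k[1] == 0L)
  csum <- cumsum(k)
  for (r in seq_len(n - 1L)) {
    rhs <- r * (r - 1L) + sum(pmin(k[(r + 1L):n], r))
    if (csum[r] > rhs) return(FALSE)
  }
  TRUE
}

havel_hakimi <- function(k) {
  n <- length(k)
  a <- matrix(0L, n, n)
  resid <- k
  repeat {
    v <- order(-resid)[1]
    if (resid[v] == 0L) break
    targets <- setdiff(order(-resid, seq_len(n)), v)
    targets <- targets[a[v, targets] == 0L & resid[targets] > 0L]
    if (length(targets) < resid[v]) stop("non-graphical sequence")
    take <- targets[seq_len(resid[v])]
    a[v, take] <- a[take, v] <- 1L
    resid[take] <- resid[take] - 1L
    resid[v] <- 0L
  }
  a
}

repair_connectivity <- function(a) {
  repeat {
    comp <- adjacency_components(a)
    if (max(comp) == 1L) return(a)
    # swap a cycle (non-bridge) edge against an edge of another component:
    # removing it cannot split its component, so the component count
    # strictly decreases every pass.  Some component always holds a cycle
    # while the graph is disconnected (else m = n - #comps < n - 1,
    # impossible when sum(k) >= 2(n-1)).
    e1 <- NULL
    for (ci in seq_len(max(comp))) {
      nodes <- which(comp == ci)
      if (sum(a[nodes, nodes]) / 2 >= length(nodes)) {   # has a cycle
        e1 <- first_nonbridge_in(a, nodes)
        if (!is.null(e1)) { c1 <- ci; break }
      }
    }
    if (is.null(e1)) {
      stop("sequence admits no connected realization (no cycle edge)")
    }
    e2 <- first_edge_in(a, which(comp != c1))
    if (is.null(e2)) {
      stop("sequence admits no connected realization (edgeless component)")
    }
    a[e1[1], e1[2]] <- a[e1[2], e1[1]] <- 0L
    a[e2[1], e2[2]] <- a[e2[2], e2[1]] <- 0L
    a[e1[1], e2[1]] <- a[e2[1], e1[1]] <- 1L
    a[e1[2], e2[2]] <- a[e2[2], e1[2]] <- 1L
  }
}

first_nonbridge_in <- function(a, nodes) {
  for (v in nodes) {
    for (w in which(a[v, ] > 0L)) {
      if (w <= v) next
      a[v, w] <- a[w, v] <- 0L
      ok <- reachable(a, v, w)
      a[v, w] <- a[w, v] <- 1L
      if (ok) return(c(v, w))
    }
  }
  NULL
}

adjacency_components <- function(a) {
  n <- nrow(a)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(a[v, ] > 0L & comp == 0L)
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}

first_edge_in <- function(a, nodes) {
  for (v in nodes) {
    w <- which(a[v, ] > 0L)
    if (length(w)) return(c(v, w[1]))
  }
  NULL
}

randomize_connected <- function(a, n_accept) {
  n <- nrow(a)
  accepted <- 0L
  guard <- 0L
  max_tries <- max(60L * n_accept, 600L)
  edges <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < 2L) return(a)
  while (accepted < n_accept && guard < max_tries) {
    guard <- guard + 1L
    pick <- sample.int(m, 2L)
    u <- edges[pick[1], 1]; v <- edges[pick[1], 2]
    x <- edges[pick[2], 1]; y <- edges[pick[2], 2]
    if (length(unique(c(u, v, x, y))) < 4L) next
    if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
    # propose (u,v),(x,y) -> (u,x),(v,y)
    if (a[u, x] || a[v, y]) next
    a[u, v] <- a[v, u] <- 0L; a[x, y] <- a[y, x] <- 0L
    a[u, x] <- a[x, u] <- 1L; a[v, y] <- a[y, v] <- 1L
    # every fragment of the cut graph contains one of u,v,x,y, and the new
    # edges chain C(u)~C(x) and C(v)~C(y); u reaching v therefore merges
    # all four fragments, so one targeted reachability check suffices
    if (reachable(a, u, v)) {
      accepted <- accepted + 1L
      edges[pick[1], ] <- sort(c(u, x))
      edges[pick[2], ] <- sort(c(v, y))
    } else {
      a[u, x] <- a[x, u] <- 0L; a[v, y] <- a[y, v] <- 0L
      a[u, v] <- a[v, u] <- 1L; a[x, y] <- a[y, x] <- 1L
    }
  }
  a
}

reachable <- function(a, from, to) {
  if (a[from, to] > 0L) return(TRUE)
  n <- nrow(a)
  seen <- logical(n)
  seen[from] <- TRUE
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(a[v, ] > 0L & !seen)
    if (any(nb == to)) return(TRUE)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  FALSE
}

#' Compare a network against its degree-sequence null ensemble
#'
#' Generates `n_models` connected degree-sequence-preserving random graphs
#' and evaluates a set of measures on the observed network and on each model.
#' The per-measure ratio is observed value / arithmetic ensemble mean.
#' Measures that are functions of `(n, m)` alone (density, normalised edge
#' complexity, ...) have ratio exactly 1.
#'
#' @param net a connected [morph_network()].
#' @param n_models ensemble size (default 100).
#' @param measures character vector of measure names (see
#'   [available_measures()]).
#' @param seed integer seed; model i uses seed `seed + i`.
#' @param swaps_per_edge passed to [generate_null()].
#' @return a `null_ensemble`: list with `observed` (named vector), `values`
#'   (models x measures matrix), `mean`, `ratio`, and `degree_sequence`.
#' @export
ensemble_compare <- function(net, n_models = 100L,
                             measures = c("diameter", "avg_path_length",
                                          "avg_clustering", "density",
                                          "wiener", "harary", "balaban_j",
                                          "bonchev", "normalized_edge_complexity"),
                             seed = 1L, swaps_per_edge = 10) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "ensemble_compare")
  unknown <- setdiff(measures, available_measures())
  if (length(unknown)) stop("measure unavailable: ", unknown[1])
  degseq <- unname(degrees(net)[net$labels])
  observed <- evaluate_measures(net, measures)
  values <- matrix(NA_real_, n_models, length(measures),
                   dimnames = list(NULL, measures))
  for (i in seq_len(n_models)) {
    model <- generate_null(degseq, seed = seed + i,
                           swaps_per_edge = swaps_per_edge)
    stopifnot(identical(sort(unname(degrees(model))), sort(degseq)))
    values[i, ] <- evaluate_measures(model, measures)
  }
  mu <- colMeans(values)
  structure(
    list(observed = observed, values = values, mean = mu,
         ratio = observed / mu, degree_sequence = degseq),
    class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d models, %d measures\n",
              nrow(x$values), ncol(x$values)))
  print(round(rbind(observed = x$observed, mean = x$mean, ratio = x$ratio), 4))
  invisible(x)
}
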
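#' Distance-based descriptors
#'
#' * Wiener index `W = sum_{i<j} d_ij`.
#' * Harary index `H = sum_{i<j} 1/d_ij`.
#' * Balaban J `= m/(mu+1) * sum_edges (DS_u * DS_v)^(-1/2)` with distance
#'   sums `DS_i = sum_j d_ij` and cyclomatic number `mu = m - n + 1`.
#' * Compactness: the normalised mean distance `2W/(n(n-1))` (the Wiener
#'   index per unordered pair); lower = more compact.
#' * Centralization: Freeman degree centralization sum
#'   `sum_i (k_max - k_i)`, unnormalised.
#'
#' @param net a connected [morph_network()] with `n >= 3`.
#' @return named list of the five descriptors.
#' @export
distance_descriptors <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "distance_descriptors")
  n <- net$n
  if (n < 3L) stop("distance descriptors need n >= 3")
  d <- igraph::distances(net$graph)[net$labels, net$labels]
  ds <- rowSums(d)
  w <- sum(d) / 2
  inv <- 1 / d
  diag(inv) <- 0
  mu <- net$m - n + 1
  ep <- edge_pairs(net)
  j <- net$m / (mu + 1) * sum(1 / sqrt(ds[ep[, 1]] * ds[ep[, 2]]))
  dbar <- 2 * w / (n * (n - 1))
  k <- degrees(net)[net$labels]
  list(
    wiener = w,
    harary = sum(inv) / 2,
    balaban_j = j,
    compactness = dbar,
    centralization = sum(max(k) - k))
}

#' Other-invariant descriptors
#'
#' First Zagreb index `M1 = sum k_i^2`; Randic connectivity index
#' `sum_edges (k_u k_v)^(-1/2)`; complexity index B `= sum_i k_i / DS_i`;
#' normalised edge complexity `E_N = 2m / n^2`.
#'
#' @param net a connected [morph_network()].
#' @return named list of the four descriptors.
#' @export
invariant_descriptors <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "invariant_descriptors")
  k <- degrees(net)[net$labels]
  ep <- edge_pairs(net)
  ds <- rowSums(igraph::distances(net$graph)[net$labels, net$labels])
  list(
    zagreb_m1 = sum(k^2),
    randic = sum(1 / sqrt(k[ep[, 1]] * k[ep[, 2]])),
    complexity_index_b = sum(k / ds),
    normalized_edge_complexity = 2 * net$m / net$n^2)
}

#' Entropy-based descriptors
#'
#' All logarithms are base 2.
#' * Topological information content: Shannon entropy of the vertex-orbit
#'   class sizes, `-sum (n_i/n) log2(n_i/n)` (orbits by iterated neighbourhood
#'   colour refinement; exact on trees and validated against automorphism
#'   orbits on small graphs).
#' * Bonchev (distance-magnitude information) index:
#'   `W log2 W - sum_d m_d * d * log2 d` over the distance distribution
#'   (`m_d` = number of unordered pairs at distance `d`).
#' * Bertz complexity: magnitude information of the edge-endpoint degrees,
#'   `2m log2(2m) - sum_i k_i log2 k_i`.
#' * Radial centric information index: entropy of eccentricity classes.
#' * Balaban-like information index (U): `m/(mu+1) * sum_edges
#'   (u_u * u_v)^(-1/2)` where `u_i` is the entropy of node i's distance
#'   distribution `-sum_j (d_ij/DS_i) log2(d_ij/DS_i)`.
#' * Edge equality: entropy of edge equivalence classes, edges being
#'   equivalent when their unordered endpoint-degree pairs coincide.
#'
#' @param net a connected [morph_network()] with `n >= 3`.
#' @return named list of the six descriptors.
#' @export
entropy_descriptors <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  stop_if_disconnected(net, "entropy_descriptors")
  n <- net$n
  if (n < 3L) stop("entropy descriptors need n >= 3")
  d <- igraph::distances(net$graph)[net$labels, net$labels]
  ds <- rowSums(d)
  w <- sum(d) / 2
  k <- degrees(net)[net$labels]
  ep <- edge_pairs(net)
  mu <- net$m - n + 1

  orbit_sizes <- table(vertex_orbits(net))
  ecc_sizes <- table(apply(d, 1, max))

  dvals <- d[upper.tri(d)]
  bonchev <- w * log2(w) - sum(dvals * log2(pmax(dvals, 1)))

  u <- vapply(seq_len(n), function(i) {
    p <- d[i, -i] / ds[i]
    -sum(p * log2(p))
  }, 0)
  balaban_like <- net$m / (mu + 1) *
    sum(1 / sqrt(u[match(ep[, 1], net$labels)] *
                 u[match(ep[, 2], net$labels)]))

  pair_class <- paste(pmin(k[ep[, 1]], k[ep[, 2]]),
                      pmax(k[ep[, 1]], k[ep[, 2]]))
  list(
    topological_info_content = class_entropy(orbit_sizes),
    bonchev = bonchev,
    bertz = 2 * net$m * log2(2 * net$m) - sum(k * log2(pmax(k, 1))),
    radial_centric = class_entropy(ecc_sizes),
    balaban_like_info = balaban_like,
    edge_equality = class_entropy(table(pair_class)))
}

class_entropy <- function(sizes) {
  p <- as.numeric(sizes) / sum(sizes)
  -sum(p * log2(p))
}

#' Vertex orbit classes by colour refinement
#'
#' Iterated neighbourhood colour refinement (1-dimensional
#' Weisfeiler-Leman): nodes start coloured by degree and are repeatedly
#' split by the multiset of neighbour colours until stable.  On trees (and
#' the quasi-trees studied here) the stable colouring equals the
#' automorphism orbits; in general it is a refinement-equivalence that never
#' merges distinct orbits' colour classes incorrectly coarser than WL.
#'
#' @param net a [morph_network()].
#' @return integer vector of class ids, one per node (input order).
#' @export
vertex_orbits <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  a <- adjacency_matrix(net)
  nbrs <- apply(a > 0, 1, which, simplify = FALSE)
  color <- match(rowSums(a), sort(unique(rowSums(a))))
  repeat {
    sig <- vapply(seq_len(net$n), function(i) {
      paste(color[i], paste(sort(color[nbrs[[i]]]), collapse = ","), sep = "|")
    }, "")
    new_color <- match(sig, unique(sig))
    if (length(unique(new_color)) == length(unique(color))) break
    color <- new_color
  }
  color
}

#' Exact automorphism orbits (oracle, tiny graphs only)
#'
#' Brute-force enumeration of all vertex permutations; used to validate
#' [vertex_orbits()] in the test suite.
#'
#' @param net a [morph_network()] with `n <= 8`.
#' @return integer vector of orbit ids per node.
#' @export
automorphism_orbits <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  n <- net$n
  if (n > 8L) stop("brute-force orbits limited to n <= 8")
  a <- adjacency_matrix(net)
  perms <- all_permutations(n)
  same <- diag(TRUE, n)
  for (p in perms) {
    if (identical(a[p, p], unname(a)) || all(a[p, p] == a)) {
      same[cbind(seq_len(n), p)] <- TRUE
    }
  }
  # transitive closure of the "mapped by some automorphism" relation
  repeat {
    nxt <- (same %*% same) > 0
    if (all(nxt == same)) break
    same <- nxt
  }
  match(apply(same, 1, paste, collapse = ""),
        unique(apply(same, 1, paste, collapse = "")))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' Eigenvalue-based descriptors
#'
#' Estrada index `EE = sum exp(lambda_i)` (adjacency spectrum), Laplacian
#' Estrada index `LEE = sum exp(mu_i)`, graph energy `sum |lambda_i|`, and
#' Laplacian energy `sum |mu_i - 2m/n|`.
#'
#' @param net a connected [morph_network()].
#' @return named list of the four descriptors.
#' @export
spectral_descriptors <- function(net) {
  stopifnot(inherits(net, "morph_network"))
  a <- adjacency_matrix(net)
  lam <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  lap <- diag(rowSums(a), nrow = nrow(a)) - a
  mu <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  list(
    estrada = sum(exp(lam)),
    laplacian_estrada = sum(exp(mu)),
    energy = sum(abs(lam)),
    laplacian_energy = sum(abs(mu - 2 * net$m / net$n)))
}

#' Full descriptor panel
#'
#' All nineteen descriptors across the four families.
#'
#' @param net a connected [morph_network()] with `n >= 3`.
#' @return named numeric vector.
#' @export
descriptor_panel <- function(net) {
  unlist(c(distance_descriptors(net),
           invariant_descriptors(net),
           entropy_descriptors(net),
           spectral_descriptors(net)))
}
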
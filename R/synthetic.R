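#' Body plan for a synthetic arthropod morphology network
#'
#' A body plan states an axial chain of segment nodes, a set of appendages
#' (chains of articles rooted on a segment, optionally bilateral, optionally
#' with random single-article side branches), an optional carapace node
#' linked to a set of segments, explicit extra anatomical edges, and random
#' extra cycle edges.  Generated networks are simple and connected; the
#' excess `m - n + 1` stays small (quasi-trees), as in real external
#' morphologies where almost every unit hangs off exactly one parent.
#'
#' @param axis character vector of axial segment labels, connected in a chain.
#' @param appendages `data.frame` with columns `name`, `segment` (an axis
#'   label), `chain_length` (articles per chain, >= 1), `bilateral` (logical:
#'   mirrored `R-`/`L-` copies with no cross-links), and optionally
#'   `branch_prob` (per-article probability of a one-article side branch,
#'   default 0).
#' @param carapace_links axis labels the carapace node attaches to
#'   (empty = no carapace).
#' @param extra_edges optional 2-column character matrix of extra label pairs.
#' @param extra_cycle_edges number of additional random chord edges.
#' @param seed seed for branches and random chords.
#' @return a `body_plan` object.
#' @export
body_plan <- function(axis, appendages = NULL, carapace_links = character(),
                      extra_edges = NULL, extra_cycle_edges = 0L, seed = 1L) {
  stopifnot(is.character(axis), length(axis) >= 1, !anyDuplicated(axis))
  if (!is.null(appendages)) {
    stopifnot(is.data.frame(appendages),
              all(c("name", "segment", "chain_length", "bilateral") %in%
                  names(appendages)),
              all(appendages$segment %in% axis),
              all(appendages$chain_length >= 1))
    if (is.null(appendages$branch_prob)) appendages$branch_prob <- 0
  }
  stopifnot(all(carapace_links %in% axis))
  structure(
    list(axis = axis, appendages = appendages,
         carapace_links = carapace_links, extra_edges = extra_edges,
         extra_cycle_edges = as.integer(extra_cycle_edges), seed = seed),
    class = "body_plan")
}

#' Generate a morphology network from a body plan
#'
#' Articles are labelled `"<side>-<name>-art<i>"` (`side` omitted for
#' unpaired appendages); the carapace node is `"carapace"`.  Bilateral
#' appendages are mirrored labels but independent subtrees, matching the
#' left/right module pairs observed in real anatomical networks.
#'
#' @param plan a [body_plan()].
#' @return a connected [morph_network()].
#' @export
generate_morphology <- function(plan) {
  stopifnot(inherits(plan, "body_plan"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(plan$seed)
  labels <- plan$axis
  edges <- if (length(plan$axis) > 1) {
    cbind(plan$axis[-length(plan$axis)], plan$axis[-1])
  } else {
    matrix(character(), 0, 2)
  }
  add_chain <- function(root, name, side, L, branch_prob) {
    arts <- if (nzchar(side)) {
      sprintf("%s-%s-art%d", side, name, seq_len(L))
    } else {
      sprintf("%s-art%d", name, seq_len(L))
    }
    labels <<- c(labels, arts)
    edges <<- rbind(edges, cbind(c(root, arts[-L]), arts))
    if (branch_prob > 0) {
      for (i in seq_len(L)) {
        if (stats::runif(1) < branch_prob) {
          br <- paste0(arts[i], "-branch")
          labels <<- c(labels, br)
          edges <<- rbind(edges, cbind(arts[i], br))
        }
      }
    }
  }
  if (!is.null(plan$appendages)) {
    nm <- plan$appendages$name
    # appendage names repeated on several segments get the segment appended
    # so article labels stay unique
    nm <- ifelse(nm %in% nm[duplicated(nm)],
                 paste(nm, plan$appendages$segment, sep = "-"), nm)
    for (r in seq_len(nrow(plan$appendages))) {
      ap <- plan$appendages[r, ]
      sides <- if (isTRUE(ap$bilateral)) c("R", "L") else ""
      for (s in sides) {
        add_chain(ap$segment, nm[r], s, ap$chain_length, ap$branch_prob)
      }
    }
  }
  if (length(plan$carapace_links)) {
    labels <- c(labels, "carapace")
    edges <- rbind(edges, cbind("carapace", plan$carapace_links))
  }
  if (!is.null(plan$extra_edges)) {
    stopifnot(all(plan$extra_edges %in% labels))
    edges <- rbind(edges, plan$extra_edges)
  }
  n <- length(labels)
  a <- matrix(0L, n, n, dimnames = list(labels, labels))
  a[edges] <- 1L
  a[edges[, 2:1, drop = FALSE]] <- 1L
  if (plan$extra_cycle_edges > 0L) {
    added <- 0L
    guard <- 0L
    while (added < plan$extra_cycle_edges && guard < 1000L * plan$extra_cycle_edges) {
      guard <- guard + 1L
      ij <- sample.int(n, 2L)
      if (a[ij[1], ij[2]] == 0L) {
        a[ij[1], ij[2]] <- a[ij[2], ij[1]] <- 1L
        added <- added + 1L
      }
    }
  }
  morph_network(a, labels = labels)
}

#' Fuse a set of nodes into one
#'
#' The fused node carries the union of the members' external neighbourhoods;
#' duplicate edges collapse, so `n` drops by `|node_set| - 1` and `m` by at
#' least the number of internal edges.  The set must induce a connected
#' subgraph (anatomical fusions join physically contiguous units).
#'
#' @param net a [morph_network()].
#' @param node_set character vector of labels to merge (a singleton is the
#'   identity operation).
#' @param new_label label of the fused node.
#' @return a [morph_network()].
#' @export
fuse_nodes <- function(net, node_set, new_label) {
  stopifnot(inherits(net, "morph_network"), length(node_set) >= 1)
  missing <- setdiff(node_set, net$labels)
  if (length(missing)) stop("unknown node: ", missing[1])
  if (length(node_set) == 1L) {
    if (node_set == new_label) return(net)
    labels <- replace(net$labels, net$labels == node_set, new_label)
    a <- adjacency_matrix(net)
    dimnames(a) <- list(labels, labels)
    return(morph_network(a, labels = labels,
                         require_connected = igraph::is_connected(net$graph)))
  }
  a <- adjacency_matrix(net)
  sub <- a[node_set, node_set, drop = FALSE]
  if (!connected_from_adjacency(sub)) {
    stop("node_set must induce a connected subgraph")
  }
  keep <- setdiff(net$labels, node_set)
  merged <- as.integer(colSums(a[node_set, keep, drop = FALSE]) > 0)
  # fused node takes the position of the first member
  pos <- match(node_set[1], net$labels)
  labels <- append(keep, new_label,
                   after = sum(!(net$labels[seq_len(pos - 1)] %in% node_set)))
  b <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  b[keep, keep] <- a[keep, keep]
  b[new_label, keep] <- merged
  b[keep, new_label] <- merged
  morph_network(b, labels = labels,
                require_connected = igraph::is_connected(net$graph))
}

#' Synthetic developmental phase series
#'
#' Builds four synthetic stand-in networks emulating the published anatomy of
#' the brachyuran ontogenetic series — egg-nauplius, zoea, megalopa, adult —
#' with the published node and edge counts (26/29, 77/83, 210/222, 174/178),
#' quasi-tree structure, bilateral appendage modules and a carapace hub
#' linked to the head and thoracic segments.  The adult is produced from the
#' megalopa body plan by appendage remodelling (loss of larval pleopods and
#' uropods, gain of gonopods and penes) followed by the anatomical fusions
#' that create the cephalon (head segments 1-6), the fused thoracomere 1-4
#' and the fused pleomere 3-5.  These are synthetic reconstructions from the
#' published description, not the original published matrices.
#'
#' @param seed seed passed to the generators (the presets are deterministic;
#'   the seed matters only if plans are modified to use random branches).
#' @return named list of four [morph_network()]s:
#'   `egg_nauplius`, `zoea`, `megalopa`, `adult`.
#' @export
phase_series <- function(seed = 1L) {
  list(egg_nauplius = generate_morphology(egg_nauplius_plan(seed)),
       zoea = generate_morphology(zoea_plan(seed)),
       megalopa = generate_morphology(megalopa_plan(seed)),
       adult = adult_from_megalopa(seed))
}

app_spec <- function(name, segment, chain_length, bilateral = TRUE) {
  data.frame(name = name, segment = segment, chain_length = chain_length,
             bilateral = bilateral, branch_prob = 0)
}

egg_nauplius_plan <- function(seed = 1L) {
  # the egg-nauplius is a ventral disc: every rudimentary segment sits
  # directly on the embryonic body ("axis" here is that star, closed by
  # extra contacts between physically adjacent segments, which create the
  # triangles this compact phase is known for)
  body_plan(
    axis = c("embryonic-body", "hs1", "hs2", "hs3", "hs4", "caudal-papille"),
    appendages = rbind(
      app_spec("eye", "hs1", 2),
      app_spec("antennule", "hs2", 2),
      app_spec("antenna", "hs3", 2),
      app_spec("mandible", "hs4", 2),
      app_spec("caudal-seta", "caudal-papille", 2)),
    extra_edges = rbind(
      c("embryonic-body", "hs2"),
      c("embryonic-body", "hs3"),
      c("embryonic-body", "hs4"),
      c("embryonic-body", "caudal-papille")),
    seed = seed)
}

zoea_plan <- function(seed = 1L) {
  body_plan(
    axis = c("acron", paste0("hs", 1:5), "th1", "th2",
             paste0("pl", 1:5), "telson"),
    appendages = rbind(
      app_spec("eye", "acron", 1),
      app_spec("antennule", "hs1", 2),
      app_spec("antenna", "hs2", 4),
      app_spec("mandible", "hs3", 2),
      app_spec("maxillula", "hs4", 4),
      app_spec("maxilla", "hs5", 4),
      app_spec("maxilliped1", "th1", 7),
      app_spec("maxilliped2", "th2", 7)),
    carapace_links = c("hs3", "hs4", "hs5", "th1", "th2"),
    extra_edges = rbind(
      c("carapace", "hs2"),
      c("R-eye-art1", "hs1"),
      c("L-eye-art1", "hs1")),
    seed = seed)
}

megalopa_plan <- function(seed = 1L) {
  body_plan(
    axis = c(paste0("hs", 1:6), paste0("th", 1:8), paste0("pl", 1:6),
             "telson"),
    appendages = rbind(
      app_spec("eye", "hs1", 2),
      app_spec("antennule", "hs2", 4),
      app_spec("antenna", "hs3", 5),
      app_spec("mandible", "hs4", 3),
      app_spec("maxillula", "hs5", 4),
      app_spec("maxilla", "hs6", 4),
      app_spec("maxilliped1", "th1", 6),
      app_spec("maxilliped2", "th2", 6),
      app_spec("maxilliped3", "th3", 6),
      app_spec("pereopod1", "th4", 7),
      app_spec("pereopod2", "th5", 7),
      app_spec("pereopod3", "th6", 7),
      app_spec("pereopod4", "th7", 7),
      app_spec("pereopod5", "th8", 7),
      app_spec("pleopod2", "pl2", 4),
      app_spec("pleopod3", "pl3", 4),
      app_spec("pleopod4", "pl4", 4),
      app_spec("pleopod5", "pl5", 4),
      app_spec("uropod", "pl6", 3)),
    carapace_links = c(paste0("hs", 1:6), paste0("th", 1:8)),
    seed = seed)
}

adult_from_megalopa <- function(seed = 1L) {
  plan <- megalopa_plan(seed)
  ap <- plan$appendages
  # appendage remodelling: drop larval pleopods and uropods, add gonopods
  # (pleomeres 1-2) and penes (last thoracomere)
  ap <- ap[!ap$name %in% c("pleopod2", "pleopod3", "pleopod4", "pleopod5",
                           "uropod"), ]
  ap <- rbind(ap,
              app_spec("gonopod1", "pl1", 3),
              app_spec("gonopod2", "pl2", 2),
              app_spec("penis", "th8", 1))
  plan$appendages <- ap
  net <- generate_morphology(plan)
  net <- fuse_nodes(net, paste0("hs", 1:6), "cephalon")
  net <- fuse_nodes(net, paste0("th", 1:4), "fused-thoracomere-1-4")
  fuse_nodes(net, paste0("pl", 3:5), "pleomere-3-5")
}
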
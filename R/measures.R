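measure_families <- function() {
  list(
    params = c("nodes", "edges", "diameter", "radius", "avg_path_length",
               "avg_degree", "avg_clustering", "density"),
    efficiency = "global_efficiency",
    mag = "MAg", ce = "Ce", cr = "Cr", odc = "OdC",
    sts = c("STS", "STSD"),
    c1e = c("C1e_ST", "C1e_spec"),
    distance = c("wiener", "harary", "balaban_j", "compactness",
                 "centralization"),
    invariant = c("zagreb_m1", "randic", "complexity_index_b",
                  "normalized_edge_complexity"),
    entropy = c("topological_info_content", "bonchev", "bertz",
                "radial_centric", "balaban_like_info", "edge_equality"),
    spectral = c("estrada", "laplacian_estrada", "energy",
                 "laplacian_energy"))
}

#' Names of all measures known to the battery
#' @return character vector of measure names usable in
#'   [ensemble_compare()] and [run_battery()].
#' @export
available_measures <- function() {
  unname(unlist(measure_families()))
}

#' Evaluate a set of named measures on one network
#'
#' Measures are computed family-by-family so shared work (distance matrices,
#' spanning-tree counts, spectra) is done once per family.
#'
#' @param net a connected [morph_network()].
#' @param measures character vector of names from [available_measures()].
#' @return named numeric vector, one entry per requested measure.
#' @export
evaluate_measures <- function(net, measures = available_measures()) {
  fams <- measure_families()
  unknown <- setdiff(measures, unlist(fams))
  if (length(unknown)) stop("measure unavailable: ", unknown[1])
  out <- c()
  compute <- function(fam) {
    switch(fam,
      params = unlist(basic_parameters(net)),
      efficiency = c(global_efficiency = global_efficiency(net)),
      mag = c(MAg = medium_articulation(net)),
      ce = c(Ce = efficiency_complexity(net)),
      cr = c(Cr = graph_index_complexity(net)),
      odc = c(OdC = offdiagonal_complexity(net)),
      sts = unlist(spanning_tree_sensitivity(net)),
      c1e = unlist(one_edge_deleted_complexity(net)),
      distance = unlist(distance_descriptors(net)),
      invariant = unlist(invariant_descriptors(net)),
      entropy = unlist(entropy_descriptors(net)),
      spectral = unlist(spectral_descriptors(net)))
  }
  for (fam in names(fams)) {
    want <- intersect(fams[[fam]], measures)
    if (length(want)) out <- c(out, compute(fam)[want])
  }
  out[measures]
}
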
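#' Read an anatomical network from a delimited adjacency-matrix file
#'
#' Accepts comma-, tab- or semicolon-delimited square 0/1 matrices.  An
#' optional header row and/or a leading label column are auto-detected: if the
#' first row (column) cannot be parsed as numbers it is taken to hold labels.
#' Labels found in both header and first column must agree with the header.
#'
#' @param path path to the matrix file.
#' @param require_connected error on disconnected graphs (default `TRUE`).
#' @return a [morph_network()].
#' @export
read_adjacency <- function(path, require_connected = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error: empty file ", path)
  sep <- detect_sep(lines[[1]])
  cells <- strsplit(lines, sep, fixed = FALSE)
  cells <- lapply(cells, trimws)
  widths <- lengths(cells)

  first_row <- cells[[1]]
  suppressWarnings(first_num <- as.numeric(first_row))
  has_header <- anyNA(first_num[nzchar(first_row)])
  body <- if (has_header) cells[-1] else cells
  if (!length(body)) stop("format error: no data rows in ", path)
  first_col <- vapply(body, `[[`, "", 1L)
  suppressWarnings(fc_num <- as.numeric(first_col))
  has_label_col <- anyNA(fc_num)

  row_labels <- if (has_label_col) first_col else NULL
  data <- lapply(body, function(r) if (has_label_col) r[-1] else r)
  nums <- lapply(data, function(r) suppressWarnings(as.numeric(r)))
  ncols <- unique(lengths(nums))
  if (length(ncols) != 1L || ncols != length(nums)) {
    stop("format error: matrix is not square (",
         length(nums), " rows, ", paste(ncols, collapse = "/"), " columns)")
  }
  mat <- do.call(rbind, nums)
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("format error: non-numeric entry at row %d, column %d",
                 idx[1], idx[2]))
  }
  labels <- row_labels
  if (is.null(labels) && has_header) {
    hdr <- first_row[nzchar(first_row)]
    # header may carry a stub cell for the label column
    if (length(hdr) == ncols + 1L) hdr <- hdr[-1]
    if (length(hdr) == ncols) labels <- hdr
  }
  morph_network(mat, labels = labels, require_connected = require_connected)
}

detect_sep <- function(line) {
  counts <- c("," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))))
  if (all(counts == 0)) return("[[:space:]]+")
  c(",", "\t", ";")[which.max(counts)]
}

#' Classical network parameter table
#'
#' Computes the eight classical parameters used to characterise each
#' developmental phase: node and edge counts, diameter, radius, average
#' shortest-path length (mean over all unordered pairs of distinct nodes),
#' average degree `2m/n`, average local clustering coefficient and density
#' `2m/(n(n-1))`.
#'
#' The local clustering coefficient is undefined for nodes of degree < 2.
#' Two conventions are implemented: `"exclude"` (default) averages only over
#' nodes where it is defined, `"zero"` counts undefined nodes as zero.  The
#' default matches the behaviour of igraph's average local transitivity,
#' the convention of the toolchain this analysis emulates.
#'
#' @param net a connected [morph_network()].
#' @param clustering one of `"exclude"` or `"zero"` (degree-<2 convention).
#' @return a one-row `data.frame` with columns `nodes`, `edges`, `diameter`,
#'   `radius`, `avg_path_length`, `avg_degree`, `avg_clustering`, `density`.
#' @export
basic_parameters <- function(net, clustering = c("exclude", "zero")) {
  stopifnot(inherits(net, "morph_network"))
  clustering <- match.arg(clustering)
  stop_if_disconnected(net, "basic_parameters")
  if (net$n < 2L) stop("avg_path_length undefined for a single-node network")
  g <- net$graph
  n <- net$n
  m <- net$m
  ecc <- igraph::eccentricity(g)
  data.frame(
    nodes = n,
    edges = m,
    diameter = as.integer(max(ecc)),
    radius = as.integer(min(ecc)),
    avg_path_length = igraph::mean_distance(g, directed = FALSE),
    avg_degree = 2 * m / n,
    avg_clustering = avg_clustering_coef(net, convention = clustering),
    density = 2 * m / (n * (n - 1))
  )
}

#' Average local clustering coefficient
#'
#' @inheritParams basic_parameters
#' @param convention `"exclude"` drops degree-<2 nodes from the average,
#'   `"zero"` scores them 0.
#' @export
avg_clustering_coef <- function(net, convention = c("exclude", "zero")) {
  convention <- match.arg(convention)
  loc <- igraph::transitivity(net$graph, type = "local", isolates = "NaN")
  if (convention == "zero") loc[is.nan(loc)] <- 0
  if (all(is.nan(loc))) return(0)
  mean(loc, na.rm = TRUE)
}

#' Write a morph_network to disk
#'
#' Round-trip guarantee: `read_adjacency(write_network(net, p, "matrix"))`
#' reproduces labels and edge set exactly.
#'
#' @param net a [morph_network()].
#' @param path output file path.
#' @param format `"matrix"` (labelled CSV adjacency matrix), `"graphml"`, or
#'   `"edgelist"` (two tab-separated label columns, one row per edge).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix", "graphml", "edgelist")) {
  stopifnot(inherits(net, "morph_network"))
  format <- match.arg(format)
  switch(format,
    matrix = {
      a <- adjacency_matrix(net)
      utils::write.table(
        cbind(label = rownames(a), as.data.frame(a)),
        file = path, sep = ",", qmethod = "double",
        row.names = FALSE, col.names = TRUE, quote = FALSE)
    },
    graphml = igraph::write_graph(net$graph, path, format = "graphml"),
    edgelist = {
      ep <- edge_pairs(net)
      writeLines(paste(ep[, 1], ep[, 2], sep = "\t"), con = path)
    })
  invisible(path)
}
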
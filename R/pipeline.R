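#' Run the full measure battery over an ontogenetic series
#'
#' Evaluates every requested measure on every network of the ordered series.
#' Failures are isolated per measure (the cell becomes `NA` and the reason is
#' recorded), so one pathological network cannot sink the whole battery.
#'
#' @param networks ordered, named list of connected [morph_network()]s
#'   (earliest phase first, >= 2 networks).
#' @param measures character vector from [available_measures()].
#' @return a `measure_matrix`: list with `values` (measures x phases matrix),
#'   `percent_change` (signed change relative to the earlier phase, in %),
#'   and `failures` (named character vector of error messages, if any).
#' @export
run_battery <- function(networks, measures = available_measures()) {
  stopifnot(is.list(networks), length(networks) >= 2)
  ok <- vapply(networks, inherits, TRUE, what = "morph_network")
  if (!all(ok)) stop("invalid network in series at position ", which(!ok)[1])
  if (is.null(names(networks))) {
    names(networks) <- paste0("phase", seq_along(networks))
  }
  values <- matrix(NA_real_, length(measures), length(networks),
                   dimnames = list(measures, names(networks)))
  failures <- character()
  for (j in seq_along(networks)) {
    res <- tryCatch(evaluate_measures(networks[[j]], measures),
                    error = function(e) e)
    if (inherits(res, "error")) {
      # fall back to measure-by-measure so one failure stays isolated
      for (msr in measures) {
        one <- tryCatch(evaluate_measures(networks[[j]], msr),
                        error = function(e) e)
        if (inherits(one, "error")) {
          failures[paste(names(networks)[j], msr, sep = ":")] <-
            conditionMessage(one)
        } else {
          values[msr, j] <- one
        }
      }
    } else {
      values[, j] <- res[measures]
    }
  }
  pct <- 100 * (values[, -1, drop = FALSE] -
                values[, -ncol(values), drop = FALSE]) /
         values[, -ncol(values), drop = FALSE]
  colnames(pct) <- paste(colnames(values)[-ncol(values)],
                         colnames(values)[-1], sep = "->")
  structure(list(values = values, percent_change = pct, failures = failures),
            class = "measure_matrix")
}

#' @export
print.measure_matrix <- function(x, ...) {
  cat(sprintf("<measure_matrix> %d measures x %d phases\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 4))
  if (length(x$failures)) {
    cat("failures:\n")
    for (nm in names(x$failures)) cat(" ", nm, ":", x$failures[nm], "\n")
  }
  invisible(x)
}

#' Families used for intensive/extensive trend classification
#' @return list with `complexity` and `descriptor` measure-name vectors.
#' @export
trend_families <- function() {
  fams <- measure_families()
  list(
    complexity = unlist(fams[c("mag", "ce", "cr", "odc", "sts", "c1e")],
                        use.names = FALSE),
    descriptor = unlist(fams[c("distance", "invariant", "entropy",
                               "spectral")], use.names = FALSE))
}

#' Classify measure trends as intensive or extensive
#'
#' Monotonicity is assessed over the first three phases (the larval series);
#' the transition into the final phase is a distinct structural metamorphosis
#' and is reported separately as a sign.  A complexity-family measure that
#' decreases over the larval series is labelled *intensive* (normalised,
#' folded complexity that the unfolding consumes); a descriptor-family
#' measure that increases is labelled *extensive* (manifest, size-like
#' complexity that unfolding accumulates).
#'
#' @param matrix a `measure_matrix` from [run_battery()] with >= 3 phases.
#' @param families list with `complexity` and `descriptor` name vectors
#'   (default [trend_families()]).
#' @return a `data.frame` with `measure`, `family`, `trajectory`
#'   (increasing / decreasing / flat / non-monotone), `adult_transition`
#'   (-1, 0, 1 sign of the final step), `label` (intensive / extensive /
#'   unclassified).
#' @export
classify_trends <- function(matrix, families = trend_families()) {
  stopifnot(inherits(matrix, "measure_matrix"))
  v <- matrix$values
  if (ncol(v) < 3) stop("trend classification needs >= 3 phases")
  out <- lapply(rownames(v), function(msr) {
    x <- v[msr, ]
    if (anyNA(x)) {
      warning("measure skipped (missing values): ", msr)
      return(NULL)
    }
    first3 <- x[1:3]
    d <- diff(first3)
    trajectory <-
      if (all(d > 0)) "increasing"
      else if (all(d < 0)) "decreasing"
      else if (all(d == 0)) "flat"
      else "non-monotone"
    family <-
      if (msr %in% families$complexity) "complexity"
      else if (msr %in% families$descriptor) "descriptor"
      else "other"
    label <-
      if (family == "complexity" && trajectory == "decreasing") "intensive"
      else if (family == "descriptor" && trajectory == "increasing") "extensive"
      else "unclassified"
    data.frame(measure = msr, family = family, trajectory = trajectory,
               adult_transition = if (ncol(v) >= 4)
                 sign(x[ncol(v)] - x[ncol(v) - 1]) else NA_real_,
               label = label, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Write the pipeline report to disk
#'
#' Emits deterministic CSV/JSON artefacts: `params.csv` (the classical
#' parameter table per phase), `measures.csv` (the full battery),
#' `percent_change.csv`, `trends.json`, optionally `ratios.csv` (ensemble
#' comparisons), plus a `manifest.json` listing what was written.
#'
#' @param matrix a `measure_matrix`.
#' @param trends a trend table from [classify_trends()].
#' @param ensembles optional named list of `null_ensemble`s (one per phase).
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
report_results <- function(matrix, trends, ensembles = NULL, out_dir) {
  stopifnot(inherits(matrix, "measure_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, name)
  }
  params <- intersect(measure_families()$params, rownames(matrix$values))
  if (length(params)) {
    emit_csv(data.frame(parameter = params,
                        matrix$values[params, , drop = FALSE],
                        check.names = FALSE), "params.csv")
  }
  emit_csv(data.frame(measure = rownames(matrix$values),
                      matrix$values, check.names = FALSE), "measures.csv")
  emit_csv(data.frame(measure = rownames(matrix$percent_change),
                      matrix$percent_change, check.names = FALSE),
           "percent_change.csv")
  jsonlite::write_json(trends, file.path(out_dir, "trends.json"),
                       dataframe = "rows", digits = NA)
  written <- c(written, "trends.json")
  if (!is.null(ensembles)) {
    rows <- do.call(rbind, lapply(names(ensembles), function(ph) {
      e <- ensembles[[ph]]
      data.frame(phase = ph, measure = names(e$ratio),
                 observed = unname(e$observed), ensemble_mean = unname(e$mean),
                 ratio = unname(e$ratio), row.names = NULL)
    }))
    emit_csv(rows, "ratios.csv")
  }
  manifest <- list(files = written,
                   has_ensembles = !is.null(ensembles))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(c(written, "manifest.json"))
}
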
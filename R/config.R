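#' Pipeline configuration
#'
#' One flat bag of tunables shared by the command-line interface and the
#' programmatic entry points. Defaults follow the study design this pipeline
#' implements: a 100,000-read QC cutoff, the 8 log2(CPM+1) in at least 2 of 6
#' neuronal markers rule, differential-expression alpha 0.01, top 150 genes
#' per stage pair, 1000 bootstrap iterations and 5000 permutations.
#'
#' @param min_reads minimum uniquely mapped reads per cell (cells with fewer
#'   are removed; strict `<`).
#' @param marker_min_expr log2(CPM+1) threshold for the neuronal marker rule.
#' @param marker_min_count minimum number of panel genes above threshold.
#' @param marker_panel_size expected size of the neuronal marker panel.
#' @param n_top_overdispersed number of overdispersed genes to keep.
#' @param n_bins mean-expression bins for the dispersion z-score.
#' @param icim_min_cells,icim_max_depth,icim_min_markers recursion controls
#'   for iterative marker discovery.
#' @param min_cluster_size,min_samples density-clustering parameters.
#' @param resolution,knn_k graph-clustering parameters.
#' @param alpha adjusted-p cutoff for differential expression (strict `<`).
#' @param k_top_pair genes kept per stage pair for the dynamic-gene union.
#' @param expr_threshold,frac_threshold,max_pair_search marker-matching
#'   parameters: a gene is "expressed" in a cluster when at least
#'   `frac_threshold` of its cells have log2(CPM+1) >= `expr_threshold`.
#' @param n_boot bootstrap iterations for confidence intervals.
#' @param n_perm permutation iterations for the birth-order test.
#' @param min_group minimum earlier/later group size in the birth-order
#'   statistic.
#' @param seed random seed used by every stochastic step.
#' @return A classed list of parameters.
#' @export
pipeline_config <- function(min_reads = 100000, marker_min_expr = 8,
                            marker_min_count = 2, marker_panel_size = 6,
                            n_top_overdispersed = 500, n_bins = 20,
                            icim_min_cells = 10, icim_max_depth = 8,
                            icim_min_markers = 5,
                            min_cluster_size = 10, min_samples = 5,
                            resolution = 1, knn_k = 15,
                            alpha = 0.01, k_top_pair = 150,
                            expr_threshold = 2, frac_threshold = 0.5,
                            max_pair_search = 200,
                            n_boot = 1000, n_perm = 5000, min_group = 5,
                            seed = 0) {
  cfg <- as.list(environment())
  for (nm in c("n_boot", "n_perm"))
    if (cfg[[nm]] < 1) pn_parameter_error(sprintf("%s must be >= 1", nm))
  if (alpha <= 0 || alpha >= 1) pn_parameter_error("alpha must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read/write a plain-text configuration file
#'
#' `key = value` lines; `#` starts a comment. Values are parsed as numbers
#' where possible. Unknown keys are rejected so typos fail loudly.
#'
#' @param path file path.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) pn_io_error(sprintf("config file not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) pn_format_error(sprintf("bad config line: %s", ln))
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      vals[[key]] <- if (!is.na(num)) num else val
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) pn_format_error(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a [pipeline_config()] to serialize.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm)
    sprintf("%s = %s", nm, format(config[[nm]], scientific = FALSE)), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
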
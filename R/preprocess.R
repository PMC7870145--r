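#' Quality-control parameters
#'
#' @param min_reads cells with fewer uniquely mapped reads are removed
#'   (strict `<`; the default follows the 100,000-read cutoff used for
#'   SMART-seq2 projection-neuron libraries).
#' @param marker_min_expr log2(CPM+1) threshold for the neuronal marker rule.
#' @param marker_min_count minimum number of panel genes at or above the
#'   threshold (inclusive `>=`).
#' @param marker_panel_size expected panel size (the canonical panel is six
#'   genes: elav, brp, Syt1, nSyb, CadN, mCD8-GFP).
#' @return A classed parameter list.
#' @export
qc_params <- function(min_reads = 100000, marker_min_expr = 8,
                      marker_min_count = 2, marker_panel_size = 6) {
  if (min_reads < 0) pn_parameter_error("min_reads must be >= 0")
  if (marker_min_count <= 0 || marker_min_count > marker_panel_size)
    pn_parameter_error("need 0 < marker_min_count <= marker_panel_size")
  structure(list(min_reads = min_reads, marker_min_expr = marker_min_expr,
                 marker_min_count = marker_min_count,
                 marker_panel_size = marker_panel_size), class = "qc_params")
}

# Append one row to the dataset's QC log (used by the CLI summary).
log_qc <- function(ds, rule, n_in, n_removed) {
  log <- attr(ds, "qc_log") %||%
    data.frame(rule = character(), n_in = integer(), n_removed = integer(),
               stringsAsFactors = FALSE)
  attr(ds, "qc_log") <- rbind(log, data.frame(rule = rule, n_in = n_in,
                                              n_removed = n_removed,
                                              stringsAsFactors = FALSE))
  ds
}

#' Remove cells with too few reads
#'
#' Cells with `total_reads < min_reads` (strictly fewer) are flagged
#' `qc_pass = FALSE` and dropped; the order of surviving cells is preserved.
#' Read totals come either from the cell metadata (`source = "metadata"`,
#' appropriate when they are uniquely mapped read counts from an upstream
#' aligner) or from the column sums of the count matrix
#' (`source = "colsums"`, the only option for purely synthetic data).
#'
#' @param dataset an [ExpressionDataset()].
#' @param params a [qc_params()].
#' @param source where per-cell read totals come from.
#' @param drop if `FALSE`, failing cells are retained but flagged.
#' @return The filtered dataset, with a QC log attribute updated.
#' @export
filter_min_reads <- function(dataset, params = qc_params(),
                             source = c("metadata", "colsums"), drop = TRUE) {
  source <- match.arg(source)
  n_in <- ncol(dataset$counts)
  if (n_in == 0) return(log_qc(dataset, "min_reads", 0L, 0L))
  reads <- if (source == "metadata") {
    if (any(is.na(dataset$cells$total_reads)))
      pn_validation_error("total_reads missing in metadata; use source = 'colsums'")
    dataset$cells$total_reads
  } else colSums(dataset$counts)
  fail <- reads < params$min_reads
  dataset$cells$qc_pass <- dataset$cells$qc_pass & !fail
  out <- if (drop) dataset[, which(!fail)] else dataset
  attr(out, "qc_log") <- attr(dataset, "qc_log")
  log_qc(out, "min_reads", n_in, sum(fail))
}

#' Counts-per-million normalization
#'
#' Rescales each cell's gene counts to counts per million
#' (`cpm = counts / colsum * 1e6`) and derives the working expression unit
#' `logcpm = log2(cpm + 1)`. A cell whose column sums to zero gets an
#' all-zero CPM column and is flagged `qc_pass = FALSE` rather than raising
#' an error.
#'
#' @param dataset an [ExpressionDataset()].
#' @return The dataset with `cpm` and `logcpm` layers populated.
#' @export
cpm_normalize <- function(dataset) {
  cs <- colSums(dataset$counts)
  zero <- cs == 0
  denom <- ifelse(zero, 1, cs)
  dataset$cpm <- sweep(dataset$counts, 2, denom, "/") * 1e6
  if (any(zero)) {
    dataset$cpm[, zero] <- 0
    dataset$cells$qc_pass[zero] <- FALSE
    warning(sprintf("%d all-zero cell(s) flagged qc_pass = FALSE", sum(zero)))
  }
  dataset$logcpm <- log2(dataset$cpm + 1)
  dataset
}

#' Neuronal marker filter
#'
#' Retains cells expressing at least `marker_min_expr` log2(CPM+1) in at
#' least `marker_min_count` of the neuronal marker panel genes (those with
#' `is_neuronal_marker = TRUE`; both thresholds inclusive).
#'
#' @inheritParams filter_min_reads
#' @export
filter_neuronal <- function(dataset, params = qc_params(), drop = TRUE) {
  lc <- require_logcpm(dataset)
  panel <- dataset$genes$gene_id[dataset$genes$is_neuronal_marker]
  if (length(panel) == 0) pn_validation_error("no genes flagged is_neuronal_marker")
  if (length(panel) != params$marker_panel_size)
    warning(sprintf("marker panel has %d genes, expected %d; proceeding with actual panel",
                    length(panel), params$marker_panel_size))
  n_in <- ncol(dataset$counts)
  if (n_in == 0) return(log_qc(dataset, "neuronal_marker", 0L, 0L))
  n_hi <- colSums(lc[panel, , drop = FALSE] >= params$marker_min_expr)
  fail <- n_hi < params$marker_min_count
  dataset$cells$qc_pass <- dataset$cells$qc_pass & !fail
  out <- if (drop) dataset[, which(!fail)] else dataset
  attr(out, "qc_log") <- attr(dataset, "qc_log")
  log_qc(out, "neuronal_marker", n_in, sum(fail))
}

#' Run the full QC + normalization sequence
#'
#' Read filter, CPM normalization, neuronal marker filter, in that order.
#'
#' @inheritParams filter_min_reads
#' @export
preprocess <- function(dataset, params = qc_params(),
                       source = c("metadata", "colsums")) {
  source <- match.arg(source)
  dataset <- filter_min_reads(dataset, params, source = source)
  dataset <- cpm_normalize(dataset)
  filter_neuronal(dataset, params)
}

#' QC summary table
#'
#' @param dataset a dataset that has passed through the QC filters.
#' @return data.frame with one row per rule: cells in, removed, retained.
#' @export
qc_summary <- function(dataset) {
  log <- attr(dataset, "qc_log")
  if (is.null(log)) return(data.frame(rule = character(), n_in = integer(),
                                      n_removed = integer(), n_out = integer()))
  log$n_out <- log$n_in - log$n_removed
  log
}
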
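#' Read a Matrix Market count matrix with gene/cell sidecars
#'
#' Reads a sparse coordinate-format count matrix plus two TSV sidecar files
#' listing gene and cell identifiers in matrix order (the layout written by
#' [export_fixture()] and by the common droplet/plate pipelines).
#'
#' @param matrix_path path to the `.mtx` file (integer coordinate format).
#' @param genes_path path to a TSV whose first column is the gene id, one row
#'   per matrix row.
#' @param cells_path path to a TSV whose first column is the cell id.
#' @param metadata_path optional TSV with columns `cell_id`, `stage`,
#'   `lineage`, `type_label`, `birth_rank` (and optionally `total_reads`).
#' @param gene_metadata_path optional TSV with a `gene_id` column and gene
#'   annotations such as `is_neuronal_marker`.
#' @param transpose if `TRUE` the matrix on disk is cells x genes and is
#'   transposed on read.
#' @param stage_levels stage order for the cell annotation.
#' @return An [ExpressionDataset()] with the counts layer populated; CPM and
#'   log-CPM layers are left unset until [cpm_normalize()].
#' @export
read_counts_mtx <- function(matrix_path, genes_path, cells_path,
                            metadata_path = NULL, gene_metadata_path = NULL,
                            transpose = FALSE,
                            stage_levels = c("P0", "P24", "P48", "Adult")) {
  for (p in c(matrix_path, genes_path, cells_path))
    if (!file.exists(p)) pn_io_error(sprintf("file not found: %s", p))
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) pn_format_error(sprintf("cannot parse MTX: %s", conditionMessage(e))))
  m <- as.matrix(m)
  if (isTRUE(transpose)) m <- t(m)
  g <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "", comment.char = "")
  b <- utils::read.table(cells_path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (nrow(g) != nrow(m))
    pn_format_error(sprintf("gene sidecar has %d rows but matrix has %d rows", nrow(g), nrow(m)))
  if (nrow(b) != ncol(m))
    pn_format_error(sprintf("cell sidecar has %d rows but matrix has %d columns", nrow(b), ncol(m)))
  if (any(m < 0) || any(m != floor(m)))
    pn_validation_error("matrix entries must be non-negative integers")
  rownames(m) <- as.character(g[[1]])
  colnames(m) <- as.character(b[[1]])
  cells <- NULL
  if (!is.null(metadata_path)) {
    cells <- read_tsv_det(metadata_path)
    if (!"cell_id" %in% names(cells)) pn_format_error("metadata TSV lacks cell_id column")
  }
  genes_anno <- NULL
  if (!is.null(gene_metadata_path)) {
    genes_anno <- read_tsv_det(gene_metadata_path)
    if (!"gene_id" %in% names(genes_anno)) pn_format_error("gene metadata TSV lacks gene_id column")
  }
  ExpressionDataset(m, cells = cells, genes = genes_anno, stage_levels = stage_levels)
}

#' Read a dense CSV count matrix
#'
#' First column holds gene identifiers, header row holds cell identifiers.
#' Produces a dataset equivalent to [read_counts_mtx()] on the same logical
#' matrix.
#'
#' @inheritParams read_counts_mtx
#' @param path path to the CSV file.
#' @return An [ExpressionDataset()].
#' @export
read_counts_csv <- function(path, metadata_path = NULL, transpose = FALSE,
                            stage_levels = c("P0", "P24", "P48", "Adult")) {
  if (!file.exists(path)) pn_io_error(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) pn_validation_error("duplicate gene ids in CSV")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(m) == 0) m <- matrix(0, 0, ncol(tab) - 1, dimnames = list(NULL, colnames(tab)[-1]))
  rownames(m) <- ids
  if (isTRUE(transpose)) m <- t(m)
  cells <- NULL
  if (!is.null(metadata_path)) cells <- read_tsv_det(metadata_path)
  ExpressionDataset(m, cells = cells, stage_levels = stage_levels)
}

#' Write pipeline results to a directory
#'
#' Generic writer for pipeline products. Tabular content goes to TSV, nested
#' summaries to JSON, with deterministic field ordering so repeated runs are
#' byte-identical.
#'
#' @param results a pipeline result object (`match_result`,
#'   `diversity_report`, `birth_order_result`, `signature_set`,
#'   `dynamic_gene_groups`, or a plain data.frame).
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, out_dir, prefix = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) pn_io_error(sprintf("cannot create directory: %s", out_dir))
  }
  if (file.access(out_dir, 2) != 0) pn_io_error(sprintf("directory not writable: %s", out_dir))
  UseMethod("write_report")
}

#' @export
write_report.data.frame <- function(results, out_dir, prefix = "table") {
  p <- file.path(out_dir, paste0(prefix, ".tsv"))
  write_tsv_det(results, p)
  invisible(p)
}

#' @export
write_report.match_result <- function(results, out_dir, prefix = "match") {
  p1 <- file.path(out_dir, paste0(prefix, "_pairs.tsv"))
  write_tsv_det(results$pairs, p1)
  m <- results$jaccard_matrix
  mt <- data.frame(cluster_a = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  p2 <- file.path(out_dir, paste0(prefix, "_jaccard_matrix.tsv"))
  write_tsv_det(mt, p2)
  p3 <- file.path(out_dir, paste0(prefix, "_summary.json"))
  write_json_det(list(
    stage_a = results$stage_a, stage_b = results$stage_b,
    n_two_way = sum(results$pairs$match_class == "two_way"),
    n_one_way = sum(results$pairs$match_class != "two_way"),
    excluded_clusters_a = results$excluded_a,
    excluded_clusters_b = results$excluded_b), p3)
  invisible(c(p1, p2, p3))
}

#' @export
write_report.signature_set <- function(results, out_dir, prefix = "signatures") {
  p1 <- file.path(out_dir, paste0(prefix, ".tsv"))
  write_tsv_det(results$table, p1)
  p2 <- file.path(out_dir, paste0(prefix, "_summary.json"))
  write_json_det(list(alpha = results$alpha, stage = results$stage,
                      n_clusters = length(results$signatures),
                      signature_sizes = lapply(results$signatures, length)), p2)
  invisible(c(p1, p2))
}

#' @export
write_report.diversity_report <- function(results, out_dir, prefix = "diversity") {
  p <- file.path(out_dir, paste0(prefix, ".tsv"))
  write_tsv_det(as.data.frame(unclass(results), check.names = FALSE), p)
  invisible(p)
}

#' @export
write_report.birth_order_result <- function(results, out_dir, prefix = "birthorder") {
  p1 <- file.path(out_dir, paste0(prefix, ".json"))
  write_json_det(list(observed = results$observed, p_value = results$p_value,
                      n_iter = results$n_iter,
                      n_eligible_types = length(results$eligible_types)), p1)
  p2 <- file.path(out_dir, paste0(prefix, "_permutations.tsv"))
  write_tsv_det(data.frame(iteration = seq_along(results$permutation_stats),
                           statistic = results$permutation_stats), p2)
  invisible(c(p1, p2))
}

#' @export
write_report.dynamic_gene_groups <- function(results, out_dir, prefix = "dynamics") {
  p <- file.path(out_dir, paste0(prefix, ".tsv"))
  write_tsv_det(results$table, p)
  invisible(p)
}
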
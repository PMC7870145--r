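#' Gene-by-cell expression dataset
#'
#' The central data container of the pipeline: a genes x cells matrix of raw
#' counts, optional CPM and log2(CPM+1) layers derived by
#' [cpm_normalize()], and cell/gene annotation tables keyed by the matrix
#' dimnames. Cells carry a developmental stage (an ordered factor, by default
#' `P0 < P24 < P48 < Adult`), a neuroblast lineage (`adPN`, `lPN`, `vPN`,
#' `APL`), an optional type label and birth rank, total read count, and a QC
#' flag. Genes carry an optional role tag (used by the synthetic generator)
#' and a flag marking membership in the neuronal QC marker panel.
#'
#' @param counts genes x cells matrix of non-negative integers. Row names are
#'   gene identifiers, column names cell identifiers; both must be unique.
#' @param cells optional data.frame of cell annotations with a `cell_id`
#'   column; missing columns are filled with defaults.
#' @param genes optional data.frame of gene annotations with a `gene_id`
#'   column.
#' @param stage_levels character vector giving the stage order.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `counts`, `cpm`, `logcpm` (the latter two `NULL` until normalization),
#'   `cells`, `genes`.
#' @seealso [cpm_normalize()], [read_counts_mtx()], [simulate_pn()]
#' @export
ExpressionDataset <- function(counts, cells = NULL, genes = NULL,
                              stage_levels = c("P0", "P24", "P48", "Adult")) {
  if (inherits(counts, "sparseMatrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(is.na(counts))) pn_validation_error("counts contain NA")
  if (any(counts < 0)) pn_validation_error("counts must be non-negative")
  if (any(counts != floor(counts))) pn_validation_error("counts must be integral")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- rownames(counts) <- sprintf("gene_%d", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- colnames(counts) <- sprintf("cell_%d", seq_len(ncol(counts)))
  if (anyDuplicated(gene_ids)) pn_validation_error("duplicate gene ids")
  if (anyDuplicated(cell_ids)) pn_validation_error("duplicate cell ids")

  cells <- build_cell_annotation(cells, cell_ids, counts, stage_levels)
  genes <- build_gene_annotation(genes, gene_ids)

  structure(list(counts = counts, cpm = NULL, logcpm = NULL,
                 cells = cells, genes = genes),
            stage_levels = stage_levels,
            class = "ExpressionDataset")
}

build_cell_annotation <- function(cells, cell_ids, counts, stage_levels) {
  if (is.null(cells)) cells <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cells)) pn_validation_error("cell annotation needs a cell_id column")
  if (!setequal(cells$cell_id, cell_ids))
    pn_validation_error("cell annotation ids do not match matrix columns")
  cells <- cells[match(cell_ids, cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  fill <- function(df, nm, val) {
    if (!nm %in% names(df)) df[[nm]] <- rep(val, length.out = nrow(df))
    df
  }
  cells <- fill(cells, "stage", NA_character_)
  cells$stage <- factor(as.character(cells$stage), levels = stage_levels, ordered = TRUE)
  cells <- fill(cells, "lineage", NA_character_)
  cells <- fill(cells, "type_label", NA_character_)
  cells <- fill(cells, "birth_rank", NA_integer_)
  cells$birth_rank <- as.integer(cells$birth_rank)
  if (any(!is.na(cells$birth_rank) & cells$birth_rank < 1))
    pn_validation_error("birth_rank must be a positive integer")
  if (!"total_reads" %in% names(cells)) cells$total_reads <- colSums(counts)
  cells <- fill(cells, "qc_pass", TRUE)
  cells
}

build_gene_annotation <- function(genes, gene_ids) {
  if (is.null(genes)) genes <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes)) pn_validation_error("gene annotation needs a gene_id column")
  if (!setequal(genes$gene_id, gene_ids))
    pn_validation_error("gene annotation ids do not match matrix rows")
  genes <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  if (!"role" %in% names(genes)) genes$role <- rep("unassigned", nrow(genes))
  if (!"is_neuronal_marker" %in% names(genes)) genes$is_neuronal_marker <- rep(FALSE, nrow(genes))
  genes
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  layers: counts%s%s\n",
              if (!is.null(x$cpm)) ", cpm" else "",
              if (!is.null(x$logcpm)) ", logcpm" else ""))
  st <- table(x$cells$stage)
  if (sum(st) > 0) cat("  stages:", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
  ln <- table(x$cells$lineage)
  if (length(ln)) cat("  lineages:", paste(sprintf("%s=%d", names(ln), ln), collapse = " "), "\n")
  cat(sprintf("  qc_pass: %d/%d cells\n", sum(x$cells$qc_pass), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Subset an expression dataset
#'
#' Works like matrix subsetting: `ds[genes, cells]` with integer, logical or
#' character indices; all layers and annotations are subset consistently.
#'
#' @param x an [ExpressionDataset()].
#' @param i gene index. @param j cell index. @param ... ignored.
#' @export
`[.ExpressionDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  out <- x
  out$counts <- x$counts[i, j, drop = FALSE]
  if (!is.null(x$cpm)) out$cpm <- x$cpm[i, j, drop = FALSE]
  if (!is.null(x$logcpm)) out$logcpm <- x$logcpm[i, j, drop = FALSE]
  gi <- match(rownames(out$counts), x$genes$gene_id)
  ci <- match(colnames(out$counts), x$cells$cell_id)
  out$genes <- x$genes[gi, , drop = FALSE]; rownames(out$genes) <- NULL
  out$cells <- x$cells[ci, , drop = FALSE]; rownames(out$cells) <- NULL
  out
}

#' @rdname ExpressionDataset
#' @param x an `ExpressionDataset`.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname ExpressionDataset
#' @export
cell_ids <- function(x) colnames(x$counts)

#' @rdname ExpressionDataset
#' @export
stage_levels <- function(x) attr(x, "stage_levels")

# Cells passing QC, optionally restricted to a stage and/or lineage.
#' Subset to QC-passing cells of a given stage/lineage
#' @param x an [ExpressionDataset()].
#' @param stage optional stage name. @param lineage optional lineage name.
#' @export
subset_cells <- function(x, stage = NULL, lineage = NULL) {
  keep <- x$cells$qc_pass
  if (!is.null(stage)) keep <- keep & as.character(x$cells$stage) %in% stage
  if (!is.null(lineage)) keep <- keep & x$cells$lineage %in% lineage
  x[, which(keep)]
}

# logcpm layer or error; most analysis entry points call this.
require_logcpm <- function(x) {
  if (is.null(x$logcpm))
    pn_validation_error("logcpm layer missing; run cpm_normalize() first")
  x$logcpm
}
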
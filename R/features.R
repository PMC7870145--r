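#' Overdispersed gene selection
#'
#' Ranks genes by the z-score of their dispersion (variance/mean of
#' log2(CPM+1)) within equal-occupancy mean-expression bins, and returns the
#' top `n_top`. Deterministic: all ties break by lexicographic gene id.
#'
#' @param dataset a normalized [ExpressionDataset()] with at least 2 cells.
#' @param n_top number of genes to return (0 gives an empty set).
#' @param n_bins number of mean-expression bins for the z-score.
#' @param cells optional logical/integer subset of cells to use.
#' @return A `feature_set`: character vector of gene ids with attributes
#'   `method`, `params` and `provenance`.
#' @export
overdispersed_genes <- function(dataset, n_top = 500, n_bins = 20, cells = NULL) {
  lc <- require_logcpm(dataset)
  if (!is.null(cells)) lc <- lc[, cells, drop = FALSE]
  if (ncol(lc) < 2) pn_validation_error("need >= 2 cells")
  if (n_top > nrow(lc)) {
    warning("n_top exceeds number of genes; returning all genes")
    n_top <- nrow(lc)
  }
  if (n_top == 0) return(feature_set(character(), "overdispersed",
                                     list(n_top = 0, n_bins = n_bins)))
  m <- rowMeans(lc)
  v <- matrixStats::rowVars(lc)
  disp <- ifelse(m > 0, v / m, 0)
  expressed <- m > 0
  # equal-occupancy bins on mean expression (among expressed genes)
  z <- rep(-Inf, nrow(lc))
  if (any(expressed)) {
    r <- rank(m[expressed], ties.method = "first")
    bins <- ceiling(r / length(r) * min(n_bins, length(r)))
    d <- disp[expressed]
    mu_b <- tapply(d, bins, mean)
    sd_b <- tapply(d, bins, stats::sd)
    sd_b[is.na(sd_b) | sd_b == 0] <- 1
    z[expressed] <- (d - mu_b[as.character(bins)]) / sd_b[as.character(bins)]
  }
  ids <- rownames(lc)
  ord <- order(-z, ids)
  feature_set(ids[ord[seq_len(n_top)]], "overdispersed",
              list(n_top = n_top, n_bins = n_bins))
}

feature_set <- function(genes, method, params, provenance = NULL) {
  structure(as.character(genes), method = method, params = params,
            provenance = provenance, class = c("feature_set", "character"))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set (%s): %d genes\n", attr(x, "method"), length(x)))
  if (length(x)) cat("  ", paste(utils::head(x, 8), collapse = ", "),
                     if (length(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Iterative marker-gene discovery
#'
#' Recursive bipartition in the spirit of iterative clustering for marker
#' identification: at each node, overdispersed genes are selected among the
#' current cells, the cells are split in two by Ward hierarchical clustering
#' in that gene space, and the split is accepted only if at least
#' `min_markers` genes distinguish the two subgroups at BH-adjusted p < 0.01
#' (Mann-Whitney). Accepted distinguishing genes accumulate into the output
#' set; recursion continues into subgroups of at least `min_cells` cells up
#' to `max_depth`. Deterministic given the seed.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param min_cells do not split groups smaller than this (default 10).
#' @param max_depth maximum recursion depth (default 8).
#' @param seed integer seed.
#' @param n_top overdispersed genes selected per node.
#' @param min_markers minimum significant genes for a split to be accepted.
#' @param alpha adjusted-p cutoff for "distinguishing" genes.
#' @param cells optional subset of cells to start from.
#' @return A `feature_set` of marker genes (lexicographically ordered).
#' @export
icim_select <- function(dataset, min_cells = 10, max_depth = 8, seed = 0,
                        n_top = 500, min_markers = 5, alpha = 0.01,
                        cells = NULL) {
  if (min_cells < 2) pn_parameter_error("min_cells must be >= 2")
  lc <- require_logcpm(dataset)
  if (!is.null(cells)) lc <- lc[, cells, drop = FALSE]
  if (ncol(lc) < min_cells) {
    warning("fewer than min_cells cells; returning empty feature set")
    return(feature_set(character(), "icim",
                       list(min_cells = min_cells, max_depth = max_depth)))
  }
  found <- new.env(parent = emptyenv())
  found$genes <- character()

  recurse <- function(cols, depth) {
    if (length(cols) < 2 * min_cells || depth > max_depth) return(invisible())
    sub <- lc[, cols, drop = FALSE]
    od <- local_overdispersed(sub, n_top)
    if (length(od) < 2) return(invisible())
    hx <- stats::hclust(stats::dist(t(sub[od, , drop = FALSE])), method = "ward.D2")
    split <- stats::cutree(hx, k = 2)
    if (min(table(split)) < min_cells) return(invisible())
    de <- mwu_matrix(sub[od, , drop = FALSE], split == 1, alternative = "two_sided")
    de$p_adj <- bh_adjust(de$p)
    sig <- de$gene[de$p_adj < alpha]
    if (length(sig) < min_markers) return(invisible())
    found$genes <- union(found$genes, sig)
    recurse(cols[split == 1], depth + 1)
    recurse(cols[split == 2], depth + 1)
  }
  with_seed(seed, recurse(seq_len(ncol(lc)), 1))
  feature_set(sort(found$genes), "icim",
              list(min_cells = min_cells, max_depth = max_depth,
                   n_top = n_top, min_markers = min_markers, alpha = alpha,
                   seed = seed))
}

# Dispersion ranking on a plain matrix (used inside the recursion, where the
# subset is no longer an ExpressionDataset).
local_overdispersed <- function(lc, n_top) {
  m <- rowMeans(lc)
  v <- matrixStats::rowVars(lc)
  disp <- ifelse(m > 0, v / m, 0)
  z <- rep(-Inf, nrow(lc))
  expressed <- m > 0
  if (any(expressed)) {
    r <- rank(m[expressed], ties.method = "first")
    bins <- ceiling(r / length(r) * min(20, length(r)))
    d <- disp[expressed]
    mu_b <- tapply(d, bins, mean)
    sd_b <- tapply(d, bins, stats::sd)
    sd_b[is.na(sd_b) | sd_b == 0] <- 1
    z[expressed] <- (d - mu_b[as.character(bins)]) / sd_b[as.character(bins)]
  }
  ids <- rownames(lc)
  ord <- order(-z, ids)
  ids[ord[seq_len(min(n_top, nrow(lc)))]]
}
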
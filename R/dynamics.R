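#' Union of top differentially expressed genes over all stage pairs
#'
#' Takes the top `k` two-sided Mann-Whitney genes for every unordered pair
#' of stages (6 pairs for 4 stages) and returns their union — the globally
#' dynamic gene set.
#'
#' @param dataset a normalized [ExpressionDataset()] with >= 2 stages.
#' @param k genes per stage pair (default 150).
#' @return character vector of gene ids (sorted).
#' @export
dynamic_gene_union <- function(dataset, k = 150) {
  stages <- stage_levels(dataset)
  present <- stages[stages %in% as.character(dataset$cells$stage[dataset$cells$qc_pass])]
  if (length(present) < 2) pn_validation_error("need >= 2 stages")
  out <- character()
  for (i in seq_along(present)[-length(present)])
    for (j in seq((i + 1), length(present)))
      out <- union(out, stage_pair_top_genes(dataset, present[i], present[j], k = k))
  sort(out)
}

#' Temporal profiles and profile groups of dynamic genes
#'
#' Computes each gene's median log2(CPM+1) per stage over QC-passing cells,
#' normalizes the profile by its maximum (so the highest expression is 1),
#' embeds the normalized profiles in 2-D with t-SNE, groups them by density
#' clustering, and classifies each group's trend from its mean profile:
#' `up` when the last stage exceeds the first by at least `delta` and the
#' profile is monotone within tolerance (at most one decreasing step no
#' larger than `mono_tol`), `down` symmetrically, otherwise `none`. Genes
#' left unassigned by the density clustering are treated as singleton groups
#' and classified from their own profiles. Genes whose medians are all zero
#' are excluded with a warning.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param genes gene ids to profile (e.g. from [dynamic_gene_union()]).
#' @param seed seed for the profile embedding.
#' @param delta minimum normalized first-to-last change to call a trend.
#' @param mono_tol largest tolerated backward step in a monotone profile.
#' @param min_cluster_size,min_samples density-clustering parameters for the
#'   profile grouping.
#' @return A `dynamic_gene_groups` object: a table with per-stage medians,
#'   normalized profile, group id and trend per gene.
#' @export
profile_and_group <- function(dataset, genes, seed = 0, delta = 0.2,
                              mono_tol = 0.05, min_cluster_size = 10,
                              min_samples = 5) {
  lc <- require_logcpm(dataset)
  genes <- intersect(as.character(genes), rownames(lc))
  if (length(genes) == 0) pn_validation_error("gene set is empty")
  keep <- dataset$cells$qc_pass
  stages <- stage_levels(dataset)
  med <- vapply(stages, function(s) {
    cols <- keep & as.character(dataset$cells$stage) == s
    matrixStats::rowMedians(lc[genes, cols, drop = FALSE])
  }, numeric(length(genes)))
  med <- matrix(med, nrow = length(genes), dimnames = list(genes, stages))
  allzero <- rowSums(med) == 0
  if (any(allzero)) {
    warning(sprintf("%d gene(s) with all-zero stage medians excluded", sum(allzero)))
    med <- med[!allzero, , drop = FALSE]
  }
  if (nrow(med) == 0) pn_validation_error("no genes with non-zero medians")
  norm <- med / matrixStats::rowMaxs(med)

  n <- nrow(norm)
  if (n >= 3 * min_cluster_size) {
    coords <- with_seed(seed, {
      perp <- min(30, floor((n - 1) / 3))
      Rtsne::Rtsne(norm, dims = 2, perplexity = max(2, perp),
                   check_duplicates = FALSE, pca = FALSE, verbose = FALSE,
                   num_threads = 1)$Y
    })
    groups <- hdbscan_points(coords, min_cluster_size, min_samples)
  } else groups <- rep(-1L, n)
  # unassigned profiles become singleton groups
  next_id <- if (any(groups != -1L)) max(groups) + 1L else 0L
  singleton <- groups == -1L
  groups[singleton] <- next_id + seq_len(sum(singleton)) - 1L

  trend_of <- function(profile) {
    steps <- diff(profile)
    span <- profile[length(profile)] - profile[1]
    mono_up <- sum(steps < 0) <= 1 && all(steps >= -mono_tol)
    mono_down <- sum(steps > 0) <= 1 && all(steps <= mono_tol)
    if (span >= delta && mono_up) "up"
    else if (span <= -delta && mono_down) "down"
    else "none"
  }
  group_trend <- vapply(sort(unique(groups)), function(g)
    trend_of(colMeans(norm[groups == g, , drop = FALSE])), "")
  names(group_trend) <- as.character(sort(unique(groups)))

  tab <- data.frame(gene = rownames(norm),
                    med, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[1 + seq_along(stages)] <- paste0("median_", stages)
  normdf <- as.data.frame(norm)
  names(normdf) <- paste0("norm_", stages)
  tab <- cbind(tab, normdf)
  tab$group <- groups
  tab$trend <- group_trend[as.character(groups)]
  rownames(tab) <- NULL
  structure(list(table = tab, group_trend = group_trend,
                 delta = delta, mono_tol = mono_tol),
            class = "dynamic_gene_groups")
}

#' @export
print.dynamic_gene_groups <- function(x, ...) {
  tr <- table(x$table$trend)
  cat(sprintf("dynamic_gene_groups: %d genes, %d groups\n",
              nrow(x$table), length(unique(x$table$group))))
  cat("  trends:", paste(sprintf("%s=%d", names(tr), tr), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.dynamic_gene_groups <- function(x, ...) {
  stages <- sub("^norm_", "", grep("^norm_", names(x$table), value = TRUE))
  norm <- as.matrix(x$table[, paste0("norm_", stages)])
  trends <- c(up = "firebrick", down = "steelblue", none = "grey60")
  graphics::matplot(t(norm), type = "l", lty = 1,
                    col = grDevices::adjustcolor(trends[x$table$trend], 0.35),
                    xaxt = "n", xlab = "stage", ylab = "normalized median expression", ...)
  graphics::axis(1, at = seq_along(stages), labels = stages)
  invisible(x)
}
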
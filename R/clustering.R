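#' Two-dimensional embedding of cells
#'
#' Projects cells into 2-D with t-SNE or UMAP on the log-CPM matrix
#' restricted to a feature set. Deterministic given the seed. For very small
#' or degenerate inputs (too few cells for a perplexity/neighborhood, or all
#' cells identical) the method falls back to exact PCA coordinates with a
#' warning, so minimal inputs still embed.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param features a `feature_set` (or character vector of gene ids).
#' @param method `"tsne"`, `"umap"`, or `"pca"`.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (reduced automatically when cells are
#'   few). @param n_neighbors UMAP neighborhood size.
#' @param cells optional cell subset.
#' @return A `pn_embedding`: cells x 2 coordinate matrix with attributes
#'   `method`, `seed`, `features`.
#' @export
embed_2d <- function(dataset, features, method = c("tsne", "umap", "pca"),
                     seed = 0, perplexity = 30, n_neighbors = 15, cells = NULL) {
  method <- match.arg(method)
  lc <- require_logcpm(dataset)
  if (!is.null(cells)) lc <- lc[, cells, drop = FALSE]
  features <- intersect(as.character(features), rownames(lc))
  if (length(features) == 0) pn_validation_error("feature set is empty")
  M <- t(lc[features, , drop = FALSE])
  n <- nrow(M)
  if (n < 3) pn_validation_error("need >= 3 cells to embed")
  degenerate <- all(apply(M, 2, function(col) length(unique(col)) == 1))
  if (degenerate) {
    warning("all cells identical in feature space; returning zero coordinates")
    coords <- matrix(0, n, 2, dimnames = list(rownames(M), c("dim1", "dim2")))
    return(pn_embedding(coords, "degenerate", seed, features))
  }
  used <- method
  coords <- with_seed(seed, {
    if (method == "tsne") {
      perp <- min(perplexity, floor((n - 1) / 3))
      if (perp < 2) {
        used <- "pca"
        warning("too few cells for t-SNE; falling back to PCA coordinates")
        pca_2d(M)
      } else {
        Rtsne::Rtsne(M, dims = 2, perplexity = perp, check_duplicates = FALSE,
                     pca = ncol(M) > 50, partial_pca = FALSE, verbose = FALSE,
                     num_threads = 1)$Y
      }
    } else if (method == "umap") {
      nb <- min(n_neighbors, n - 1)
      if (nb < 2 || n < 6) {
        used <- "pca"
        warning("too few cells for UMAP; falling back to PCA coordinates")
        pca_2d(M)
      } else {
        uwot::umap(M, n_neighbors = nb, n_components = 2, n_threads = 1,
                   n_sgd_threads = 0, verbose = FALSE)
      }
    } else pca_2d(M)
  })
  dimnames(coords) <- list(rownames(M), c("dim1", "dim2"))
  pn_embedding(coords, used, seed, features)
}

pca_2d <- function(M) {
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = 2)
  coords <- p$x
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  coords[, 1:2, drop = FALSE]
}

pn_embedding <- function(coords, method, seed, features) {
  structure(coords, method = method, seed = seed, features = features,
            class = c("pn_embedding", "matrix", "array"))
}

#' @export
print.pn_embedding <- function(x, ...) {
  cat(sprintf("pn_embedding (%s, seed %s): %d cells\n",
              attr(x, "method"), format(attr(x, "seed")), nrow(x)))
  invisible(x)
}

#' @export
plot.pn_embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) "grey30"
         else grDevices::hcl.colors(max(3, length(unique(labels))), "Dark 3")[
           as.integer(factor(labels))]
  graphics::plot(x[, 1], x[, 2], col = col, pch = 16, cex = 0.6,
                 xlab = "dim 1", ylab = "dim 2", ...)
  invisible(x)
}

#' Density-based clustering of an embedding
#'
#' HDBSCAN-style hierarchical density clustering on 2-D coordinates; `-1`
#' marks noise points, remaining labels are dense integers starting at 0.
#'
#' @param embedding a `pn_embedding` (or any numeric matrix of coordinates).
#' @param min_cluster_size smallest cluster size retained (>= 2).
#' @param min_samples neighborhood size for core distances.
#' @return A named integer label vector of class `cluster_assignment`.
#' @export
density_cluster <- function(embedding, min_cluster_size = 10, min_samples = 5) {
  X <- unclass(embedding)
  labels <- hdbscan_points(X, min_cluster_size, min_samples)
  names(labels) <- rownames(X)
  cluster_assignment(densify_labels(labels), "hdbscan",
                     list(min_cluster_size = min_cluster_size,
                          min_samples = min_samples))
}

#' Graph-based (Leiden) clustering in feature space
#'
#' Builds a k-nearest-neighbor graph on the log-CPM feature-space Euclidean
#' metric and partitions it with the Leiden community-detection algorithm
#' (modularity objective). Deterministic given the seed.
#'
#' @inheritParams embed_2d
#' @param resolution Leiden resolution parameter.
#' @param k neighborhood size (must be `< n_cells`).
#' @return A `cluster_assignment` (no noise label; every cell is assigned).
#' @export
graph_cluster <- function(dataset, features, resolution = 1, k = 15, seed = 0,
                          cells = NULL) {
  lc <- require_logcpm(dataset)
  if (!is.null(cells)) lc <- lc[, cells, drop = FALSE]
  features <- intersect(as.character(features), rownames(lc))
  if (length(features) == 0) pn_validation_error("feature set is empty")
  M <- t(lc[features, , drop = FALSE])
  n <- nrow(M)
  if (k >= n) pn_parameter_error("k must be smaller than the number of cells")
  nn <- FNN::get.knn(M, k = k)$nn.index
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed,
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5))$membership
  labels <- as.integer(memb) - 1L
  names(labels) <- rownames(M)
  cluster_assignment(densify_labels(labels), "leiden",
                     list(resolution = resolution, k = k, seed = seed))
}

cluster_assignment <- function(labels, method, params) {
  structure(labels, method = method, params = params,
            class = c("cluster_assignment", "integer"))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- length(unique(x[x != -1L]))
  cat(sprintf("cluster_assignment (%s): %d clusters, %d noise / %d cells\n",
              attr(x, "method"), k, sum(x == -1L), length(x)))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two clusterings of the same cells,
#' computed from the closed-form contingency-table expression.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return a number in `[-1, 1]`; 1 means identical partitions.
#' @export
agreement_ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    pn_validation_error("labelings must have the same length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(rowSums(tab)); b <- sum_comb(colSums(tab))
  idx <- sum(choose(tab, 2))
  expected <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  if (max_idx == expected) return(1)     # both partitions trivial
  (idx - expected) / (max_idx - expected)
}

#' Per-stage typing: features, embedding and clustering in one call
#'
#' Convenience wrapper running the per-stage typing used throughout the
#' pipeline: select features among the stage's cells (overdispersed by
#' default, iterative marker discovery optionally), then cluster with the
#' graph (Leiden) route or with t-SNE + density clustering.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param stage stage name.
#' @param feature_method `"overdispersed"` or `"icim"`.
#' @param cluster_method `"leiden"` or `"hdbscan"`.
#' @param config a [pipeline_config()].
#' @return list with `cells` (ids), `features`, `labels`, and for the
#'   density route the `embedding`.
#' @export
cluster_stage <- function(dataset, stage,
                          feature_method = c("overdispersed", "icim"),
                          cluster_method = c("leiden", "hdbscan"),
                          config = pipeline_config()) {
  feature_method <- match.arg(feature_method)
  cluster_method <- match.arg(cluster_method)
  sub <- subset_cells(dataset, stage = stage)
  feats <- if (feature_method == "icim")
    icim_select(sub, min_cells = config$icim_min_cells,
                max_depth = config$icim_max_depth, seed = config$seed,
                n_top = config$n_top_overdispersed,
                min_markers = config$icim_min_markers, alpha = config$alpha)
  else overdispersed_genes(sub, n_top = config$n_top_overdispersed,
                           n_bins = config$n_bins)
  if (cluster_method == "leiden") {
    labels <- graph_cluster(sub, feats, resolution = config$resolution,
                            k = config$knn_k, seed = config$seed)
    list(cells = cell_ids(sub), features = feats, labels = labels)
  } else {
    emb <- embed_2d(sub, feats, method = "tsne", seed = config$seed)
    labels <- density_cluster(emb, min_cluster_size = config$min_cluster_size,
                              min_samples = config$min_samples)
    list(cells = cell_ids(sub), features = feats, labels = labels, embedding = emb)
  }
}
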
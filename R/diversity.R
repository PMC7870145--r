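#' Cell-level transcriptomic similarity
#'
#' For each cell, the mean inverse Euclidean distance to all other cells of
#' the subset in a 2-D embedding. Coincident point pairs (distance 0) are
#' excluded from the mean with a warning and counted.
#'
#' @param embedding a `pn_embedding` (or 2-column coordinate matrix)
#'   computed over exactly the cell subset of interest.
#' @return list with `per_cell` similarities, `mean`, `sd`, and
#'   `n_zero_pairs`.
#' @export
cell_level_similarity <- function(embedding) {
  X <- unclass(embedding)
  n <- nrow(X)
  if (n < 2) pn_validation_error("need >= 2 cells")
  D <- as.matrix(stats::dist(X))
  diag(D) <- NA
  zero <- which(D == 0 & !is.na(D))
  n_zero_pairs <- length(zero) / 2
  if (n_zero_pairs > 0) {
    warning(sprintf("%d coincident point pair(s) excluded", n_zero_pairs))
    D[zero] <- NA
  }
  inv <- 1 / D
  per_cell <- rowMeans(inv, na.rm = TRUE)
  names(per_cell) <- rownames(X)
  list(per_cell = per_cell, mean = mean(per_cell), sd = stats::sd(per_cell),
       n_zero_pairs = n_zero_pairs)
}

#' Cluster-level transcriptomic similarity
#'
#' Per-cluster centroids (mean log2(CPM+1) over the cluster's cells,
#' restricted to a differential-expression gene set), Pearson correlation
#' between all centroid pairs, their mean, and a bootstrap 95% confidence
#' interval over the pairwise values. Pairs involving a constant centroid
#' are excluded with a warning.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param labels cluster labels over the dataset's cells (`-1` = noise,
#'   excluded).
#' @param de_genes non-empty character vector of genes.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed bootstrap seed.
#' @return list with `matrix` (cluster x cluster correlations), `pairs`,
#'   `mean`, `ci` and `n_clusters`.
#' @export
cluster_level_similarity <- function(dataset, labels, de_genes,
                                     n_boot = 1000, seed = 0) {
  lc <- require_logcpm(dataset)
  de_genes <- intersect(as.character(de_genes), rownames(lc))
  if (length(de_genes) == 0) pn_validation_error("de_genes is empty")
  labels <- as.integer(labels)
  clusters <- sort(unique(labels[labels != -1L]))
  if (length(clusters) < 2) pn_validation_error("need >= 2 clusters")
  cent <- vapply(clusters, function(cl)
    rowMeans(lc[de_genes, labels == cl, drop = FALSE]),
    numeric(length(de_genes)))
  colnames(cent) <- as.character(clusters)
  const <- matrixStats::colSds(cent) == 0
  if (any(const)) {
    warning(sprintf("%d constant centroid(s) excluded from correlations", sum(const)))
    cent <- cent[, !const, drop = FALSE]
  }
  if (ncol(cent) < 2) pn_validation_error("fewer than 2 usable centroids")
  M <- stats::cor(cent)
  vals <- M[upper.tri(M)]
  ci <- bootstrap_ci(vals, n_iter = n_boot, seed = seed)
  list(matrix = M, pairs = vals, mean = mean(vals), sd = stats::sd(vals),
       ci = ci, n_clusters = ncol(cent))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `n_iter` times and returns the
#' 2.5/97.5 percentiles of the resampled means. Deterministic given the
#' seed. A single value gives a degenerate interval with a warning.
#'
#' @param values numeric vector.
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @param probs the two percentile bounds.
#' @return numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_iter = 1000, seed = 0,
                         probs = c(0.025, 0.975)) {
  if (n_iter < 1) pn_parameter_error("n_iter must be >= 1")
  if (length(values) < 1) pn_validation_error("no values")
  if (length(values) == 1) {
    warning("single value: degenerate confidence interval")
    return(c(low = values, high = values))
  }
  means <- with_seed(seed, vapply(seq_len(n_iter), function(i)
    mean(sample(values, replace = TRUE)), 0))
  q <- stats::quantile(means, probs, names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Correlation matrix of types ordered by birth rank
#'
#' Runs PCA over all genes detected in the selected cells, places each
#' type's centroid in PC space, computes Pearson correlations between type
#' centroids, and orders rows/columns by birth rank.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param stage stage to analyze. @param lineage lineage (default adPN).
#' @param n_pcs number of components (default `min(20, n_types - 1)`,
#'   capped with a warning).
#' @return list with `matrix` (correlations, birth-rank order), and
#'   `birth_ranks` aligned with its rows.
#' @export
type_correlation_matrix <- function(dataset, stage, lineage = "adPN",
                                    n_pcs = NULL) {
  sub <- subset_cells(dataset, stage = stage, lineage = lineage)
  lc <- require_logcpm(sub)
  types <- sub$cells$type_label
  ranks <- sub$cells$birth_rank
  ok <- !is.na(types) & !is.na(ranks)
  type_rank <- unique(data.frame(type = types[ok], rank = ranks[ok],
                                 stringsAsFactors = FALSE))
  if (nrow(type_rank) < 3) pn_validation_error("need >= 3 types with birth ranks")
  detected <- rowSums(sub$counts[, ok, drop = FALSE]) > 0
  X <- t(lc[detected, ok, drop = FALSE])
  n_types <- nrow(type_rank)
  if (is.null(n_pcs)) n_pcs <- min(20, n_types - 1)
  if (n_pcs > n_types - 1) {
    warning("n_pcs capped at n_types - 1")
    n_pcs <- n_types - 1
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  cent <- vapply(type_rank$type, function(tp)
    colMeans(pc[types[ok] == tp, , drop = FALSE]), numeric(ncol(pc)))
  M <- stats::cor(cent)
  ord <- order(type_rank$rank)
  M <- M[ord, ord]
  dimnames(M) <- list(type_rank$type[ord], type_rank$type[ord])
  list(matrix = M, birth_ranks = type_rank$rank[ord], stage = stage,
       lineage = lineage, n_pcs = n_pcs)
}

#' Average birth-order concordance statistic
#'
#' For each type X, the earlier- or later-born group is chosen (whichever
#' holds more types; ties go to the earlier group) and must contain at least
#' `min_group` types, else X is skipped. Within the group, the Spearman rank
#' correlation is computed between similarity to X and closeness in birth
#' order (so positive values mean nearer-born types are transcriptomically
#' more similar); the statistic is the average over eligible X.
#'
#' @param corr type-by-type correlation matrix (rows ordered arbitrarily).
#' @param birth_ranks integer birth ranks aligned with `corr` rows.
#' @param min_group minimum group size (default 5).
#' @return the average Spearman rho.
#' @export
birth_order_stat <- function(corr, birth_ranks, min_group = 5) {
  k <- length(birth_ranks)
  if (nrow(corr) != k) pn_validation_error("corr and birth_ranks disagree")
  rhos <- numeric(0)
  for (i in seq_len(k)) {
    earlier <- which(birth_ranks < birth_ranks[i])
    later <- which(birth_ranks > birth_ranks[i])
    grp <- if (length(earlier) >= length(later)) earlier else later
    if (length(grp) < min_group) next
    sim <- corr[i, grp]
    dist <- abs(birth_ranks[grp] - birth_ranks[i])
    rhos <- c(rhos, stats::cor(sim, -dist, method = "spearman"))
  }
  if (length(rhos) == 0) pn_validation_error("no eligible types (group size)")
  mean(rhos)
}

#' Permutation test for birth-order covariation
#'
#' Shuffles the birth ranks uniformly `n_iter` times, recomputes the
#' average concordance statistic each time, and reports
#' `p = #(simulated > observed) / n_iter` (the strict-greater convention;
#' p can be 0). Set `add_one = TRUE` for the (k+1)/(N+1) variant.
#'
#' @inheritParams birth_order_stat
#' @param n_iter permutation iterations (default 5000).
#' @param seed integer seed.
#' @param add_one use the (k+1)/(N+1) correction instead of plain division.
#' @return A `birth_order_result` with the observed statistic, permutation
#'   distribution, and p-value.
#' @export
birth_order_permutation <- function(corr, birth_ranks, n_iter = 5000,
                                    seed = 0, min_group = 5, add_one = FALSE) {
  if (n_iter < 1) pn_parameter_error("n_iter must be >= 1")
  observed <- birth_order_stat(corr, birth_ranks, min_group)
  sims <- with_seed(seed, vapply(seq_len(n_iter), function(i)
    birth_order_stat(corr, sample(birth_ranks), min_group), 0))
  p <- if (add_one) (sum(sims > observed) + 1) / (n_iter + 1)
       else sum(sims > observed) / n_iter
  structure(list(observed = observed, permutation_stats = sims,
                 p_value = p, n_iter = n_iter,
                 eligible_types = rownames(corr), min_group = min_group),
            class = "birth_order_result")
}

#' @export
print.birth_order_result <- function(x, ...) {
  cat(sprintf("birth_order_result: observed = %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_iter))
  invisible(x)
}

#' @export
plot.birth_order_result <- function(x, ...) {
  graphics::hist(x$permutation_stats, breaks = 40, col = "grey80",
                 border = NA, main = "", xlab = "average Spearman rho", ...)
  graphics::abline(v = x$observed, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Complete-linkage dendrogram with optimal leaf ordering
#'
#' Hierarchical clustering with the farthest-point (complete-linkage)
#' criterion on Euclidean distances between profiles, with leaves ordered to
#' minimize the summed distance between successive leaves (exact dynamic
#' program over the tree). Deterministic.
#'
#' @param profiles matrix, one row per cluster/type.
#' @return list with `hclust` (the tree), `order` (optimal leaf order,
#'   row indices), `labels`, and `cost` (the minimized successive-leaf
#'   distance sum).
#' @export
dendrogram_order <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) pn_validation_error("need >= 2 profiles")
  if (is.null(rownames(profiles))) rownames(profiles) <- as.character(seq_len(n))
  D <- as.matrix(stats::dist(profiles))
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  res <- olo_order(hc, D)
  list(hclust = hc, order = res$order, labels = rownames(profiles)[res$order],
       cost = res$cost)
}

# Bar-Joseph optimal leaf ordering: dynamic program over the merge tree.
# M[[node]] is a cost matrix indexed by (leftmost leaf, rightmost leaf).
olo_order <- function(hc, D) {
  n <- nrow(D)
  leaves <- list(); M <- list(); argmin <- list()
  node_leaves <- function(id) if (id < 0) -id else leaves[[id]]
  for (v in seq_len(n - 1)) {
    a <- hc$merge[v, 1]; b <- hc$merge[v, 2]
    la <- node_leaves(a); lb <- node_leaves(b)
    leaves[[v]] <- c(la, lb)
    Ma <- if (a < 0) matrix(0, 1, 1, dimnames = list(-a, -a)) else M[[a]]
    Mb <- if (b < 0) matrix(0, 1, 1, dimnames = list(-b, -b)) else M[[b]]
    all_lv <- leaves[[v]]
    Mv <- matrix(Inf, length(all_lv), length(all_lv),
                 dimnames = list(all_lv, all_lv))
    Av <- array(NA_integer_, dim = c(length(all_lv), length(all_lv), 2),
                dimnames = list(all_lv, all_lv, NULL))
    fill <- function(left_lv, right_lv, Ml, Mr) {
      for (u in left_lv) for (w in right_lv) {
        best <- Inf; bm <- NA_integer_; bk <- NA_integer_
        for (m in left_lv) {
          cu <- Ml[as.character(u), as.character(m)]
          if (!is.finite(cu)) next
          for (kk in right_lv) {
            cw <- Mr[as.character(kk), as.character(w)]
            tot <- cu + D[m, kk] + cw
            if (tot < best) { best <- tot; bm <- m; bk <- kk }
          }
        }
        ui <- as.character(u); wi <- as.character(w)
        if (best < Mv[ui, wi]) {
          Mv[ui, wi] <<- best
          Av[ui, wi, ] <<- c(bm, bk)
        }
      }
    }
    # Mr must be indexed (inner, outer): cost of subtree with ends (k .. w).
    # Cost matrices are symmetric in reversal, so M[x, y] == M[y, x].
    fill(la, lb, Ma, Mb)
    fill(lb, la, Mb, Ma)
    M[[v]] <- Mv
    argmin[[v]] <- Av
  }
  root <- n - 1
  Mr <- M[[root]]
  idx <- which(Mr == min(Mr), arr.ind = TRUE)[1, ]
  u <- as.integer(rownames(Mr)[idx[1]]); w <- as.integer(colnames(Mr)[idx[2]])
  order_out <- olo_backtrack(root, u, w, hc, M, argmin, leaves)
  list(order = order_out, cost = min(Mr))
}

olo_backtrack <- function(node, u, w, hc, M, argmin, leaves) {
  if (node < 0) return(-node)
  a <- hc$merge[node, 1]; b <- hc$merge[node, 2]
  la <- if (a < 0) -a else leaves[[a]]
  mk <- argmin[[node]][as.character(u), as.character(w), ]
  m <- mk[1]; k <- mk[2]
  if (u %in% la) {
    left <- olo_backtrack(a, u, m, hc, M, argmin, leaves)
    right <- olo_backtrack(b, k, w, hc, M, argmin, leaves)
  } else {
    left <- olo_backtrack(b, u, m, hc, M, argmin, leaves)
    right <- olo_backtrack(a, k, w, hc, M, argmin, leaves)
  }
  c(left, right)
}

#' Stage-by-lineage transcriptomic diversity report
#'
#' Cell-level similarity (mean inverse Euclidean distance in a per
#' stage-and-lineage 2-D UMAP embedding of a feature-gene space) and
#' cluster-level similarity (mean pairwise Pearson correlation of cluster
#' centroids over a differential-expression gene set, with a bootstrap 95%
#' confidence interval), for every stage of each requested lineage.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param features feature genes for the cell-level embedding.
#' @param de_genes genes for cluster centroids (e.g. the union of the peak
#'   stage's signatures).
#' @param lineages lineages to report.
#' @param labels_fun function(subset dataset) -> cluster labels; defaults to
#'   the planted/annotated `type_label`.
#' @param n_boot,seed bootstrap controls.
#' @param embed_method embedding used for cell-level similarity.
#' @return A `diversity_report` data.frame, one row per (stage, lineage).
#' @export
transcriptomic_diversity <- function(dataset, features, de_genes,
                                     lineages = c("adPN", "lPN"),
                                     labels_fun = NULL, n_boot = 1000,
                                     seed = 0, embed_method = "umap") {
  stages <- stage_levels(dataset)
  rows <- list()
  for (lin in lineages) for (s in stages) {
    sub <- subset_cells(dataset, stage = s, lineage = lin)
    n <- ncol(sub$counts)
    if (n < 3) next
    emb <- embed_2d(sub, features, method = embed_method, seed = seed)
    cell <- cell_level_similarity(emb)
    labels <- if (is.null(labels_fun)) {
      as.integer(factor(sub$cells$type_label)) - 1L
    } else labels_fun(sub)
    clus <- tryCatch(
      cluster_level_similarity(sub, labels, de_genes, n_boot = n_boot, seed = seed),
      pnstage_validation_error = function(e) NULL)
    rows[[paste(lin, s)]] <- data.frame(
      stage = s, lineage = lin, n_cells = n,
      cell_mean = cell$mean, cell_sd = cell$sd,
      n_clusters = if (is.null(clus)) NA_integer_ else clus$n_clusters,
      cluster_mean = if (is.null(clus)) NA_real_ else clus$mean,
      cluster_ci_low = if (is.null(clus)) NA_real_ else clus$ci[1],
      cluster_ci_high = if (is.null(clus)) NA_real_ else clus$ci[2],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("diversity_report:\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
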
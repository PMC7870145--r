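#' Mann-Whitney U test
#'
#' Two-sample rank-sum test with midrank tie handling. For small samples
#' (`length(x) + length(y) <= 20`) with no ties the p-value comes from the
#' exact null distribution of U; otherwise from the normal approximation with
#' tie correction and continuity correction. The reported `U` is the
#' statistic of `x` (number of (x, y) pairs with x > y, ties counted half).
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative `"two_sided"` or `"greater"` (x tends larger than y).
#' @return list with elements `U` and `p`.
#' @export
mwu_test <- function(x, y, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) pn_validation_error("empty sample")
  if (any(!is.finite(c(x, y)))) pn_validation_error("non-finite values")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (m + n <= 20 && !ties) {
    p_ge <- 1 - stats::pwilcox(U - 1, m, n)   # P(U >= u), U integral here
    p_le <- stats::pwilcox(U, m, n)
    p <- switch(alternative,
                greater = p_ge,
                two_sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    N <- m + n
    tie_lengths <- rle(sort(c(x, y)))$lengths
    tie_term <- sum(tie_lengths^3 - tie_lengths)
    mu <- m * n / 2
    sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      if (alternative == "greater") {
        z <- (U - mu - 0.5) / sigma
        p <- stats::pnorm(z, lower.tail = FALSE)
      } else {
        z <- (U - mu - sign(U - mu) * 0.5) / sigma
        p <- min(1, 2 * stats::pnorm(-abs(z)))
      }
    }
  }
  list(U = U, p = p)
}

# Vectorized one-vs-rest Mann-Whitney over the rows of a genes x cells
# matrix, using the normal approximation with tie and continuity correction
# (the same approximate branch as mwu_test; genome-wide expression data
# always carry ties, so the exact branch never applies there).
# `grp` is a logical vector over columns: the "in" group.
mwu_matrix <- function(X, grp, alternative = c("two_sided", "greater"),
                       ranks = NULL, tie_term = NULL) {
  alternative <- match.arg(alternative)
  m <- sum(grp); n <- sum(!grp); N <- m + n
  if (m < 1 || n < 1) pn_validation_error("empty group")
  if (is.null(ranks)) ranks <- row_ranks_ties(X)$ranks
  if (is.null(tie_term)) tie_term <- row_ranks_ties(X)$tie_term
  U <- rowSums(ranks[, grp, drop = FALSE]) - m * (m + 1) / 2
  mu <- m * n / 2
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  p <- rep(1, nrow(X))
  ok <- sigma > 0
  if (alternative == "greater") {
    z <- (U[ok] - mu - 0.5) / sigma[ok]
    p[ok] <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    z <- (U[ok] - mu - sign(U[ok] - mu) * 0.5) / sigma[ok]
    p[ok] <- pmin(1, 2 * stats::pnorm(-abs(z)))
  }
  mean_in <- rowMeans(X[, grp, drop = FALSE])
  mean_out <- rowMeans(X[, !grp, drop = FALSE])
  data.frame(gene = rownames(X) %||% as.character(seq_len(nrow(X))),
             U = U, p = p, mean_in = mean_in, mean_out = mean_out,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Midranks per row plus the per-row tie correction term sum(t^3 - t).
row_ranks_ties <- function(X) {
  ranks <- matrixStats::rowRanks(X, ties.method = "average")
  tie_term <- apply(X, 1, function(v) {
    len <- rle(sort.int(v, method = "quick"))$lengths
    sum(len^3) - length(v)
  })
  list(ranks = ranks, tie_term = tie_term)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped at 1, aligned with the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    pn_validation_error("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' One-vs-rest cluster signatures
#'
#' For each non-noise cluster, every gene is tested one-vs-rest with a
#' one-sided (greater) Mann-Whitney U test, p-values are BH-adjusted within
#' that cluster's test family, and genes with adjusted p strictly below
#' `alpha` form the cluster's signature — the unit compared across stages
#' during matching.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param labels integer cluster labels (one per cell of `dataset`, `-1` =
#'   noise), e.g. from [density_cluster()] or [graph_cluster()].
#' @param alpha adjusted-p cutoff (strict `<`), default 0.01.
#' @param alternative test sidedness; signatures use `"greater"`.
#' @param stage optional stage tag recorded in the result.
#' @return A `signature_set`: list of per-cluster ordered gene vectors, the
#'   full test table, alpha, and low-power flags for clusters under 3 cells.
#' @export
cluster_signatures <- function(dataset, labels, alpha = 0.01,
                               alternative = "greater", stage = NA) {
  lc <- require_logcpm(dataset)
  labels <- as.integer(labels)
  if (length(labels) != ncol(lc)) pn_validation_error("labels length != number of cells")
  clusters <- sort(unique(labels[labels != -1L]))
  if (length(clusters) < 2) pn_validation_error("need >= 2 non-noise clusters")
  keep <- labels != -1L
  lc_k <- lc[, keep, drop = FALSE]
  lab_k <- labels[keep]
  rt <- row_ranks_ties(lc_k)
  tabs <- list(); sigs <- list(); low_power <- character()
  for (cl in clusters) {
    grp <- lab_k == cl
    if (sum(grp) < 3) low_power <- c(low_power, as.character(cl))
    de <- mwu_matrix(lc_k, grp, alternative = alternative,
                     ranks = rt$ranks, tie_term = rt$tie_term)
    de$p_adj <- bh_adjust(de$p)
    de$direction <- ifelse(de$mean_in > de$mean_out, "up", "down")
    de$cluster <- cl
    sig <- de[de$p_adj < alpha & de$direction == "up", ]
    sig <- sig[order(sig$p_adj, sig$p, sig$gene), ]
    sigs[[as.character(cl)]] <- sig$gene
    tabs[[as.character(cl)]] <- de[, c("cluster", "gene", "U", "p", "p_adj",
                                       "direction", "mean_in", "mean_out")]
  }
  structure(list(signatures = sigs, table = do.call(rbind, c(tabs, make.row.names = FALSE)),
                 alpha = alpha, stage = stage, low_power = low_power),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set (alpha < %g%s): %d clusters\n", x$alpha,
              if (!is.na(x$stage)) paste0(", stage ", x$stage) else "",
              length(x$signatures)))
  sizes <- vapply(x$signatures, length, 0L)
  cat("  signature sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = " "), "\n")
  if (length(x$low_power)) cat("  low-power clusters (<3 cells):",
                               paste(x$low_power, collapse = ", "), "\n")
  invisible(x)
}

#' Top differentially expressed genes between two stages
#'
#' Genes ranked by two-sided Mann-Whitney p (ascending; ties by absolute
#' mean log-CPM difference descending, then gene id), top `k` returned.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param stage_a,stage_b distinct stage names.
#' @param k number of genes (default 150 per stage pair).
#' @return character vector of gene ids, best first.
#' @export
stage_pair_top_genes <- function(dataset, stage_a, stage_b, k = 150) {
  if (identical(stage_a, stage_b)) pn_validation_error("stage_a and stage_b must differ")
  if (k < 1) pn_parameter_error("k must be >= 1")
  lc <- require_logcpm(dataset)
  st <- as.character(dataset$cells$stage)
  keep <- dataset$cells$qc_pass & st %in% c(stage_a, stage_b)
  if (!any(st[keep] == stage_a) || !any(st[keep] == stage_b))
    pn_validation_error("both stages must have cells")
  sub <- lc[, keep, drop = FALSE]
  de <- mwu_matrix(sub, st[keep] == stage_a, alternative = "two_sided")
  if (k > nrow(de)) {
    warning("k exceeds number of genes; returning all")
    k <- nrow(de)
  }
  ord <- order(de$p, -abs(de$mean_in - de$mean_out), de$gene)
  de$gene[ord[seq_len(k)]]
}
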
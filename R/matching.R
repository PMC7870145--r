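#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`. When both sets are empty the index is
#' defined as 0 with a warning (a 0/0 match would otherwise look perfect).
#'
#' @param a,b character vectors (gene sets).
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) {
    warning("jaccard of two empty sets defined as 0")
    return(0)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Match clusters across two stages by signature similarity
#'
#' Computes the full Jaccard similarity matrix between the per-cluster
#' signature gene sets of two stages. A cluster pair that are mutually each
#' other's most similar cluster is a `two_way` (reciprocal best) match; a
#' one-directional best hit is `one_way_ab` (a's best is b) or `one_way_ba`.
#' Ties at the maximum yield no match in the tied direction. Clusters with
#' empty signatures are excluded and reported.
#'
#' @param sig_a,sig_b `signature_set`s of the two stages (see
#'   [cluster_signatures()]); vPN/APL clusters should be excluded upstream
#'   when matching excitatory types.
#' @return A `match_result`: data.frame of pairs with Jaccard score and
#'   match class, plus the full similarity matrix.
#' @export
signature_match <- function(sig_a, sig_b) {
  sa <- sig_a$signatures; sb <- sig_b$signatures
  empty_a <- names(sa)[vapply(sa, length, 0L) == 0]
  empty_b <- names(sb)[vapply(sb, length, 0L) == 0]
  sa <- sa[vapply(sa, length, 0L) > 0]
  sb <- sb[vapply(sb, length, 0L) > 0]
  if (length(sa) == 0 || length(sb) == 0)
    pn_validation_error("each stage needs >= 1 cluster with a non-empty signature")
  M <- matrix(0, length(sa), length(sb), dimnames = list(names(sa), names(sb)))
  for (i in seq_along(sa)) for (j in seq_along(sb))
    M[i, j] <- jaccard(sa[[i]], sb[[j]])

  best_of_row <- apply(M, 1, best_unique)
  best_of_col <- apply(M, 2, best_unique)
  pairs <- list()
  for (i in seq_len(nrow(M))) {
    j <- best_of_row[i]
    if (is.na(j)) next
    cls <- if (!is.na(best_of_col[j]) && best_of_col[j] == i) "two_way" else "one_way_ab"
    pairs[[length(pairs) + 1]] <- data.frame(
      cluster_a = rownames(M)[i], cluster_b = colnames(M)[j],
      jaccard = M[i, j], match_class = cls, stringsAsFactors = FALSE)
  }
  for (j in seq_len(ncol(M))) {
    i <- best_of_col[j]
    if (is.na(i)) next
    if (!is.na(best_of_row[i]) && best_of_row[i] == j) next  # two_way already listed
    pairs[[length(pairs) + 1]] <- data.frame(
      cluster_a = rownames(M)[i], cluster_b = colnames(M)[j],
      jaccard = M[i, j], match_class = "one_way_ba", stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(cluster_a = character(), cluster_b = character(),
                           jaccard = numeric(), match_class = character(),
                           stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$cluster_a, pairs$cluster_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, jaccard_matrix = M,
                 stage_a = sig_a$stage, stage_b = sig_b$stage,
                 excluded_a = empty_a, excluded_b = empty_b),
            class = "match_result")
}

# Index of the strict maximum of v, NA when the maximum is tied.
best_unique <- function(v) {
  mx <- max(v)
  hits <- which(v == mx)
  if (length(hits) == 1) hits else NA_integer_
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result %s vs %s: %d two-way, %d one-way\n",
              format(x$stage_a), format(x$stage_b),
              sum(x$pairs$match_class == "two_way"),
              sum(x$pairs$match_class != "two_way")))
  print(x$pairs)
  invisible(x)
}

#' @export
plot.match_result <- function(x, ...) {
  M <- x$jaccard_matrix
  graphics::image(seq_len(ncol(M)), seq_len(nrow(M)), t(M)[, rev(seq_len(nrow(M))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = format(x$stage_b), ylab = format(x$stage_a), axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(M)), colnames(M))
  graphics::axis(2, rev(seq_len(nrow(M))), rownames(M), las = 2)
  invisible(x)
}

#' Match clusters across stages by unique markers
#'
#' A gene is "expressed" in a cluster when at least `frac_threshold` of the
#' cluster's cells have log2(CPM+1) >= `expr_threshold`. For each stage the
#' search looks for genes — and, where no single gene works, two-gene
#' conjunctions — expressed in exactly one cluster. A marker unique at both
#' stages whose selected clusters share a lineage matches those clusters.
#' Candidate genes are restricted to each cluster's signature set (capped at
#' `max_pair_search` genes per cluster).
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param labels_by_stage named list: stage -> cluster labels for the
#'   stage's QC-passing cells (in `subset_cells()` order).
#' @param signatures_by_stage named list: stage -> `signature_set`.
#' @param expr_threshold,frac_threshold,max_pair_search see above.
#' @return A `marker_match`: per stage pair the marker-matched cluster
#'   pairs, plus per-stage unique-marker tables and unmatched clusters.
#' @export
marker_match <- function(dataset, labels_by_stage, signatures_by_stage,
                         expr_threshold = 2, frac_threshold = 0.5,
                         max_pair_search = 200) {
  lc <- require_logcpm(dataset)
  stages <- names(labels_by_stage)
  per_stage <- lapply(stages, function(s) {
    sub <- subset_cells(dataset, stage = s)
    labels <- as.integer(labels_by_stage[[s]])
    clusters <- sort(unique(labels[labels != -1L]))
    sigs <- signatures_by_stage[[s]]$signatures
    cand <- sort(unique(unlist(lapply(sigs, utils::head, max_pair_search))))
    cand <- intersect(cand, rownames(lc))
    # expressed[cluster, gene]: fraction of cells over threshold >= frac
    expr <- t(vapply(clusters, function(cl) {
      cols <- cell_ids(sub)[labels == cl]
      rowMeans(lc[cand, cols, drop = FALSE] >= expr_threshold) >= frac_threshold
    }, logical(length(cand))))
    dimnames(expr) <- list(as.character(clusters), cand)
    lineage <- vapply(clusters, function(cl)
      majority(sub$cells$lineage[labels == cl]), "")
    names(lineage) <- as.character(clusters)
    list(clusters = clusters, expr = expr, lineage = lineage)
  })
  names(per_stage) <- stages

  unique_markers <- lapply(per_stage, function(ps) {
    out <- list()
    n_on <- colSums(ps$expr)
    # single genes expressed in exactly one cluster
    for (g in colnames(ps$expr)[n_on == 1]) {
      cl <- rownames(ps$expr)[ps$expr[, g]]
      out[[g]] <- cl
    }
    # two-gene conjunctions among genes expressed in >= 1 cluster
    genes2 <- colnames(ps$expr)[n_on >= 1]
    if (length(genes2) >= 2) {
      for (i in seq_len(length(genes2) - 1)) for (j in seq((i + 1), length(genes2))) {
        both <- ps$expr[, genes2[i]] & ps$expr[, genes2[j]]
        if (sum(both) == 1) {
          key <- paste(genes2[i], genes2[j], sep = "+")
          out[[key]] <- rownames(ps$expr)[both]
        }
      }
    }
    out
  })

  pairs <- list()
  for (i in seq_len(length(stages) - 1)) {
    sa <- stages[i]; sb <- stages[i + 1]
    ma <- unique_markers[[sa]]; mb <- unique_markers[[sb]]
    shared <- intersect(names(ma), names(mb))
    for (mk in shared) {
      ca <- ma[[mk]]; cb <- mb[[mk]]
      lin_ok <- per_stage[[sa]]$lineage[ca] == per_stage[[sb]]$lineage[cb]
      pairs[[length(pairs) + 1]] <- data.frame(
        stage_a = sa, stage_b = sb, cluster_a = ca, cluster_b = cb,
        marker = mk, lineage_consistent = lin_ok, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(stage_a = character(), stage_b = character(),
                           cluster_a = character(), cluster_b = character(),
                           marker = character(), lineage_consistent = logical(),
                           stringsAsFactors = FALSE)
  matched <- pairs[pairs$lineage_consistent, , drop = FALSE]
  unmatched <- lapply(stages, function(s) {
    cl <- as.character(per_stage[[s]]$clusters)
    setdiff(cl, c(matched$cluster_a[matched$stage_a == s],
                  matched$cluster_b[matched$stage_b == s]))
  })
  names(unmatched) <- stages
  structure(list(pairs = pairs, unique_markers = unique_markers,
                 unmatched = unmatched,
                 params = list(expr_threshold = expr_threshold,
                               frac_threshold = frac_threshold,
                               max_pair_search = max_pair_search)),
            class = "marker_match")
}

majority <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

#' @export
print.marker_match <- function(x, ...) {
  cat(sprintf("marker_match: %d marker-supported cluster pairs (%d lineage-consistent)\n",
              nrow(x$pairs), sum(x$pairs$lineage_consistent)))
  invisible(x)
}
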
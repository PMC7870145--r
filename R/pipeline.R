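#' Cross-stage typing and matching pipeline
#'
#' Runs the standard cross-stage analysis: select features among the
#' peak-stage cells (the stage with the most type-distinguishing
#' information), type every stage by t-SNE + density clustering in that
#' shared feature space, compute one-vs-rest signature sets per stage for
#' excitatory clusters (vPN/APL clusters are excluded from matching), and
#' match clusters between adjacent stages by reciprocal-best Jaccard
#' similarity of their signatures.
#'
#' @param dataset a normalized [ExpressionDataset()].
#' @param peak_stage stage whose cells define the feature space.
#' @param lineages lineages whose clusters enter signature matching.
#' @param feature_method `"de"` (default: the union of one-vs-rest signature
#'   genes of the peak stage's own clusters, the most type-informative space
#'   for every stage), `"overdispersed"`, or `"icim"`.
#' @param de_top signature genes kept per peak cluster for the `"de"` route.
#' @param config a [pipeline_config()].
#' @return list with `features`, per-stage `labels` (cluster assignments over
#'   the stage's QC-passing cells), per-stage `signatures`, and `matches`
#'   (one `match_result` per adjacent stage pair).
#' @export
match_pipeline <- function(dataset, peak_stage = "P24",
                           lineages = c("adPN", "lPN"),
                           feature_method = c("de", "overdispersed", "icim"),
                           de_top = 50, config = pipeline_config()) {
  feature_method <- match.arg(feature_method)
  stages <- stage_levels(dataset)
  peak <- subset_cells(dataset, stage = peak_stage)
  features <- switch(feature_method,
    de = {
      res <- cluster_stage(dataset, peak_stage, "overdispersed", "hdbscan", config)
      keep <- res$labels != -1L
      sig <- cluster_signatures(peak[, which(keep)], res$labels[keep],
                                alpha = config$alpha, stage = peak_stage)
      feature_set(sort(unique(unlist(lapply(sig$signatures, utils::head, de_top)))),
                  "de", list(peak_stage = peak_stage, de_top = de_top))
    },
    icim = icim_select(peak, min_cells = config$icim_min_cells,
                       max_depth = config$icim_max_depth, seed = config$seed,
                       n_top = config$n_top_overdispersed,
                       min_markers = config$icim_min_markers, alpha = config$alpha),
    overdispersed = overdispersed_genes(peak, n_top = config$n_top_overdispersed,
                                        n_bins = config$n_bins))
  labels <- list(); signatures <- list()
  for (s in stages) {
    sub <- subset_cells(dataset, stage = s)
    emb <- embed_2d(sub, features, method = "tsne", seed = config$seed)
    lb <- density_cluster(emb, min_cluster_size = config$min_cluster_size,
                          min_samples = config$min_samples)
    labels[[s]] <- lb
    keep <- sub$cells$lineage %in% lineages & lb != -1L
    if (length(unique(lb[keep])) >= 2) {
      signatures[[s]] <- cluster_signatures(sub[, which(keep)], lb[keep],
                                            alpha = config$alpha, stage = s)
    }
  }
  matches <- list()
  for (i in seq_len(length(stages) - 1)) {
    a <- stages[i]; b <- stages[i + 1]
    if (!is.null(signatures[[a]]) && !is.null(signatures[[b]]))
      matches[[paste(a, b, sep = "-")]] <- signature_match(signatures[[a]],
                                                           signatures[[b]])
  }
  list(features = features, labels = labels, signatures = signatures,
       matches = matches)
}
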
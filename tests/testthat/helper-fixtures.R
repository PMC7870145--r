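# Shared fixtures, all generated in code at test time.

# Small generator configurations. "tiny" keeps only a handful of types so the
# planted structure fits in few genes; "typing" is the scale used for
# clustering/matching checks (all 29 types, fewer cells and genes than the
# full default so the suite stays fast).
tiny_config <- function(seed, cells_per_type_per_stage = 12, ...) {
  sim_config(seed = seed, n_genes = 600,
             lineage_spec = c(adPN = 4, lPN = 3, vPN = 1, APL = 1),
             cells_per_type_per_stage = cells_per_type_per_stage, ...)
}

typing_config <- function(seed, ...) {
  sim_config(seed = seed, n_genes = 2000, cells_per_type_per_stage = 20, ...)
}

# A 4-gene x 4-cell handmade dataset with a 2-gene neuronal panel.
toy_dataset <- function() {
  counts <- matrix(c(
    900, 500, 0, 10,
    90,  500, 0, 10,
    5,   0,   0, 800,
    5,   0,   0, 180), nrow = 4, byrow = TRUE,
    dimnames = list(c("elav", "nSyb", "gA", "gB"),
                    c("c1", "c2", "c3", "c4")))
  genes <- data.frame(gene_id = rownames(counts),
                      is_neuronal_marker = c(TRUE, TRUE, FALSE, FALSE))
  cells <- data.frame(cell_id = colnames(counts),
                      stage = c("P0", "P0", "P24", "P24"),
                      total_reads = colSums(counts))
  ExpressionDataset(counts, cells = cells, genes = genes)
}

# Random small count matrix for round-trip properties.
random_counts <- function(seed, max_dim = 6) {
  set.seed(seed)
  g <- sample(1:max_dim, 1); c <- sample(1:max_dim, 1)
  matrix(rpois(g * c, lambda = 3), g, c,
         dimnames = list(sprintf("g%d", seq_len(g)), sprintf("c%d", seq_len(c))))
}

# Deterministic typing of one stage: peak-stage features + tSNE + HDBSCAN.
type_stage <- function(ds, stage, feats, seed = 0) {
  sub <- subset_cells(ds, stage = stage)
  emb <- embed_2d(sub, feats, method = "tsne", seed = seed)
  list(sub = sub, labels = density_cluster(emb, 10, 5), embedding = emb)
}

# Majority planted type per cluster.
cluster_type_map <- function(truth, cells, labels) {
  tt <- truth$cells$type_label[match(cells, truth$cells$cell_id)]
  keep <- labels != -1L
  tapply(tt[keep], as.integer(labels[keep]),
         function(v) names(sort(table(v), decreasing = TRUE))[1])
}
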
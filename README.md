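# pnstage

Stage-resolved single-cell transcriptomic typing of *Drosophila* olfactory
projection neurons (PNs).

Developing neurons change their transcriptomes so much between pupal stages
and adulthood that clusters found at one timepoint cannot be assumed to be
the same cell types as clusters found at another. `pnstage` implements the
complete statistical workflow for this setting, for anyone analyzing
multi-timepoint SMART-seq-style single-cell data of a lineage-structured
neuronal population:

* **QC + normalization** — remove cells with < 100,000 reads, rescale to
  CPM, work in log2(CPM+1), keep cells with ≥ 8 log2(CPM+1) in ≥ 2/6
  canonical neuronal markers (*elav, brp, Syt1, nSyb, CadN, mCD8-GFP*).
* **Feature selection** — overdispersed genes (binned variance/mean
  z-score) and an iterative marker-discovery scheme (recursive Ward
  bipartition accepting splits with ≥ 5 BH-significant genes).
* **Per-stage clustering** — t-SNE + an HDBSCAN-style density clusterer
  (implemented from first principles), and Leiden on a kNN graph as an
  independent route; adjusted Rand index utilities.
* **Differential expression** — one-vs-rest Mann–Whitney U (exact for
  small samples, tie/continuity-corrected approximation genome-wide),
  Benjamini–Hochberg adjustment, per-cluster signature sets at adjusted
  p < 0.01, and top-150 rankings between stage pairs.
* **Cross-stage matching** — reciprocal-best Jaccard matching of cluster
  signature sets between adjacent stages
  (`J(A,B) = |A ∩ B| / |A ∪ B|`; mutual argmax ⇒ two-way match), plus
  manual-style matching via genes or two-gene combinations uniquely
  expressed in one cluster per stage.
* **Transcriptomic diversity** — cell-level mean inverse Euclidean distance
  in a 2-D UMAP per stage/lineage, and cluster-level mean pairwise Pearson
  correlation of centroids with bootstrap 95% CIs.
* **Birth-order covariation** — for each type *X*, the Spearman correlation
  between similarity-to-*X* and closeness in birth order within the larger
  earlier/later group (≥ 5 types); the average over types is tested by
  shuffling birth ranks (p = #(sim > obs)/N).
* **Dynamic genes** — union of top-150 stage-pair genes, max-normalized
  median profiles, density-grouped, trends classified up/down/none.
* **Synthetic data** — a negative-binomial generator with planted types,
  markers, stage programs, a pruning module, birth-order gradients and
  neurotransmitter programs, so the whole pipeline is testable end to end
  without any downloads.

## Worked example

```r
library(pnstage)

sim <- simulate_pn(sim_config(seed = 1, n_genes = 2000, cells_per_type_per_stage = 20))
ds  <- preprocess(sim$dataset, source = "colsums")
ds
#> ExpressionDataset: 2000 genes x 2255 cells
#>   layers: counts, cpm, logcpm
#>   stages: P0=561 P24=562 P48=562 Adult=570
#>   lineages: adPN=1163 APL=78 lPN=782 vPN=232
#>   qc_pass: 2255/2255 cells
qc_summary(ds)
#>              rule n_in n_removed n_out
#> 1       min_reads 2320        65  2255
#> 2 neuronal_marker 2255         0  2255
```

65 of 2320 simulated cells fell below the 100,000-read cutoff (the planted
log-normal library tail); all survivors pass the neuronal panel.

```r
res <- match_pipeline(ds, config = pipeline_config(seed = 1))
res$labels$P24
#> cluster_assignment (hdbscan): 29 clusters, 0 noise / 562 cells
res$matches[["P24-P48"]]$pairs[1:5, ]
#>   cluster_a cluster_b   jaccard match_class
#> 1         1         1 1.0000000     two_way
#> 2        11         3 0.9090909     two_way
#> 3        12        26 0.6666667     two_way
#> 4        13         9 1.0000000     two_way
#> 5        14        10 0.9090909     two_way
```

All 29 planted types are resolved at the peak stage, and adjacent-stage
clusters pair up as reciprocal best hits with high Jaccard similarity of
their signature gene sets.

```r
tc <- type_correlation_matrix(ds, stage = "P0", lineage = "adPN")
birth_order_permutation(tc$matrix, tc$birth_ranks, n_iter = 1000, seed = 1)
#> birth_order_result: observed = 0.6739, p = 0 (1000 permutations)

dg <- profile_and_group(ds, dynamic_gene_union(ds, k = 150), seed = 1)
dg
#> dynamic_gene_groups: 215 genes, 4 groups
#>   trends: down=150 up=65
```

At the first stage, transcriptomic similarity of adPN types tracks their
birth order (average Spearman rho 0.67, none of 1000 shuffles exceeded it);
the globally dynamic gene set recovers the planted 150 downregulated and 60
upregulated program genes with monotone trends.

A thin command-line front end over the same functions lives in
`inst/scripts/pn-pipeline.R` (subcommands `simulate`, `qc`, `features`,
`cluster`, `de`, `match`, `diversity`, `birthorder`, `dynamics`, `report`;
global `--config`, `--seed`, `--log-level`); outputs are byte-identical
across runs with the same config and seed.

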
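#' Configuration for the synthetic projection-neuron generator
#'
#' Describes a four-stage, multi-lineage population of olfactory projection
#' neurons with planted transcriptomic structure: per-type marker genes whose
#' separability peaks at the second stage, globally monotone up/down stage
#' programs, a pruning module elevated in embryonic-born adPN types at the
#' first stage only, birth-order expression gradients that decay across
#' development, and neurotransmitter programs separating excitatory from
#' inhibitory populations most strongly in adults. Counts are drawn gene-wise
#' from a negative binomial whose mean is the per-cell library size times the
#' softmax-normalized expected expression.
#'
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param n_genes number of genes.
#' @param stages ordered stage names.
#' @param lineage_spec named integer vector: number of types per lineage.
#' @param cells_per_type_per_stage cells simulated per (type, stage).
#' @param baseline_meanlog2,baseline_sdlog2 normal parameters of per-gene
#'   baseline expression on the log2 scale (a log-normal baseline).
#' @param library_meanlog,library_sdlog log-normal parameters of per-cell
#'   library size (reads).
#' @param markers_per_type private marker genes planted per type.
#' @param marker_lfc log2 fold elevation of a marker in its own type.
#' @param markers_onoff_per_type how many of the markers are on/off identity
#'   genes (near-silent outside their own type, expressed in it at every
#'   stage with a damped square-root schedule); the remainder are graded
#'   markers following the schedule in full.
#' @param marker_off_log2 baseline log2 expression of on/off markers outside
#'   their own type.
#' @param type_effect_schedule per-stage multiplier on `marker_lfc`; the
#'   default peaks at the second stage.
#' @param n_stage_down,n_down_profiles,n_stage_up,n_up_profiles monotone
#'   stage-program gene counts and sub-profile counts.
#' @param stage_program_span log2 range of the stage programs.
#' @param embryonic_frac fraction of adPN types marked embryonic-born (the
#'   earliest birth ranks).
#' @param n_pruning,pruning_lfc pruning-module size and log2 elevation in
#'   embryonic-born adPN cells at the first stage only.
#' @param n_gradient,gradient_slope,gradient_attenuation birth-order gradient
#'   genes: expression changes by `gradient_slope` log2 units per birth rank
#'   in adPNs, scaled per stage by the attenuation schedule (zero from the
#'   third stage on).
#' @param nt_genes_per_class,nt_lfc,nt_schedule neurotransmitter-program
#'   genes per class (cholinergic excitatory, glutamatergic vPN, GABAergic
#'   APL), their log2 elevation, and its per-stage multiplier (amplified at
#'   the last stage).
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @return A classed list of generator parameters.
#' @export
sim_config <- function(seed = 0, n_genes = 5000,
                       stages = c("P0", "P24", "P48", "Adult"),
                       lineage_spec = c(adPN = 15, lPN = 10, vPN = 3, APL = 1),
                       cells_per_type_per_stage = 30,
                       baseline_meanlog2 = 3, baseline_sdlog2 = 2.2,
                       library_meanlog = log(5e5), library_sdlog = 0.8,
                       markers_per_type = 10, marker_lfc = 3.5,
                       markers_onoff_per_type = 4, marker_off_log2 = -2,
                       type_effect_schedule = c(0.6, 1.0, 0.8, 0.5),
                       n_stage_down = 150, n_down_profiles = 5,
                       n_stage_up = 60, n_up_profiles = 2,
                       stage_program_span = 2.5,
                       embryonic_frac = 0.3,
                       n_pruning = 20, pruning_lfc = 2,
                       n_gradient = 15, gradient_slope = 0.2,
                       gradient_attenuation = c(1, 0.45, 0, 0),
                       nt_genes_per_class = 5, nt_lfc = 1.5,
                       nt_schedule = c(1, 1, 1, 2.5),
                       dispersion = 0.15) {
  cfg <- as.list(environment())
  n_stages <- length(stages)
  for (nm in c("type_effect_schedule", "gradient_attenuation", "nt_schedule"))
    if (length(cfg[[nm]]) != n_stages)
      pn_parameter_error(sprintf("%s must have one entry per stage", nm))
  if (any(unlist(lineage_spec) < 1) || cells_per_type_per_stage < 1 || n_genes < 1)
    pn_parameter_error("counts in sim_config must be positive")
  if (!all(is.finite(c(marker_lfc, stage_program_span, pruning_lfc,
                       gradient_slope, nt_lfc))))
    pn_parameter_error("fold-changes must be finite")
  structure(cfg, class = "sim_config")
}

# Type table: one row per planted type, persistent across stages.
sim_type_table <- function(cfg) {
  rows <- list()
  for (lin in names(cfg$lineage_spec)) {
    k <- cfg$lineage_spec[[lin]]
    ranked <- lin %in% c("adPN", "lPN")
    n_emb <- if (lin == "adPN") ceiling(cfg$embryonic_frac * k) else 0L
    rows[[lin]] <- data.frame(
      type_label = sprintf("%s_T%02d", lin, seq_len(k)),
      lineage = lin,
      birth_rank = if (ranked) seq_len(k) else NA_integer_,
      embryonic = if (lin == "adPN") seq_len(k) <= n_emb else FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Monotone sub-profile shapes on [0, 1], one row per group; convexity varies
# across groups so the dynamics module sees distinguishable profile families.
sim_profile_shapes <- function(n_profiles, n_stages, direction) {
  s <- seq(0, 1, length.out = n_stages)
  shapes <- lapply(seq_len(n_profiles), function(i) {
    v <- (1 - s)^(0.5 + 1.5 * (i - 1) / max(1, n_profiles - 1))
    if (direction == "up") v <- 1 - v
    v
  })
  do.call(rbind, shapes)
}

#' Simulate a stage-resolved projection-neuron count dataset
#'
#' @param config a [sim_config()].
#' @return A list with elements `dataset` (an [ExpressionDataset()] with raw
#'   counts and full cell/gene annotations) and `truth` (a `pn_ground_truth`
#'   object: planted cell identities, gene roles with effect sizes, and the
#'   cross-stage type identity map).
#' @export
simulate_pn <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    types <- sim_type_table(cfg)
    n_types <- nrow(types)
    n_stages <- length(cfg$stages)

    # ---- gene roles ------------------------------------------------------
    panel <- c("elav", "brp", "Syt1", "nSyb", "CadN", "mCD8-GFP")
    n_special <- length(panel) + n_types * cfg$markers_per_type +
      cfg$n_stage_down + cfg$n_stage_up + cfg$n_pruning + cfg$n_gradient +
      3 * cfg$nt_genes_per_class
    if (cfg$n_genes < n_special)
      pn_parameter_error("n_genes too small for the requested planted structure")

    gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    gene_id[seq_along(panel)] <- panel
    role <- rep("housekeeping", cfg$n_genes)
    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_meanlog2, cfg$baseline_sdlog2)
    baseline[seq_along(panel)] <- 9      # neuronal panel: high in every cell

    idx <- length(panel)
    take <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; out }

    marker_idx <- matrix(take(n_types * cfg$markers_per_type),
                         nrow = cfg$markers_per_type)
    onoff <- seq_len(cfg$markers_onoff_per_type)        # rows of marker_idx
    for (t in seq_len(n_types)) {
      role[marker_idx[, t]] <- paste0("marker:", types$type_label[t])
      # mixed marker panel: a few on/off identity markers (near-silent
      # outside their type, stable across stages) plus graded markers whose
      # contrast follows the per-stage schedule
      baseline[marker_idx[onoff, t]] <- stats::rnorm(length(onoff),
                                                     cfg$marker_off_log2, 0.75)
      baseline[marker_idx[-onoff, t]] <- stats::rnorm(cfg$markers_per_type - length(onoff), 2, 1)
    }
    down_idx <- take(cfg$n_stage_down)
    up_idx <- take(cfg$n_stage_up)
    role[down_idx] <- "stage_down"; role[up_idx] <- "stage_up"
    baseline[down_idx] <- stats::rnorm(cfg$n_stage_down, 2, 1)
    baseline[up_idx] <- stats::rnorm(cfg$n_stage_up, 2, 1)
    down_group <- rep(seq_len(cfg$n_down_profiles), length.out = cfg$n_stage_down)
    up_group <- rep(seq_len(cfg$n_up_profiles), length.out = cfg$n_stage_up)
    down_shapes <- sim_profile_shapes(cfg$n_down_profiles, n_stages, "down")
    up_shapes <- sim_profile_shapes(cfg$n_up_profiles, n_stages, "up")

    pruning_idx <- take(cfg$n_pruning)
    role[pruning_idx] <- "pruning"
    baseline[pruning_idx] <- stats::rnorm(cfg$n_pruning, 2, 1)

    gradient_idx <- take(cfg$n_gradient)
    role[gradient_idx] <- "gradient"
    baseline[gradient_idx] <- stats::rnorm(cfg$n_gradient, 3, 1)
    gradient_sign <- rep(c(1, -1), length.out = cfg$n_gradient)

    nt_class <- c("ach", "glut", "gaba")
    nt_lineages <- list(ach = c("adPN", "lPN"), glut = "vPN", gaba = "APL")
    nt_idx <- lapply(nt_class, function(cl) take(cfg$nt_genes_per_class))
    names(nt_idx) <- nt_class
    for (cl in nt_class) {
      role[nt_idx[[cl]]] <- paste0("neurotransmitter:", cl)
      baseline[nt_idx[[cl]]] <- stats::rnorm(cfg$nt_genes_per_class, 1.5, 0.5)
    }

    # ---- expected log2 expression per (type, stage) group ----------------
    n_groups <- n_types * n_stages
    E <- matrix(baseline, cfg$n_genes, n_groups)
    grp_type <- rep(seq_len(n_types), times = n_stages)
    grp_stage <- rep(seq_len(n_stages), each = n_types)

    for (g in seq_len(n_groups)) {
      t <- grp_type[g]; s <- grp_stage[g]
      E[marker_idx[onoff, t], g] <- E[marker_idx[onoff, t], g] +
        cfg$marker_lfc * sqrt(cfg$type_effect_schedule[s])
      E[marker_idx[-onoff, t], g] <- E[marker_idx[-onoff, t], g] +
        cfg$marker_lfc * cfg$type_effect_schedule[s]
      E[down_idx, g] <- E[down_idx, g] +
        cfg$stage_program_span * down_shapes[cbind(down_group, rep(s, length(down_idx)))]
      E[up_idx, g] <- E[up_idx, g] +
        cfg$stage_program_span * up_shapes[cbind(up_group, rep(s, length(up_idx)))]
      if (types$embryonic[t] && s == 1)
        E[pruning_idx, g] <- E[pruning_idx, g] + cfg$pruning_lfc
      if (types$lineage[t] == "adPN" && !is.na(types$birth_rank[t])) {
        centered <- types$birth_rank[t] - (cfg$lineage_spec[["adPN"]] + 1) / 2
        E[gradient_idx, g] <- E[gradient_idx, g] +
          gradient_sign * cfg$gradient_slope * centered * cfg$gradient_attenuation[s]
      }
      for (cl in nt_class) {
        if (types$lineage[t] %in% nt_lineages[[cl]])
          E[nt_idx[[cl]], g] <- E[nt_idx[[cl]], g] + cfg$nt_lfc * cfg$nt_schedule[s]
      }
    }
    # Expression fractions per group (softmax on log2 scale).
    Fq <- 2^E
    Fq <- sweep(Fq, 2, colSums(Fq), "/")

    # ---- cells -----------------------------------------------------------
    n_cells <- n_groups * cfg$cells_per_type_per_stage
    cell_grp <- rep(seq_len(n_groups), each = cfg$cells_per_type_per_stage)
    cell_id <- sprintf("%s_%s_c%02d", cfg$stages[grp_stage[cell_grp]],
                       types$type_label[grp_type[cell_grp]],
                       sequence(rep(cfg$cells_per_type_per_stage, n_groups)))
    lib <- stats::rlnorm(n_cells, cfg$library_meanlog, cfg$library_sdlog)

    mu <- Fq[, cell_grp, drop = FALSE]
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes,
                     dimnames = list(gene_id, cell_id))

    cells <- data.frame(
      cell_id = cell_id,
      stage = cfg$stages[grp_stage[cell_grp]],
      lineage = types$lineage[grp_type[cell_grp]],
      type_label = types$type_label[grp_type[cell_grp]],
      birth_rank = types$birth_rank[grp_type[cell_grp]],
      stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = gene_id, role = role,
                        is_neuronal_marker = gene_id %in% panel,
                        stringsAsFactors = FALSE)
    ds <- ExpressionDataset(counts, cells = cells, genes = genes,
                            stage_levels = cfg$stages)

    truth <- structure(list(
      cells = cbind(cells, embryonic = types$embryonic[grp_type[cell_grp]]),
      genes = data.frame(gene_id = gene_id, role = role, baseline_log2 = baseline,
                         stringsAsFactors = FALSE),
      types = types,
      type_map = data.frame(type_label = types$type_label,
                            persists = TRUE, stringsAsFactors = FALSE),
      expected_log2 = E, group_type = grp_type, group_stage = grp_stage,
      config = cfg), class = "pn_ground_truth")
    list(dataset = ds, truth = truth)
  })
}

#' Export a simulated dataset as an on-disk fixture
#'
#' Writes the layout read back by [read_counts_mtx()]: `matrix.mtx`,
#' `genes.tsv`, `cells.tsv`, a cell `metadata.tsv`, plus ground-truth tables
#' and the generator parameters as JSON (so every planted effect size is
#' recorded alongside the data).
#'
#' @param sim the list returned by [simulate_pn()].
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the directory path.
#' @export
export_fixture <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) pn_io_error(sprintf("cannot create directory: %s", out_dir))
  }
  ds <- sim$dataset
  Matrix::writeMM(Matrix::Matrix(ds$counts, sparse = TRUE),
                  file.path(out_dir, "matrix.mtx"))
  writeLines(gene_ids(ds), file.path(out_dir, "genes.tsv"), useBytes = TRUE)
  writeLines(cell_ids(ds), file.path(out_dir, "cells.tsv"), useBytes = TRUE)
  meta <- ds$cells[, c("cell_id", "stage", "lineage", "type_label", "birth_rank")]
  meta$stage <- as.character(meta$stage)
  write_tsv_det(meta, file.path(out_dir, "metadata.tsv"))
  write_tsv_det(ds$genes[, c("gene_id", "is_neuronal_marker")],
                file.path(out_dir, "gene_metadata.tsv"))
  write_tsv_det(sim$truth$cells, file.path(out_dir, "ground_truth_cells.tsv"))
  write_tsv_det(sim$truth$genes, file.path(out_dir, "ground_truth_genes.tsv"))
  cfgl <- sim$truth$config
  write_json_det(unclass(cfgl)[!vapply(unclass(cfgl), is.function, TRUE)],
                 file.path(out_dir, "sim_params.json"))
  invisible(out_dir)
}
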
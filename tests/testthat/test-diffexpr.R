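test_that("rank-sum test reproduces exact small-sample cases", {
  r <- mwu_test(c(5, 6, 7), c(1, 2, 3), alternative = "greater")
  expect_equal(r$U, 9)
  expect_equal(r$p, 0.05)
  r2 <- mwu_test(c(5, 6, 7), c(1, 2, 3), alternative = "two_sided")
  expect_equal(r2$p, 0.10)
  r3 <- mwu_test(c(1, 2, 3), c(1, 2, 3), alternative = "two_sided")
  expect_equal(r3$U, 4.5)
  expect_equal(r3$p, 1.0)
  expect_error(mwu_test(numeric(0), 1:3), class = "pnstage_validation_error")
})

test_that("exact branch agrees with full enumeration on random instances", {
  set.seed(101)
  for (i in 1:200) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    vals <- sample(1:1000, m + n)         # distinct -> no ties, exact branch
    x <- vals[seq_len(m)]; y <- vals[-seq_len(m)]
    alt <- sample(c("two_sided", "greater"), 1)
    got <- mwu_test(x, y, alternative = alt)
    want <- oracle_mwu(x, y, alternative = alt)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("vectorized scan matches the scalar approximation branch", {
  set.seed(55)
  X <- matrix(rpois(30 * 24, 3), nrow = 30,
              dimnames = list(sprintf("g%d", 1:30), sprintf("c%d", 1:24)))
  grp <- rep(c(TRUE, FALSE), each = 12)
  for (alt in c("two_sided", "greater")) {
    mat <- pnstage:::mwu_matrix(X, grp, alternative = alt)
    for (g in seq_len(nrow(X))) {
      sc <- mwu_test(X[g, grp], X[g, !grp], alternative = alt)
      expect_equal(mat$U[g], sc$U)
      expect_equal(mat$p[g], sc$p, tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches the step-up recursion", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.1, 1.2)), class = "pnstage_validation_error")
  set.seed(77)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    s <- sort(p)
    expect_true(all(diff(bh_adjust(s)) >= -1e-15))
  }
})

test_that("signatures capture planted markers and obey the strict alpha cut", {
  frac <- vapply(1:10, function(seed) {
    sim <- simulate_pn(tiny_config(seed))
    ds <- cpm_normalize(sim$dataset)
    sub <- subset_cells(ds, stage = "P24", lineage = c("adPN", "lPN"))
    labels <- as.integer(factor(sub$cells$type_label)) - 1L
    sig <- cluster_signatures(sub, labels, alpha = 0.01)
    types <- sort(unique(sub$cells$type_label))
    mean(vapply(seq_along(types), function(i) {
      mk <- sim$truth$genes$gene_id[sim$truth$genes$role == paste0("marker:", types[i])]
      mean(mk %in% sig$signatures[[as.character(i - 1)]])
    }, 0))
  }, 0)
  expect_gte(mean(frac), 0.9)

  # boundary: a gene whose adjusted p equals alpha exactly is excluded
  sim <- simulate_pn(tiny_config(1))
  ds <- cpm_normalize(sim$dataset)
  sub <- subset_cells(ds, stage = "P24", lineage = c("adPN", "lPN"))
  labels <- as.integer(factor(sub$cells$type_label)) - 1L
  sig <- cluster_signatures(sub, labels, alpha = 0.01)
  tab0 <- sig$table[sig$table$cluster == 0 & sig$table$direction == "up", ]
  probe <- tab0[which.min(abs(tab0$p_adj - stats::median(tab0$p_adj))), ]
  sig_at <- cluster_signatures(sub, labels, alpha = probe$p_adj)
  expect_false(probe$gene %in% sig_at$signatures[["0"]])
})

test_that("signatures are invariant to label permutation and cell order", {
  sim <- simulate_pn(tiny_config(4))
  ds <- cpm_normalize(sim$dataset)
  sub <- subset_cells(ds, stage = "P24", lineage = "adPN")
  labels <- as.integer(factor(sub$cells$type_label)) - 1L
  sig <- cluster_signatures(sub, labels, alpha = 0.01)
  # permute label ids
  permuted <- c(2L, 0L, 3L, 1L)[labels + 1L]
  sig_p <- cluster_signatures(sub, permuted, alpha = 0.01)
  expect_identical(sig$signatures[["0"]], sig_p$signatures[["2"]])
  # permute cell order
  set.seed(2)
  ord <- sample(ncol(sub$counts))
  sig_o <- cluster_signatures(sub[, ord], labels[ord], alpha = 0.01)
  expect_identical(sig$signatures, sig_o$signatures)

  expect_error(cluster_signatures(sub, rep(0L, ncol(sub$counts))),
               class = "pnstage_validation_error")
})

test_that("stage-pair ranking is dominated by planted program genes", {
  sim <- simulate_pn(tiny_config(6))
  ds <- cpm_normalize(sim$dataset)
  top <- stage_pair_top_genes(ds, "P0", "Adult", k = 150)
  roles <- sim$truth$genes$role[match(top, sim$truth$genes$gene_id)]
  dynamic_roles <- c("stage_up", "stage_down", "pruning", "gradient",
                     grep("^neurotransmitter", unique(roles), value = TRUE))
  expect_gte(mean(roles %in% dynamic_roles), 0.8)
  expect_error(stage_pair_top_genes(ds, "P0", "P0"),
               class = "pnstage_validation_error")
  expect_warning(allg <- stage_pair_top_genes(ds, "P0", "P24", k = 1e6),
                 "exceeds")
  expect_length(allg, nrow(ds$counts))
})
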
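test_that("cell-level similarity is the mean inverse pairwise distance", {
  two <- matrix(c(0, 0, 2, 0), ncol = 2, byrow = TRUE)
  r <- cell_level_similarity(two)
  expect_equal(unname(r$per_cell), c(0.5, 0.5))
  collinear <- matrix(c(0, 0, 1, 0, 2, 0), ncol = 2, byrow = TRUE)
  r2 <- cell_level_similarity(collinear)
  expect_equal(unname(r2$per_cell), c(0.75, 1.0, 0.75))
  # homogeneity: rescaling coordinates by c scales similarities by 1/c
  r3 <- cell_level_similarity(collinear * 4)
  expect_equal(r3$per_cell, r2$per_cell / 4)
  # coincident points excluded with a warning
  dup <- rbind(collinear, c(0, 0))
  expect_warning(r4 <- cell_level_similarity(dup), "coincident")
  expect_equal(r4$n_zero_pairs, 1)
  expect_error(cell_level_similarity(two[1, , drop = FALSE]),
               class = "pnstage_validation_error")
})

test_that("cluster-level similarity is Pearson correlation between centroids", {
  lc <- cbind(a1 = c(1, 2, 3), a2 = c(1, 2, 3),
              b1 = c(3, 2, 1), b2 = c(3, 2, 1),
              c1 = c(2, 4, 6), c2 = c(2, 4, 6))
  rownames(lc) <- c("g1", "g2", "g3")
  counts <- matrix(1, 3, 6, dimnames = dimnames(lc))
  ds <- cpm_normalize(ExpressionDataset(counts))
  ds$logcpm <- lc
  r <- cluster_level_similarity(ds, c(0, 0, 1, 1, 2, 2), rownames(lc), n_boot = 50)
  expect_equal(unname(r$matrix["0", "1"]), -1)
  expect_equal(unname(r$matrix["0", "2"]), 1)   # affine invariance
  # identical centroids correlate at 1
  r2 <- cluster_level_similarity(ds, c(0, 1, 2, 2, 3, 3), rownames(lc), n_boot = 50)
  expect_equal(unname(r2$matrix["0", "1"]), 1)
  # constant centroid excluded
  lc2 <- lc; lc2[, 5:6] <- 5
  ds$logcpm <- lc2
  w <- capture_warnings(r3 <- cluster_level_similarity(ds, c(0, 0, 1, 1, 2, 2), rownames(lc)))
  expect_true(any(grepl("constant", w)))   # a one-pair CI also warns
  expect_equal(r3$n_clusters, 2)
})

test_that("bootstrap interval is deterministic, degenerate-safe and calibrated", {
  v <- c(1, 2, 3, 4, 5)
  ci1 <- bootstrap_ci(v, n_iter = 200, seed = 9)
  ci2 <- bootstrap_ci(v, n_iter = 200, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], mean(v)); expect_gte(ci1[2], mean(v))
  expect_warning(ci3 <- bootstrap_ci(7), "single value")
  expect_equal(unname(ci3), c(7, 7))
  expect_equal(unname(bootstrap_ci(rep(2, 10), n_iter = 100)), c(2, 2))
  expect_error(bootstrap_ci(1:3, n_iter = 0), class = "pnstage_parameter_error")
  # coverage of the mean of N(0,1), n = 100, ~95% over 200 replications
  set.seed(123)
  hits <- vapply(1:200, function(i) {
    x <- rnorm(100)
    ci <- bootstrap_ci(x, n_iter = 400, seed = i)
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  expect_gte(mean(hits), 0.89)
  expect_lte(mean(hits), 0.99)
})

test_that("type correlation matrices are valid and birth-ordered", {
  sim <- simulate_pn(sim_config(seed = 51, n_genes = 700,
                                lineage_spec = c(adPN = 8, lPN = 3, vPN = 1, APL = 1),
                                cells_per_type_per_stage = 12))
  ds <- cpm_normalize(sim$dataset)
  tc <- type_correlation_matrix(ds, stage = "P0", lineage = "adPN")
  expect_equal(unname(diag(tc$matrix)), rep(1, nrow(tc$matrix)))
  expect_equal(tc$matrix, t(tc$matrix))
  expect_identical(tc$birth_ranks, sort(tc$birth_ranks))
  expect_warning(type_correlation_matrix(ds, stage = "P0", lineage = "adPN",
                                         n_pcs = 50), "capped")
})

test_that("adjacent-birth types correlate more than distant ones at the first stage", {
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_pn(sim_config(seed = seed, n_genes = 1200,
                                  lineage_spec = c(adPN = 10, lPN = 2, vPN = 1, APL = 1),
                                  cells_per_type_per_stage = 12))
    ds <- cpm_normalize(sim$dataset)
    tc <- type_correlation_matrix(ds, stage = "P0", lineage = "adPN")
    M <- tc$matrix
    n <- nrow(M)
    adj <- M[cbind(seq_len(n - 1), seq2(2, n))]
    far <- M[abs(outer(seq_len(n), seq_len(n), "-")) >= 3 & upper.tri(M)]
    mean(adj) > mean(far)
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("the concordance statistic matches a brute-force oracle", {
  # perfect concordance: similarity strictly decreasing in birth distance
  k <- 8
  ranks <- seq_len(k)
  M <- 1 - abs(outer(ranks, ranks, "-")) / 10
  dimnames(M) <- list(paste0("t", ranks), paste0("t", ranks))
  expect_equal(birth_order_stat(M, ranks, min_group = 5), 1)
  # random matrices: equality with the oracle, and a null mean near zero
  set.seed(31)
  stats <- vapply(1:100, function(i) {
    k <- sample(7:12, 1)
    A <- matrix(rnorm(k * k), k)
    M <- cov2cor(crossprod(A))
    ranks <- sample(k)
    got <- birth_order_stat(M, ranks, min_group = 3)
    expect_equal(got, oracle_birth_order(M, ranks, min_group = 3), tolerance = 1e-12)
    got
  }, 0)
  expect_lt(abs(mean(stats)), 0.1)
  expect_error(birth_order_stat(M[1:3, 1:3], ranks[1:3], min_group = 5),
               class = "pnstage_validation_error")
})

test_that("permutation p follows the strict-greater rule and matches enumeration", {
  k <- 8
  ranks <- seq_len(k)
  M <- 1 - abs(outer(ranks, ranks, "-")) / 10
  dimnames(M) <- list(paste0("t", ranks), paste0("t", ranks))
  res <- birth_order_permutation(M, ranks, n_iter = 1000, seed = 1)
  expect_lt(res$p_value, 0.01)
  # observed equals the distribution maximum -> p = 0 under strict greater
  expect_identical(sum(res$permutation_stats > res$observed), 0L)
  expect_identical(res$p_value, 0)
  # the add-one variant cannot be zero
  res1 <- birth_order_permutation(M, ranks, n_iter = 200, seed = 1, add_one = TRUE)
  expect_gt(res1$p_value, 0)
  expect_error(birth_order_permutation(M, ranks, n_iter = 0),
               class = "pnstage_parameter_error")

  # sampled p agrees with full enumeration for k <= 7 types
  set.seed(77)
  k <- 6
  A <- matrix(rnorm(k * k), k)
  M6 <- cov2cor(crossprod(A))
  ranks6 <- sample(k)
  obs <- birth_order_stat(M6, ranks6, min_group = 3)
  perms <- gtools_style_perms(k)
  all_stats <- apply(perms, 1, function(p) birth_order_stat(M6, ranks6[p], min_group = 3))
  p_exact <- mean(all_stats > obs)
  res6 <- birth_order_permutation(M6, ranks6, n_iter = 2000, seed = 3, min_group = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lte(abs(res6$p_value - p_exact), 3 * se + 1e-9)
})

test_that("complete-linkage joins and optimal leaf order match brute force", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:7, 1)
    X <- matrix(rnorm(n * 3), n)
    D <- as.matrix(dist(X))
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    expect_equal(sort(hc$height), sort(oracle_complete_linkage_heights(D)),
                 tolerance = 1e-12)
    res <- dendrogram_order(X)
    expect_equal(res$cost, oracle_olo_cost(res$hclust, D), tolerance = 1e-12)
    # the order is a valid permutation and achieves the reported cost
    o <- res$order
    expect_setequal(o, seq_len(n))
    expect_equal(sum(D[cbind(o[-n], o[-1])]), res$cost, tolerance = 1e-12)
  }
})

test_that("dendrogram ordering handles base cases deterministically", {
  two <- matrix(c(0, 0, 3, 4), ncol = 2, byrow = TRUE)
  r <- dendrogram_order(two)
  expect_equal(r$hclust$height, 5)
  # mutual distances (1, 5, 5): the distance-1 pair joins first
  pts <- matrix(c(0, 0, 1, 0, 0.5, 4.97), ncol = 2, byrow = TRUE)
  r3 <- dendrogram_order(pts)
  expect_identical(sort(r3$hclust$merge[1, ]), c(-2L, -1L))
  # leaf order is invariant to input row order (up to global reversal)
  X <- matrix(rnorm(12), 6)
  rownames(X) <- paste0("p", 1:6)
  a <- dendrogram_order(X)
  perm <- c(3, 1, 6, 2, 5, 4)
  b <- dendrogram_order(X[perm, ])
  la <- a$labels
  lb <- b$labels
  expect_true(identical(la, lb) || identical(la, rev(lb)) ||
              a$cost == b$cost)
  expect_error(dendrogram_order(X[1, , drop = FALSE]),
               class = "pnstage_validation_error")
})
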
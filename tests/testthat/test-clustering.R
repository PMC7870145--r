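test_that("embedding is deterministic and handles minimal inputs", {
  sim <- simulate_pn(tiny_config(21))
  ds <- cpm_normalize(sim$dataset)
  sub <- ds[, which(ds$cells$stage == "P24")]
  fs <- overdispersed_genes(sub, 50)
  for (m in c("tsne", "umap")) {
    e1 <- embed_2d(sub, fs, method = m, seed = 3)
    e2 <- embed_2d(sub, fs, method = m, seed = 3)
    expect_identical(unclass(e1), unclass(e2))
    expect_identical(dim(e1), c(ncol(sub$counts), 2L))
  }
  # 3 cells: coordinates still produced (PCA fallback)
  e3 <- suppressWarnings(embed_2d(sub[, 1:3], fs, method = "tsne"))
  expect_identical(nrow(e3), 3L)
  # identical cells: degenerate but not an error
  cdup <- sub$counts[, rep(1, 5)]
  colnames(cdup) <- sprintf("d%d", 1:5)
  dsd <- cpm_normalize(ExpressionDataset(cdup))
  expect_warning(ed <- embed_2d(dsd, fs, method = "tsne"), "identical")
  expect_true(all(ed == 0))
  expect_error(embed_2d(sub[, 1:2], fs), class = "pnstage_validation_error")
})

test_that("well-separated types are far apart in the embedding", {
  ok <- vapply(1:10, function(seed) {
    sim <- simulate_pn(tiny_config(seed))
    ds <- cpm_normalize(sim$dataset)
    two <- c("adPN_T01", "adPN_T02")
    sub <- ds[, which(ds$cells$type_label %in% two & ds$cells$stage == "P24")]
    fs <- overdispersed_genes(sub, 50)
    emb <- embed_2d(sub, fs, method = "tsne", seed = seed)
    grp <- sub$cells$type_label == two[1]
    centroids <- rbind(colMeans(emb[grp, ]), colMeans(emb[!grp, ]))
    between <- sqrt(sum((centroids[1, ] - centroids[2, ])^2))
    within <- mean(c(sqrt(rowSums(sweep(emb[grp, ], 2, centroids[1, ])^2)),
                     sqrt(rowSums(sweep(emb[!grp, ], 2, centroids[2, ])^2))))
    between > 3 * within
  }, TRUE)
  expect_gte(sum(ok), 9)
})

test_that("density clustering resolves two separated Gaussian blobs exactly", {
  set.seed(42)
  X <- rbind(matrix(rnorm(100, 0, 1), ncol = 2),
             matrix(rnorm(100, 10, 1), ncol = 2))
  labels <- density_cluster(X, min_cluster_size = 10, min_samples = 5)
  truth <- rep(0:1, each = 50)
  assigned <- labels != -1L
  expect_identical(length(unique(labels[assigned])), 2L)
  expect_equal(agreement_ari(labels[assigned], truth[assigned]), 1)
})

test_that("density clustering labels sparse uniform noise as noise", {
  set.seed(7)
  X <- matrix(runif(80, 0, 100), ncol = 2)
  labels <- density_cluster(X, min_cluster_size = 20, min_samples = 10)
  expect_true(all(labels == -1L))
})

test_that("duplicating every point leaves the blob partition unchanged", {
  set.seed(9)
  X <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
             matrix(rnorm(60, 10, 0.5), ncol = 2))
  l1 <- density_cluster(X, min_cluster_size = 10, min_samples = 5)
  Xd <- rbind(X, X)
  l2 <- density_cluster(Xd, min_cluster_size = 10, min_samples = 5)
  # same partition of the distinct locations, up to label names
  expect_equal(agreement_ari(l1, l2[seq_len(nrow(X))]), 1)
  expect_identical(l2[seq_len(nrow(X))], l2[nrow(X) + seq_len(nrow(X))])
})

test_that("density clustering validates parameters", {
  X <- matrix(rnorm(40), ncol = 2)
  expect_error(density_cluster(X, min_cluster_size = 1),
               class = "pnstage_parameter_error")
})

test_that("graph clustering recovers well-separated types and is deterministic", {
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_pn(tiny_config(seed))
    ds <- cpm_normalize(sim$dataset)
    two <- c("adPN_T01", "adPN_T02")
    sub <- ds[, which(ds$cells$type_label %in% two & ds$cells$stage == "P24")]
    fs <- overdispersed_genes(sub, 50)
    lb <- graph_cluster(sub, fs, resolution = 1, k = 5, seed = seed)
    agreement_ari(as.integer(lb), as.integer(sub$cells$type_label == two[1])) == 1
  }, TRUE)
  expect_gte(sum(hits), 9)

  sim <- simulate_pn(tiny_config(3))
  ds <- cpm_normalize(sim$dataset)
  sub <- ds[, which(ds$cells$stage == "P24")]
  fs <- overdispersed_genes(sub, 50)
  a <- graph_cluster(sub, fs, seed = 1)
  b <- graph_cluster(sub, fs, seed = 1)
  expect_identical(as.integer(a), as.integer(b))
  expect_error(graph_cluster(sub, fs, k = ncol(sub$counts)),
               class = "pnstage_parameter_error")
})

test_that("a homogeneous population stays one community at low resolution", {
  sim <- simulate_pn(tiny_config(15, type_effect_schedule = c(0, 0, 0, 0)))
  ds <- cpm_normalize(sim$dataset)
  sub <- ds[, which(ds$cells$lineage == "adPN" & ds$cells$stage == "P48")]
  fs <- overdispersed_genes(sub, 50)
  lb <- graph_cluster(sub, fs, resolution = 0.1, seed = 0)
  expect_identical(length(unique(as.integer(lb))), 1L)
})

test_that("adjusted Rand index matches its closed form and an external oracle", {
  expect_equal(agreement_ari(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(agreement_ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(agreement_ari(rep(1, 6), 1:6), 0)
  expect_error(agreement_ari(1:3, 1:4), class = "pnstage_validation_error")
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:100) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(agreement_ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cluster count peaks at the second stage with per-stage features", {
  ok <- vapply(1:10, function(seed) {
    sim <- simulate_pn(sim_config(seed = seed, n_genes = 900,
                                  lineage_spec = c(adPN = 6, lPN = 4, vPN = 2, APL = 1),
                                  cells_per_type_per_stage = 15))
    ds <- cpm_normalize(sim$dataset)
    k_of <- function(stage) {
      sub <- subset_cells(ds, stage = stage)
      fs <- overdispersed_genes(sub, 300)
      emb <- embed_2d(sub, fs, method = "tsne", seed = seed)
      lb <- density_cluster(emb, 10, 5)
      length(unique(lb[lb != -1L]))
    }
    k_of("P24") >= k_of("Adult")
  }, TRUE)
  expect_gte(sum(ok), 8)
})

test_that("density and graph clustering agree on well-separated fixtures", {
  sim <- simulate_pn(tiny_config(30))
  ds <- cpm_normalize(sim$dataset)
  sub <- subset_cells(ds, stage = "P24")
  fs <- overdispersed_genes(sub, 300)
  emb <- embed_2d(sub, fs, method = "tsne", seed = 0)
  hdb <- density_cluster(emb, 10, 5)
  led <- graph_cluster(sub, fs, resolution = 2, k = 10, seed = 0)
  keep <- hdb != -1L
  expect_gte(agreement_ari(as.integer(hdb[keep]), as.integer(led[keep])), 0.8)
})
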
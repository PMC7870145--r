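sig_set <- function(sigs, stage = NA) {
  structure(list(signatures = sigs, alpha = 0.01, stage = stage),
            class = "signature_set")
}

test_that("Jaccard index follows its set definition", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(z <- jaccard(character(), character()), "empty")
  expect_equal(z, 0)
  set.seed(19)
  pool <- sprintf("g%d", 1:12)
  for (i in 1:100) {
    a <- sample(pool, sample(0:8, 1))
    b <- sample(pool, sample(1:8, 1))
    expect_equal(jaccard(a, b), oracle_jaccard(a, b))
  }
})

test_that("reciprocal-best matching classifies pairs by mutual argmax", {
  # identical signature families: everything matches two-way at 1
  fam <- list(`0` = c("a", "b"), `1` = c("c", "d"), `2` = c("e", "f"))
  mr <- signature_match(sig_set(fam, "P24"), sig_set(fam, "P48"))
  tw <- mr$pairs[mr$pairs$match_class == "two_way", ]
  expect_equal(nrow(tw), 3)
  expect_true(all(tw$jaccard == 1))
  expect_true(all(tw$cluster_a == tw$cluster_b))

  # engineered 2x2 matrix [[0.6, 1/6], [0.2, 0.5]]: diagonal two-way matches
  a <- list(`0` = c("x1", "x2", "x3", "x4", "s1"),
            `1` = c("y1", "y2", "y3", "t1"))
  b <- list(`0` = c("x1", "x2", "x3", "x4", "s2", "u1"),
            `1` = c("y1", "y2", "y3", "t2", "x9", "x8"))
  mr2 <- signature_match(sig_set(a), sig_set(b))
  expect_equal(unname(mr2$jaccard_matrix["0", "0"]), 4 / 7)
  tw2 <- mr2$pairs[mr2$pairs$match_class == "two_way", ]
  expect_identical(tw2$cluster_a, tw2$cluster_b)
  expect_equal(nrow(tw2), 2)

  # one-way structure: a2's best is b1, but b1's best is a1
  a3 <- list(a1 = c("m1", "m2", "m3", "m4", "m5", "m6"),
             a2 = c("m1", "m2", "m3", "q1", "q2", "q3"))
  b3 <- list(b1 = c("m1", "m2", "m3", "m4", "m5", "m6"),
             b2 = c("r1", "r2", "r3", "m6", "z1", "z2"))
  mr3 <- signature_match(sig_set(a3), sig_set(b3))
  cls <- mr3$pairs
  expect_identical(cls$match_class[cls$cluster_a == "a1" & cls$cluster_b == "b1"], "two_way")
  expect_identical(cls$match_class[cls$cluster_a == "a2"], "one_way_ab")
})

test_that("swapping stage order flips one-way directions", {
  a <- list(a1 = sprintf("m%d", 1:6), a2 = c("m1", "m2", "m3", "q1", "q2", "q3"))
  b <- list(b1 = sprintf("m%d", 1:6), b2 = c("r1", "r2", "m6", "z1"))
  fwd <- signature_match(sig_set(a), sig_set(b))
  rev <- signature_match(sig_set(b), sig_set(a))
  fwd_tw <- fwd$pairs[fwd$pairs$match_class == "two_way", c("cluster_a", "cluster_b")]
  rev_tw <- rev$pairs[rev$pairs$match_class == "two_way", c("cluster_b", "cluster_a")]
  names(rev_tw) <- c("cluster_a", "cluster_b")
  expect_identical(fwd_tw[order(fwd_tw$cluster_a), ], rev_tw[order(rev_tw$cluster_a), ])
  ab <- fwd$pairs[fwd$pairs$match_class == "one_way_ab", c("cluster_a", "cluster_b")]
  ba <- rev$pairs[rev$pairs$match_class == "one_way_ba", c("cluster_b", "cluster_a")]
  expect_identical(unname(unlist(ab)), unname(unlist(ba)))
})

test_that("empty signatures are excluded and ties yield no match", {
  a <- list(`0` = c("a", "b"), `1` = character())
  b <- list(`0` = c("a", "b"))
  mr <- expect_silent(signature_match(sig_set(a), sig_set(b)))
  expect_identical(mr$excluded_a, "1")
  # tie: two b-clusters equally similar to a0 -> no match from a0
  a2 <- list(a0 = c("p", "q"))
  b2 <- list(b0 = c("p", "z"), b1 = c("q", "z"))
  mr2 <- signature_match(sig_set(a2), sig_set(b2))
  expect_false(any(mr2$pairs$match_class %in% c("two_way", "one_way_ab")))
})

test_that("planted private markers chain the same type across stages", {
  sim <- simulate_pn(tiny_config(41))
  ds <- cpm_normalize(sim$dataset)
  stages <- stage_levels(ds)
  labels_by_stage <- list(); sigs_by_stage <- list()
  for (s in stages) {
    sub <- subset_cells(ds, stage = s)
    labels_by_stage[[s]] <- as.integer(factor(sub$cells$type_label)) - 1L
    sigs_by_stage[[s]] <- cluster_signatures(sub, labels_by_stage[[s]], alpha = 0.01, stage = s)
  }
  # the "expressed" cutoff lives on the log-CPM scale, which shifts with the
  # panel size: with 600 genes a silent gene still sits near 4 log2(CPM+1),
  # so the on/off boundary for this fixture is ~6
  mm <- marker_match(ds, labels_by_stage, sigs_by_stage, expr_threshold = 6)
  good <- mm$pairs[mm$pairs$lineage_consistent, ]
  # every adjacent-stage pair of the same labeled cluster id is the same type
  # (labels are factor codes of type_label, identical across stages here)
  expect_gte(nrow(good), 1)
  expect_true(all(good$cluster_a == good$cluster_b))
  # most types are chained between at least one stage pair
  expect_gte(length(unique(good$cluster_a)), 5)
})

test_that("markers expressed in two clusters are not unique; pairs can rescue", {
  # 3 clusters x 4 genes: A on in 1 and 2; B on in 1 and 3; C on in 3 only
  on <- 12; off <- 0
  block <- function(A, B, C, D) matrix(c(A, B, C, D), nrow = 4, byrow = TRUE)
  lc <- cbind(block(on, on, off, off)[, rep(1, 5)],
              block(on, off, off, off)[, rep(1, 5)],
              block(off, on, on, off)[, rep(1, 5)])
  rownames(lc) <- c("A", "B", "C", "D")
  colnames(lc) <- sprintf("c%d", 1:15)
  counts <- matrix(1, 4, 15, dimnames = dimnames(lc))
  cells <- data.frame(cell_id = colnames(lc), stage = "P24",
                      lineage = "adPN")
  ds <- cpm_normalize(ExpressionDataset(counts, cells = cells))
  ds$logcpm <- lc
  labels <- rep(0:2, each = 5)
  sigs <- sig_set(list(`0` = c("A", "B"), `1` = c("A"), `2` = c("B", "C")), "P24")
  mm <- marker_match(ds, list(P24 = labels), list(P24 = sigs))
  um <- mm$unique_markers$P24
  expect_false("A" %in% names(um))          # A is on in clusters 0 and 1
  expect_identical(um[["C"]], "2")          # C alone selects cluster 2
  expect_identical(um[["A+B"]], "0")        # conjunction isolates cluster 0
})
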
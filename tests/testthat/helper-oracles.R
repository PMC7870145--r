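# Independent brute-force oracles. Each is a deliberately naive
# re-implementation, kept free of any code path it is used to check.

# Exact Mann-Whitney p by full enumeration of all C(m+n, m) group assignments.
oracle_mwu <- function(x, y, alternative = "two_sided") {
  pool <- c(x, y)
  m <- length(x)
  u_of <- function(idx) {
    xx <- pool[idx]; yy <- pool[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(length(pool), m), 2, u_of)
  p_ge <- mean(us >= u_obs)
  p_le <- mean(us <= u_obs)
  p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
  list(U = u_obs, p = p)
}

# Step-up BH by the textbook recursion.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0
  for (g in a) if (g %in% b) inter <- inter + 1
  uni <- length(unique(c(a, b)))
  if (uni == 0) 0 else inter / uni
}

# Birth-order concordance: independent implementation with explicit sorting.
oracle_birth_order <- function(corr, ranks, min_group = 5) {
  rhos <- c()
  for (i in seq_along(ranks)) {
    earlier <- which(ranks < ranks[i]); later <- which(ranks > ranks[i])
    grp <- if (length(earlier) >= length(later)) earlier else later
    if (length(grp) < min_group) next
    sim_rank <- rank(-corr[i, grp])          # most similar first
    dist_rank <- rank(abs(ranks[grp] - ranks[i]))  # nearest born first
    # Spearman with midranks via Pearson on the rank vectors
    rhos <- c(rhos, stats::cor(sim_rank, dist_rank))
  }
  mean(rhos)
}

# Naive agglomerative complete linkage: returns merge heights in order.
oracle_complete_linkage_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  active <- as.list(seq_len(n))
  heights <- c()
  while (length(active) > 1) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(length(active) - 1)) for (j in seq((i + 1), length(active))) {
      h <- max(D[active[[i]], active[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    active[[bi]] <- c(active[[bi]], active[[bj]])
    active[[bj]] <- NULL
  }
  heights
}

# Minimum successive-leaf distance over all 2^(n-1) orders consistent with a
# dendrogram (flip enumeration), for small n.
oracle_olo_cost <- function(hc, D) {
  orders <- function(node) {
    if (node < 0) return(list(-node))
    a <- orders(hc$merge[node, 1]); b <- orders(hc$merge[node, 2])
    out <- list()
    for (x in a) for (y in b) { out[[length(out) + 1]] <- c(x, y); out[[length(out) + 1]] <- c(y, x) }
    out
  }
  all_ord <- orders(nrow(hc$merge))
  min(vapply(all_ord, function(o) sum(D[cbind(o[-length(o)], o[-1])]), 0))
}

seq2 <- function(a, b) if (b < a) integer(0) else seq(a, b)

# all permutations of 1..k (tiny k only)
gtools_style_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_style_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, matrix(setdiff(seq_len(k), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
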
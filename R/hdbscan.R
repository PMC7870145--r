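# Hierarchical density-based clustering (HDBSCAN-style), implemented from the
# standard construction: core distances -> mutual reachability graph -> MST ->
# single-linkage hierarchy -> condensed tree (min cluster size) ->
# excess-of-mass cluster selection. Points not absorbed by any selected
# cluster are labeled -1 (noise). Deterministic: no randomness anywhere.

hdbscan_points <- function(X, min_cluster_size, min_samples) {
  if (min_cluster_size < 2) pn_parameter_error("min_cluster_size must be >= 2")
  if (min_samples < 1) pn_parameter_error("min_samples must be >= 1")
  n <- nrow(X)
  if (n < min_cluster_size) return(rep(-1L, n))

  D <- as.matrix(stats::dist(X))
  k <- min(min_samples + 1L, n)          # +1: row includes the self distance 0
  core <- apply(D, 1, function(r) sort.int(r, method = "quick")[k])
  MR <- pmax(D, outer(core, core, pmax))

  # --- minimum spanning tree on mutual reachability (Prim) ---
  intree <- logical(n)
  dmin <- MR[1, ]; from <- rep(1L, n)
  intree[1] <- TRUE; dmin[1] <- Inf
  ea <- integer(n - 1); eb <- integer(n - 1); ew <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    j <- which.min(ifelse(intree, Inf, dmin))
    ea[i] <- from[j]; eb[i] <- j; ew[i] <- dmin[j]
    intree[j] <- TRUE; dmin[j] <- Inf
    upd <- !intree & MR[j, ] < dmin
    dmin[upd] <- MR[j, upd]; from[upd] <- j
  }
  ord <- order(ew, ea, eb)               # ascending, deterministic tie-break
  ea <- ea[ord]; eb <- eb[ord]; ew <- ew[ord]

  # --- single-linkage hierarchy via union-find ---
  n_nodes <- 2L * n - 1L
  child1 <- integer(n_nodes); child2 <- integer(n_nodes)
  height <- numeric(n_nodes); nsize <- c(rep(1L, n), integer(n - 1L))
  parent_uf <- seq_len(n)
  node_of <- seq_len(n)                  # component representative -> tree node
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  for (i in seq_len(n - 1)) {
    ra <- find(ea[i]); rb <- find(eb[i])
    node <- n + i
    child1[node] <- node_of[ra]; child2[node] <- node_of[rb]
    height[node] <- ew[i]
    nsize[node] <- nsize[node_of[ra]] + nsize[node_of[rb]]
    parent_uf[rb] <- ra
    node_of[ra] <- node
  }
  root <- n_nodes

  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, child1[v], child2[v])
    }
    out
  }
  lam <- function(h) if (h > 0) 1 / h else 1e12

  # --- condensed tree ---
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_stab <- numeric(0)
  cl_children <- list()
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    id <- length(cl_parent)
    cl_children[[id]] <<- integer(0)
    if (parent > 0) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  pt_cluster <- integer(n)               # cluster each point fell out of
  root_cl <- new_cluster(0L, 0)

  stack_node <- root; stack_cl <- root_cl
  while (length(stack_node)) {
    v <- stack_node[length(stack_node)]; cl <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    l <- lam(height[v])
    c1 <- child1[v]; c2 <- child2[v]
    s1 <- nsize[c1]; s2 <- nsize[c2]
    big1 <- s1 >= min_cluster_size; big2 <- s2 >= min_cluster_size
    if (big1 && big2) {
      cl_stab[cl] <- cl_stab[cl] + nsize[v] * (l - cl_birth[cl])
      ca <- new_cluster(cl, l); cb <- new_cluster(cl, l)
      stack_node <- c(stack_node, c1, c2)
      stack_cl <- c(stack_cl, ca, cb)
    } else if (big1 || big2) {
      small <- if (big1) c2 else c1
      big <- if (big1) c1 else c2
      cl_stab[cl] <- cl_stab[cl] + nsize[small] * (l - cl_birth[cl])
      pt_cluster[leaves_under(small)] <- cl
      stack_node <- c(stack_node, big)
      stack_cl <- c(stack_cl, cl)
    } else {
      cl_stab[cl] <- cl_stab[cl] + nsize[v] * (l - cl_birth[cl])
      pt_cluster[leaves_under(v)] <- cl
    }
  }

  # --- excess-of-mass selection (root excluded) ---
  n_cl <- length(cl_parent)
  if (n_cl == 1L) return(rep(-1L, n))
  selected <- logical(n_cl)
  sel_score <- numeric(n_cl)
  for (cl in rev(seq_len(n_cl))) {
    kids <- cl_children[[cl]]
    if (cl == root_cl) { sel_score[cl] <- sum(sel_score[kids]); next }
    if (length(kids) == 0) {
      selected[cl] <- TRUE
      sel_score[cl] <- cl_stab[cl]
    } else {
      child_sum <- sum(sel_score[kids])
      if (cl_stab[cl] > child_sum) {
        selected[cl] <- TRUE
        sel_score[cl] <- cl_stab[cl]
        # deselect all descendants
        stack <- kids
        while (length(stack)) {
          d <- stack[length(stack)]; stack <- stack[-length(stack)]
          selected[d] <- FALSE
          stack <- c(stack, cl_children[[d]])
        }
      } else sel_score[cl] <- child_sum
    }
  }

  # --- labels: nearest selected ancestor-or-self of the fall-out cluster ---
  sel_ids <- which(selected)
  labels <- rep(-1L, n)
  if (length(sel_ids)) {
    lab_of <- integer(n_cl)              # 0 = none
    for (cl in seq_len(n_cl)) {
      cur <- cl
      while (cur > 0 && !selected[cur]) cur <- cl_parent[cur]
      lab_of[cl] <- if (cur > 0) match(cur, sel_ids) else 0L
    }
    hit <- lab_of[pt_cluster] > 0L
    labels[hit] <- lab_of[pt_cluster[hit]] - 1L
  }
  labels
}
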
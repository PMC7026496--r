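# Independent brute-force oracles used to check the package's algorithms.

# Minimum number of binary state changes on a tree: exhaustive enumeration
# of all internal-node labelings, per column.
brute_fitch <- function(tree, cm) {
  edges <- tree$edge
  n_tip <- length(tree$tip.label)
  internal <- n_tip + seq_len(tree$Nnode)
  tip_states <- cm[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  total <- 0L
  for (col in seq_len(ncol(cm))) {
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      states <- integer(n_tip + tree$Nnode)
      states[seq_len(n_tip)] <- tip_states[, col]
      states[internal] <- grid[g, ]
      best <- min(best, sum(states[edges[, 1]] != states[edges[, 2]]))
    }
    total <- total + best
  }
  total
}

# Per-variant membership tally: the straightforward way to count
# UpSet-style intersection patterns.
brute_patterns <- function(sets) {
  union_keys <- unique(unlist(sets))
  pats <- vapply(union_keys, function(k) {
    paste(sort(names(sets)[vapply(sets, function(s) k %in% s, logical(1))]),
          collapse = "&")
  }, character(1))
  tab <- table(pats)
  tibble::tibble(pattern = names(tab), n = as.integer(tab))
}

# Least-squares best topology for 4 taxa: fit unconstrained OLS branch
# lengths for each of the 3 unrooted topologies, pick the smallest SSE.
# `d` is a 4x4 matrix with rownames/colnames A,B,C,D (any labels).
ls_best_topology <- function(d) {
  labs <- rownames(d)
  pairs <- utils::combn(4, 2)
  y <- apply(pairs, 2, function(ij) d[ij[1], ij[2]])
  # columns: edge to taxon 1..4, internal edge
  design_for <- function(split) {
    # split: the taxon (2..4) cherried with taxon 1
    t(apply(pairs, 2, function(ij) {
      x <- numeric(5)
      x[ij] <- 1
      same_side <- (ij[1] == 1 | ij[1] == split) == (ij[2] == 1 | ij[2] == split)
      if (!same_side) x[5] <- 1
      x
    }))
  }
  sse <- vapply(2:4, function(split) {
    X <- design_for(split)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  # return the two cherry pairs of the best topology
  split <- (2:4)[which.min(sse)]
  list(cherry = sort(labs[c(1, split)]), sse = sse)
}

# Unrooted topology equality.
topo_equal <- function(t1, t2) {
  isTRUE(all.equal(
    as.numeric(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))), 0))
}

# Benjamini-Hochberg step-up, written directly from the definition.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# A small clonal design reused across tests.
small_clonal_truth <- function(seed = 1L, ...) {
  clonal_truth("((A,B),(C,(D,E)));", n_trunk = 12L, n_branch_per_edge = 10L,
               n_private_per_leaf = 6L, deleterious_fraction = 0.4,
               seed = seed, ...)
}
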
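# Independent brute-force oracles used to validate the implementations.
# Each is written against the mathematical definition, not the package code.

# weighted UniFrac by direct branch enumeration: for every edge, find the
# descendant tip set by walking the edge matrix recursively from the child
oracle_unifrac <- function(tree, va, vb) {
  stopifnot(!is.null(names(va)), identical(names(va), names(vb)))
  pa <- va / sum(va); pb <- vb / sum(vb)
  tips_under <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree$edge[e, 2])
    tips <- intersect(tips, names(va))
    total <- total + tree$edge.length[e] * abs(sum(pa[tips]) - sum(pb[tips]))
  }
  total
}

# greedy Ward agglomeration by exhaustive search of the merge minimizing the
# within-cluster sum-of-squares increase (SS from squared distances)
oracle_ward_partitions <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  ss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  clusters <- as.list(seq_len(n))
  partitions <- list()
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  partitions[[n]] <- labels
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      cost <- ss(c(clusters[[i]], clusters[[j]])) -
        ss(clusters[[i]]) - ss(clusters[[j]])
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    labels <- integer(n)
    for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- labels
  }
  partitions
}

# equality of partitions up to label permutation: canonicalize both by
# first-occurrence relabeling
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# two-sided Fisher p by full enumeration of tables with the observed margins
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  probs <- dhyper(xs, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive scan over the midpoint threshold grid
oracle_roc_best_c <- function(values, outcomes) {
  u <- sort(unique(values))
  thr <- (u[-length(u)] + u[-1]) / 2
  best <- -Inf
  for (th in thr) {
    pos <- values > th
    sens <- mean(pos[outcomes == "NEC"])
    spec <- mean(!pos[outcomes == "control"])
    best <- max(best, (sens + spec) / 2)
  }
  best
}

# tie-corrected Kruskal-Wallis H from the rank formula, and its exact
# permutation p by enumerating all assignments of values to groups
oracle_kw_h <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

oracle_kw_perm_p <- function(x, g) {
  n <- length(x)
  obs <- oracle_kw_h(x, g)
  perms <- all_perms(n)
  stats <- apply(perms, 1, function(p) oracle_kw_h(x[p], g))
  mean(stats >= obs - 1e-12)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, sub + (sub >= i))))
}

# Spearman rho via the rank formula; exact permutation p over all orderings
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# mean count of one OTU after hypergeometric subsampling
oracle_hyper_mean <- function(count, total, depth) depth * count / total

# a random small rooted tree with positive branch lengths, leaves named
# OTU1..OTUn
random_otu_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   tip.label = paste0("OTU", seq_len(n_leaves)))
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

# random two-sample count table over a tree's leaves (every OTU on the tree)
random_two_samples <- function(tree) {
  n <- length(tree$tip.label)
  va <- rpois(n, 8) + 1L
  vb <- rpois(n, 8) + 1L
  names(va) <- names(vb) <- tree$tip.label
  m <- rbind(A = va, B = vb)
  otu_table(m)
}
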
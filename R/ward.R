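# Ward minimum-variance clustering of a distance matrix, with
# pseudo-F / pseudo-T2 diagnostics for choosing the number of clusters.

# within-cluster sum of squares of one cluster, from squared distances:
# sum over within-cluster pairs of d^2 / cluster size
.ss_within <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
}

#' Ward minimum-variance clustering
#'
#' Agglomerates by the Ward criterion: at each step the merge with the
#' smallest increase in total within-cluster sum of squares is chosen, where
#' a cluster's sum of squares is computed from the squared input distances
#' (`sum_{i<j in C} d_ij^2 / |C|`). Implemented through the Lance-Williams
#' recurrence on squared distances ([stats::hclust()] `method = "ward.D"` on
#' `d^2`); reported merge heights are the within-SS increases (half the raw
#' Lance-Williams heights), which are non-decreasing.
#'
#' @param d symmetric distance matrix with sample ids
#' @return object of class `cluster_tree`: the `hclust` fit (`$hc`), sample
#'   ids, and `$heights` = per-merge within-SS increase
#' @export
ward_cluster <- function(d) {
  d <- as_dist_matrix(d)
  if (nrow(d) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::as.dist(d^2), method = "ward.D")
  hc$labels <- rownames(d)
  structure(list(hc = hc, sample_ids = rownames(d), heights = hc$height / 2),
            class = "cluster_tree")
}

#' Cluster labels for k clusters
#' @param tree a [ward_cluster()] result
#' @param k number of clusters
#' @return named integer vector of labels
#' @export
cluster_labels <- function(tree, k) stats::cutree(tree$hc, k = k)

#' Pseudo-F and pseudo-T2 diagnostics over candidate cluster counts
#'
#' For each k: `pseudo_F = ((T - W_k)/(k-1)) / (W_k/(n-k))` with `W_k` the
#' total within-cluster sum of squares of the k-cluster partition and `T` the
#' total sum of squares, both computed from squared pairwise distances.
#' `pseudo_T2` describes the merge that forms the k-cluster partition (the
#' merge of two clusters A, B of the (k+1)-partition):
#' `(W_AB - W_A - W_B) / ((W_A + W_B)/(n_A + n_B - 2))`; when both merging
#' clusters are singletons the statistic is defined as the merge's
#' sum-of-squares increase itself.
#'
#' @param tree a [ward_cluster()] result
#' @param d the distance matrix clustered
#' @param k_max largest k to evaluate (< n)
#' @return data.frame: k, pseudo_F, pseudo_T2
#' @export
cluster_diagnostics <- function(tree, d, k_max = NULL) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (is.null(k_max)) k_max <- min(n - 1, 10)
  if (k_max >= n) stop("k_max must be < n")
  d2 <- d^2
  total <- .ss_within(d2, seq_len(n))
  out <- data.frame(k = 2:k_max, pseudo_F = NA_real_, pseudo_T2 = NA_real_)
  for (r in seq_len(nrow(out))) {
    k <- out$k[r]
    lab <- stats::cutree(tree$hc, k = k)
    w_k <- sum(vapply(split(seq_len(n), lab), function(ix) .ss_within(d2, ix), 0))
    out$pseudo_F[r] <- if (w_k == 0) Inf else
      ((total - w_k) / (k - 1)) / (w_k / (n - k))
    # the merge k+1 -> k
    lab_prev <- stats::cutree(tree$hc, k = k + 1)
    # find the two (k+1)-partition clusters that share a k-partition label
    tab <- table(lab_prev, lab)
    joint <- which(colSums(tab > 0) == 2)
    prev_ids <- rownames(tab)[tab[, joint] > 0]
    ia <- which(lab_prev == prev_ids[1]); ib <- which(lab_prev == prev_ids[2])
    wa <- .ss_within(d2, ia); wb <- .ss_within(d2, ib)
    delta <- .ss_within(d2, c(ia, ib)) - wa - wb
    df <- length(ia) + length(ib) - 2
    out$pseudo_T2[r] <- if (df == 0 || (wa + wb) == 0) {
      if (df == 0) delta else if (delta > 0) Inf else 0
    } else delta / ((wa + wb) / df)
  }
  out
}

#' Choose the number of clusters from the diagnostics
#'
#' Deterministic stand-in for reading a scree plot. Candidates are the local
#' maxima of pseudo-F over k. Stopping at k is "justified" when the merge
#' that would reduce k to k-1 clusters carries a pronounced pseudo-T2 (at or
#' above the median of all evaluated merges) — the next merge would fuse
#' genuinely separated clusters. Among justified candidates (falling back to
#' all candidates when none is justified) the k with the largest pseudo-F is
#' returned, ties toward the smallest k. A monotone-decreasing pseudo-F curve
#' yields k = 2. `k_override` short-circuits the rule.
#'
#' @param diagnostics output of [cluster_diagnostics()]
#' @param k_override integer or NULL
#' @return chosen k
#' @export
choose_k <- function(diagnostics, k_override = NULL) {
  if (!is.null(k_override)) return(as.integer(k_override))
  stopifnot(nrow(diagnostics) > 0)
  f <- diagnostics$pseudo_F
  t2 <- diagnostics$pseudo_T2
  m <- length(f)
  if (m == 1) return(as.integer(diagnostics$k[1]))
  is_locmax <- vapply(seq_len(m), function(i) {
    (i == 1 || f[i] >= f[i - 1]) && (i == m || f[i] >= f[i + 1])
  }, TRUE)
  cand <- which(is_locmax & is.finite(f))
  if (length(cand) == 0) return(2L)
  med <- stats::median(t2[is.finite(t2)])
  # merge k -> k-1 is the diagnostics row for k-1; row 1 (k = 2) is always
  # justified: there is no coarser partition to prefer
  justified <- vapply(cand, function(i) {
    i == 1 || (is.finite(t2[i - 1]) && t2[i - 1] >= med)
  }, TRUE)
  pick <- if (any(justified)) cand[justified] else cand
  best <- pick[f[pick] == max(f[pick])]
  as.integer(diagnostics$k[min(best)])
}
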
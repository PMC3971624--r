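# Rare-OTU filtering and the weighted UniFrac distance.

#' Remove rare OTUs
#'
#' Keeps exactly the OTUs that are present (count > 0) in at least
#' `min_samples` samples AND have at least `min_total` reads over the whole
#' table. Defaults implement the study rule: drop OTUs detected in only one
#' sample or with fewer than five reads overall. The sample set is unchanged.
#'
#' @param t an [otu_table()]
#' @param min_samples minimum number of samples with a nonzero count
#' @param min_total minimum total reads across samples
#' @return filtered [otu_table()]
#' @export
filter_rare_otus <- function(t, min_samples = 2, min_total = 5) {
  keep <- colSums(t > 0) >= min_samples & colSums(t) >= min_total
  if (!any(keep)) stop("rare-OTU filter removed every OTU; ordination impossible")
  if (any(rowSums(t[, keep, drop = FALSE]) == 0))
    stop("rare-OTU filter left a sample with zero reads")
  otu_table(t[, keep, drop = FALSE])
}

# branch decomposition of a rooted tree: for each edge, its length and the
# set (index vector) of tips descending from it, in one postorder pass
.branch_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  # postorder over edges so children are resolved before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  res_tips <- vector("list", nrow(edge))
  # map each edge of the postorder copy back to its row in tree$edge
  key <- paste(edge[, 1], edge[, 2])
  row_of <- stats::setNames(seq_len(nrow(edge)), key)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (r in seq_len(nrow(ord))) {
    parent <- ord[r, 1]; child <- ord[r, 2]
    e <- row_of[[paste(parent, child)]]
    res_tips[[e]] <- desc[[child]]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  list(lengths = tree$edge.length, tips = res_tips,
       tip_label = tree$tip.label)
}

#' Weighted UniFrac distance matrix
#'
#' Raw (unnormalized) weighted UniFrac: for samples A and B,
#' `sum_i b_i * |p_i^A - p_i^B|` over all branches i, where `b_i` is the
#' branch length and `p_i^X` the fraction of sample X's reads assigned to
#' OTUs descending from the branch. The normalized variant divides each pair
#' by the abundance-weighted mean root-to-tip depth, scaling distances to
#' \[0,1\].
#'
#' @param t an [otu_table()]; proportions are computed per sample from the
#'   supplied (typically rare-OTU-filtered, unrarefied) counts
#' @param tree rooted `phylo` covering every OTU that has a nonzero count
#' @param normalized logical; default FALSE (raw form)
#' @return `dist_matrix`: symmetric matrix with zero diagonal, sample ids as
#'   dimnames
#' @export
weighted_unifrac <- function(t, tree, normalized = FALSE) {
  validate_tree(tree)
  used <- colnames(t)[colSums(t) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing) > 0)
    stop("OTU with nonzero count absent from tree: ", missing[1])
  bt <- .branch_tips(tree)
  # per-sample proportions aligned to tree tip order (absent tips = 0)
  p <- matrix(0, nrow = nrow(t), ncol = length(tree$tip.label),
              dimnames = list(rownames(t), tree$tip.label))
  shared <- intersect(colnames(t), tree$tip.label)
  props <- t / rowSums(t)
  p[, shared] <- props[, shared]
  # branch mass per sample: samples x branches
  bm <- vapply(seq_along(bt$lengths), function(e) {
    tips <- bt$tips[[e]]
    if (length(tips) == 1) p[, tips] else rowSums(p[, tips, drop = FALSE])
  }, numeric(nrow(t)))
  if (is.null(dim(bm))) bm <- matrix(bm, nrow = nrow(t))
  n <- nrow(t)
  d <- matrix(0, n, n, dimnames = list(rownames(t), rownames(t)))
  # root-to-tip depth of each tip, for the normalized variant
  if (normalized) {
    depths <- vapply(seq_len(ncol(p)), function(tip) {
      sum(bt$lengths[vapply(bt$tips, function(s) tip %in% s, TRUE)])
    }, 0)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- sum(bt$lengths * abs(bm[i, ] - bm[j, ]))
    if (normalized) {
      scale <- sum((p[i, ] + p[j, ]) * depths)
      val <- if (scale > 0) val / scale else 0
    }
    d[i, j] <- d[j, i] <- val
  }
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' Weighted UniFrac between two named samples
#' @param t an [otu_table()]
#' @param tree rooted `phylo`
#' @param a,b sample ids present in `t`
#' @param normalized see [weighted_unifrac()]
#' @return single distance
#' @export
weighted_unifrac_pair <- function(t, tree, a, b, normalized = FALSE) {
  if (!all(c(a, b) %in% rownames(t))) stop("sample not in table")
  sub <- otu_table(unclass(t)[unique(c(a, b)), , drop = FALSE])
  weighted_unifrac(sub, tree, normalized = normalized)[a, b]
}

#' Validate a symmetric distance matrix
#' @param d square numeric matrix
#' @return the matrix, classed `dist_matrix`
#' @export
as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - base::t(d))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be 0")
  if (any(d < 0)) stop("negative distances")
  structure(d, class = c("dist_matrix", "matrix", "array"))
}
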
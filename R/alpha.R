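# Alpha diversity: rarefaction to a common depth, Chao1 richness and the
# Simpson diversity index.

#' Rarefy one abundance vector
#'
#' Subsamples `depth` reads without replacement (multivariate
#' hypergeometric), standardizing sequencing effort across samples.
#'
#' @param v named non-negative integer vector of OTU counts, total > 0
#' @param depth target total, must be <= sum(v)
#' @param seed integer; the draw is reproducible from it
#' @return integer vector on the same OTU set with total `depth`
#' @export
rarefy_counts <- function(v, depth, seed = 1) {
  v <- stats::setNames(as.integer(round(v)), names(v))
  if (any(v < 0)) stop("negative counts")
  total <- sum(v)
  if (depth > total)
    stop(sprintf("depth %d exceeds sample total %d", depth, total))
  if (depth == total) return(v)
  with_local_seed(seed, {
    idx <- sample.int(total, depth)
    out <- tabulate(rep.int(seq_along(v), v)[idx], nbins = length(v))
    stats::setNames(as.integer(out), names(v))
  })
}

#' Chao1 richness estimate
#'
#' Bias-corrected form `S_obs + F1*(F1-1) / (2*(F2+1))`, with F1/F2 the
#' singleton/doubleton counts; defined even when no doubletons exist. The
#' classic form `S_obs + F1^2/(2*F2)` is available via `bias_corrected =
#' FALSE` (Inf-prone when F2 = 0).
#'
#' @param v non-negative integer counts, total > 0
#' @param bias_corrected logical
#' @return estimated richness, always >= observed richness
#' @export
chao1 <- function(v, bias_corrected = TRUE) {
  v <- v[v > 0]
  if (length(v) == 0) stop("empty sample")
  s_obs <- length(v)
  f1 <- sum(v == 1); f2 <- sum(v == 2)
  if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f1 == 0) s_obs
  else s_obs + f1^2 / (2 * f2)
}

#' Simpson diversity index
#'
#' `1 - sum(p_i^2)` over relative abundances: the probability that two reads
#' drawn with replacement belong to different OTUs. Higher = more diverse.
#' `variant` selects the complement ("one_minus_D", default), the raw
#' dominance sum ("D"), or inverse Simpson ("inverse").
#'
#' @param v non-negative counts, total > 0
#' @param variant one of "one_minus_D", "D", "inverse"
#' @return diversity value
#' @export
simpson <- function(v, variant = c("one_minus_D", "D", "inverse")) {
  variant <- match.arg(variant)
  total <- sum(v)
  if (total <= 0) stop("empty sample")
  d <- sum((v / total)^2)
  switch(variant, one_minus_D = 1 - d, D = d, inverse = 1 / d)
}

#' Per-sample alpha diversity at a rarefaction depth
#'
#' Rarefies every sample to `depth` (one draw per sample, seeds derived from
#' `seed` by sample position) and computes Chao1 and Simpson on the rarefied
#' counts. Samples with fewer than `depth` reads are flagged
#' (`depth_ok = FALSE`) and get NA indices rather than being silently kept.
#'
#' @param t an [otu_table()]
#' @param depth rarefaction depth (study default 2000)
#' @param seed integer
#' @return data.frame: sample_id, depth_ok, chao1, simpson
#' @export
alpha_diversity_table <- function(t, depth = 2000, seed = 1) {
  out <- data.frame(sample_id = rownames(t), depth_ok = rowSums(t) >= depth,
                    chao1 = NA_real_, simpson = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(t))) {
    if (!out$depth_ok[i]) next
    r <- rarefy_counts(t[i, ], depth, seed = derive_seed(seed, i))
    out$chao1[i] <- chao1(r)
    out$simpson[i] <- simpson(r)
  }
  rownames(out) <- NULL
  out
}

#' Derive a sub-stream seed from a master seed
#'
#' Counter scheme: stage/sample index is mixed into the master seed by a
#' fixed multiplicative hash, kept inside 32-bit integer range, so adding a
#' stream never shifts another stream's randomness.
#'
#' @param master integer master seed
#' @param counter integer stream index
#' @return integer seed
#' @export
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}
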
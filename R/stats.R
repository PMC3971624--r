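# Univariate statistics: Kruskal-Wallis group comparisons, Spearman
# correlations, Welch t-tests, Benjamini-Hochberg adjustment, and the
# metabolite-association report.

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic; p from the chi-squared approximation with
#' (groups - 1) degrees of freedom, or from full enumeration of group
#' assignments when `exact = TRUE` (small n only).
#'
#' @param groups list of >= 2 non-empty numeric vectors
#' @param exact logical; exact permutation p-value instead of chi-squared
#' @return list: statistic, p_value, medians, n
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 0L) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1) {
    # all values tied: no separation; H = 0 by convention
    kt <- list(statistic = c(H = 0), p.value = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
  }
  p <- kt$p.value
  if (exact) {
    stat_of <- function(perm) {
      ktp <- stats::kruskal.test(x[perm], g)
      unname(ktp$statistic)
    }
    n <- length(x)
    if (n > 9) stop("exact enumeration limited to n <= 9")
    perms <- permutations_of(n)
    obs <- unname(kt$statistic)
    stats_all <- apply(perms, 1, stat_of)
    p <- mean(stats_all >= obs - 1e-12)
  }
  list(statistic = unname(kt$statistic), p_value = p,
       medians = vapply(groups, stats::median, 0),
       n = vapply(groups, length, 0L))
}

# all permutations of 1..n as a matrix (n! rows); used by exact tests
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; p-value from the t approximation with
#' n - 2 degrees of freedom. Constant input is an error (rho undefined), not
#' zero.
#'
#' @param x,y paired numeric vectors, n >= 3
#' @return list: rho, p_value, n
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant input: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; input order preserved, values
#' capped at 1, element-wise >= the raw p-values.
#'
#' @param p numeric vector of p-values in (0, 1]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Welch two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided.
#'
#' @param groups list of exactly 2 numeric vectors, each n >= 2
#' @return list: statistic, df, p_value, means, n
#' @export
welch_t <- function(groups) {
  if (length(groups) != 2) stop("welch_t takes exactly 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs n >= 2")
  v <- vapply(groups, stats::var, 0)
  if (all(v == 0)) {
    if (mean(groups[[1]]) == mean(groups[[2]]))
      return(list(statistic = 0, df = sum(lengths(groups)) - 2, p_value = 1,
                  means = vapply(groups, mean, 0),
                  n = vapply(groups, length, 0L)))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, means = vapply(groups, mean, 0),
       n = vapply(groups, length, 0L))
}

#' Metabolite association report
#'
#' For each of alanine, histidine and the alanine:histidine ratio (one
#' first-urine-sample value per infant, days 4-9): Spearman correlation
#' against the infant's window-1 Firmicutes, Proteobacteria and
#' Propionibacterium relative abundances, and Kruskal-Wallis contrasts of the
#' metabolite across five groupings (window-1 NEC-I-like cluster vs rest,
#' window-2 NEC-II-like cluster vs rest, NEC vs rest excluding non-NEC
#' deaths, NEC-I vs rest excluding deaths, NEC-II vs rest excluding deaths).
#' An optional BH column adjusts each metabolite's correlation p-values.
#'
#' @param calls [classify_dysbiosis()] output, after [assign_subtypes()] if
#'   cluster contrasts are wanted (otherwise those rows are NA)
#' @param metabolites [metabolite_records()]
#' @param windows study windows
#' @param bh add a BH-adjusted p column (across all computed rows)
#' @return data.frame: metabolite, contrast, type, estimate (rho or median
#'   difference), group_median, rest_median, p_value (+ p_adjusted)
#' @export
table2_report <- function(calls, metabolites, windows = study_windows(),
                          bh = TRUE) {
  m <- metabolites[metabolites$day_of_life >= windows$w1$first_day &
                     metabolites$day_of_life <= windows$w1$last_day, ,
                   drop = FALSE]
  m <- m[order(m$infant_id, m$day_of_life), , drop = FALSE]
  m <- m[!duplicated(m$infant_id), , drop = FALSE]
  m <- m[m$infant_id %in% calls$infant_id, , drop = FALSE]
  idx <- match(m$infant_id, calls$infant_id)
  vals <- list(alanine = m$alanine, histidine = m$histidine,
               ratio = alanine_histidine_ratio(m))
  shares <- list(Firmicutes = calls$firmicutes_w1[idx],
                 Proteobacteria = 1 - calls$firmicutes_w1[idx] -
                   calls$propionibacterium_w1[idx],
                 Propionibacterium = calls$propionibacterium_w1[idx])
  # Proteobacteria share in window 1 is recomputed exactly when available
  if (!is.null(calls$proteobacteria_w1))
    shares$Proteobacteria <- calls$proteobacteria_w1[idx]

  grp <- calls$group[idx]
  sub <- if (!is.null(calls$subtype_cluster)) calls$subtype_cluster[idx]
         else calls$subtype[idx]
  groupings <- list(
    cluster_I_vs_rest = sub == "NEC-I-like",
    cluster_II_vs_rest = sub == "NEC-II-like",
    NEC_vs_rest = ifelse(grp == "non_NEC_death", NA, grp == "NEC"),
    NEC_I_vs_rest = ifelse(grp == "non_NEC_death", NA,
                           grp == "NEC" & sub == "NEC-I-like"),
    NEC_II_vs_rest = ifelse(grp == "non_NEC_death", NA,
                            grp == "NEC" & sub == "NEC-II-like"))

  rows <- list()
  for (met in names(vals)) {
    v <- vals[[met]]
    for (sh in names(shares)) {
      s <- shares[[sh]]
      r <- tryCatch(spearman_cor(s, v), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = met, contrast = paste0(sh, "_share"),
        type = "spearman",
        estimate = if (is.null(r)) NA_real_ else r$rho,
        group_median = NA_real_, rest_median = NA_real_,
        p_value = if (is.null(r)) NA_real_ else r$p_value,
        stringsAsFactors = FALSE)
    }
    for (gn in names(groupings)) {
      gmask <- groupings[[gn]]
      ok <- !is.na(gmask) & !is.na(v)
      r <- if (sum(gmask[ok]) > 0 && sum(!gmask[ok]) > 0)
        kruskal_wallis(list(v[ok & gmask], v[ok & !gmask])) else NULL
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = met, contrast = gn, type = "kruskal_wallis",
        estimate = if (is.null(r)) NA_real_ else r$statistic,
        group_median = if (is.null(r)) NA_real_ else r$medians[1],
        rest_median = if (is.null(r)) NA_real_ else r$medians[2],
        p_value = if (is.null(r)) NA_real_ else r$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) {
    out$p_adjusted <- NA_real_
    ok <- !is.na(out$p_value)
    if (any(ok)) out$p_adjusted[ok] <- bh_adjust(out$p_value[ok])
  }
  class(out) <- c("metabolite_report", "data.frame")
  out
}
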
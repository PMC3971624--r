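# Non-metric multidimensional scaling minimizing Kruskal stress-1, reported
# on the x100 scale. Monotone (isotonic) regression of configuration
# distances on the ranks of the input dissimilarities uses pool-adjacent-
# violators via stats::isoreg; ties in the dissimilarities are handled by the
# primary approach (stable ordering, tied values may receive unequal fits).

# stress-1 (0-1 scale) and the isotonic fit for a configuration
.stress1 <- function(delta, ord, cfg_d) {
  dhat <- numeric(length(cfg_d))
  dhat[ord] <- stats::isoreg(cfg_d[ord])$yf
  ss <- sum((cfg_d - dhat)^2)
  tt <- sum(cfg_d^2)
  if (tt == 0) return(list(stress = 1, dhat = dhat))
  list(stress = sqrt(ss / tt), dhat = dhat)
}

.lower <- function(m) m[lower.tri(m)]

# analytic gradient of stress-1 wrt the configuration, dhat held fixed
.stress_grad <- function(x, dhat_m, cfg_dm, stress) {
  n <- nrow(x)
  eps <- 1e-12
  ss <- sum(.lower(cfg_dm - dhat_m)^2)
  tt <- sum(.lower(cfg_dm)^2)
  if (stress == 0 || ss == 0) return(matrix(0, n, ncol(x)))
  coef <- ((cfg_dm - dhat_m) / ss - cfg_dm / tt) / pmax(cfg_dm, eps)
  diag(coef) <- 0
  g <- matrix(0, n, ncol(x))
  for (l in seq_len(ncol(x))) {
    diffs <- outer(x[, l], x[, l], "-")
    g[, l] <- stress * rowSums(coef * diffs)
  }
  g
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimizes `stress = 100 * sqrt(sum((d_config - dhat)^2) / sum(d_config^2))`
#' where `dhat` is the monotone regression of the configuration distances on
#' the ranks of the input dissimilarities. Each random start draws a standard
#' normal configuration; one additional deterministic start uses classical
#' metric scaling (PCoA) of the input. Within a start, steepest descent with
#' step halving guarantees a non-increasing stress trace. The best start's
#' configuration is returned centered and rotated to principal axes, so axis
#' variances are non-increasing (variance is maximized along axis 1).
#'
#' @param d symmetric dissimilarity matrix (zero diagonal)
#' @param k embedding dimension (study default 3); requires n >= k + 1
#' @param n_starts number of random starts in addition to the PCoA start
#' @param seed integer; start configurations derive from it
#' @param max_iter iteration cap per start
#' @param tol relative stress-change convergence tolerance
#' @return list of class `nmds_result`: `points` (n x k, centered, principal
#'   axes), `stress` (x100), `stress_trace` (per-start numeric vectors),
#'   `converged` (per start), `best_start`, `n_starts`, `sample_ids`
#' @export
nmds <- function(d, k = 3, n_starts = 20, seed = 1, max_iter = 300,
                 tol = 1e-6) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 samples")
  delta <- .lower(d)
  if (all(delta == 0)) stop("all dissimilarities are zero; no ordination")
  ord <- order(delta)  # stable: ties keep original (index) order

  run_start <- function(x0) {
    x <- x0
    cfg_dm <- as.matrix(stats::dist(x))
    st <- .stress1(delta, ord, .lower(cfg_dm))
    trace <- st$stress
    converged <- FALSE
    step <- 0.1
    for (it in seq_len(max_iter)) {
      dhat_m <- matrix(0, n, n)
      dhat_m[lower.tri(dhat_m)] <- st$dhat
      dhat_m <- dhat_m + base::t(dhat_m)
      g <- .stress_grad(x, dhat_m, cfg_dm, st$stress)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) { converged <- TRUE; break }
      scale <- sqrt(sum(x^2)) / gn
      improved <- FALSE
      s <- step
      for (h in 1:25) {
        x_new <- x - s * scale * g
        cfg_new <- as.matrix(stats::dist(x_new))
        st_new <- .stress1(delta, ord, .lower(cfg_new))
        if (st_new$stress < st$stress) { improved <- TRUE; break }
        s <- s / 2
      }
      if (!improved) { converged <- TRUE; break }
      rel <- (st$stress - st_new$stress) / max(st$stress, 1e-12)
      x <- x_new; cfg_dm <- cfg_new; st <- st_new
      step <- min(s * 2, 1)
      trace <- c(trace, st$stress)
      if (st$stress < 1e-9 || rel < tol) { converged <- TRUE; break }
    }
    list(x = x, stress = st$stress, trace = trace, converged = converged)
  }

  starts <- vector("list", n_starts + 1)
  # deterministic start: classical metric scaling, padded if degenerate
  cm <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k))
  x0 <- matrix(0, n, k)
  x0[, seq_len(ncol(cm))] <- cm
  starts[[1]] <- with_local_seed(derive_seed(seed, 0L),
                                 x0 + matrix(stats::rnorm(n * k, sd = 1e-4), n, k))
  for (s in seq_len(n_starts))
    starts[[s + 1]] <- with_local_seed(derive_seed(seed, s),
                                       matrix(stats::rnorm(n * k), n, k))

  runs <- lapply(starts, run_start)
  stresses <- vapply(runs, `[[`, 0, "stress")
  best <- which.min(stresses)
  x <- runs[[best]]$x
  # center and rotate to principal axes
  x <- base::scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  x <- x %*% sv$v
  dimnames(x) <- list(rownames(d), paste0("axis", seq_len(k)))
  structure(list(points = x, stress = 100 * stresses[best],
                 stress_trace = lapply(runs, function(r) 100 * r$trace),
                 converged = vapply(runs, `[[`, TRUE, "converged"),
                 best_start = best, n_starts = n_starts + 1,
                 sample_ids = rownames(d)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points, %d axes, stress %.3f (best of %d starts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts))
  invisible(x)
}
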
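# Biomarker evaluation: 2x2 tables, two-sided exact test, sensitivity,
# specificity, the binary-predictor c-statistic, and the ROC cut-point
# search for continuous markers.

#' 2x2 biomarker table
#' @param a cases positive; @param b cases negative
#' @param c controls positive; @param d controls negative
#' @return list of class `two_by_two`
#' @export
two_by_two <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "two_by_two")
}

#' Two-sided Fisher exact test p-value
#'
#' With margins fixed, sums the hypergeometric probabilities of all tables
#' whose point probability does not exceed that of the observed table (within
#' relative tolerance 1e-7 for ties) — the classical two-sided convention.
#'
#' @param t a [two_by_two()] (or `a`; then supply b, c, d)
#' @param b,c,d optional counts when `t` is the scalar `a`
#' @return p-value in (0, 1]
#' @export
fisher_exact <- function(t, b = NULL, c = NULL, d = NULL) {
  if (!inherits(t, "two_by_two")) t <- two_by_two(t, b, c, d)
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Evaluate a binary biomarker against NEC/control outcomes
#'
#' Infants with NA flags are excluded and counted in `n_excluded` (they lack
#' the sample a criterion needs). Sensitivity `a/(a+b)`, specificity
#' `d/(c+d)`, and the binary-predictor c-statistic
#' `(sensitivity + specificity)/2` — the area under the two-point ROC curve.
#' The p-value is the two-sided exact test of the 2x2 table.
#'
#' @param flags named logical vector (TRUE = biomarker positive), NA allowed
#' @param outcomes named character vector over the same infants, values
#'   "NEC" or "control"
#' @param criterion label carried into the result
#' @return list of class `biomarker_result`
#' @export
evaluate_binary <- function(flags, outcomes, criterion = "criterion") {
  bad <- setdiff(unique(outcomes), c("NEC", "control"))
  if (length(bad) > 0) stop("outcomes must be NEC/control; got: ", bad[1])
  ids <- intersect(names(flags), names(outcomes))
  flags <- flags[ids]; outcomes <- outcomes[ids]
  keep <- !is.na(flags)
  n_excluded <- sum(!keep)
  flags <- flags[keep]; outcomes <- outcomes[keep]
  a <- sum(flags & outcomes == "NEC")
  b <- sum(!flags & outcomes == "NEC")
  cc <- sum(flags & outcomes == "control")
  dd <- sum(!flags & outcomes == "control")
  if (a + b == 0) stop("no evaluable cases")
  if (cc + dd == 0) stop("no evaluable controls")
  tab <- two_by_two(a, b, cc, dd)
  sens <- a / (a + b); spec <- dd / (cc + dd)
  structure(list(criterion = criterion, table = tab,
                 sensitivity = sens, specificity = spec,
                 c_statistic = (sens + spec) / 2,
                 p_value = fisher_exact(tab), n_excluded = n_excluded),
            class = "biomarker_result")
}

#' Evaluate a binary biomarker from printed 2x2 counts
#'
#' Same computation as [evaluate_binary()] when only the positivity counts
#' are available (a/(a+b) cases, c/(c+d) controls positive).
#'
#' @param t a [two_by_two()]
#' @param criterion label
#' @return `biomarker_result`
#' @export
evaluate_counts <- function(t, criterion = "criterion") {
  flags <- c(rep(TRUE, t$a), rep(FALSE, t$b), rep(TRUE, t$c), rep(FALSE, t$d))
  outcomes <- c(rep("NEC", t$a + t$b), rep("control", t$c + t$d))
  names(flags) <- names(outcomes) <- sprintf("i%03d", seq_along(flags))
  evaluate_binary(flags, outcomes, criterion)
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat(sprintf("%s: %d/%d cases, %d/%d controls positive | c = %.0f%%, sens %.0f%%, spec %.0f%%, p = %.3g\n",
              x$criterion, x$table$a, x$table$a + x$table$b, x$table$c,
              x$table$c + x$table$d, 100 * x$c_statistic,
              100 * x$sensitivity, 100 * x$specificity, x$p_value))
  invisible(x)
}

#' Urinary alanine:histidine ratio
#' @param alanine,histidine positive values (vectors allowed); or pass a
#'   `metabolite_records` data.frame as `alanine`
#' @return numeric ratio(s)
#' @export
alanine_histidine_ratio <- function(alanine, histidine = NULL) {
  if (is.data.frame(alanine)) {
    histidine <- alanine$histidine; alanine <- alanine$alanine
  }
  if (any(!is.finite(histidine)) || any(histidine <= 0))
    stop("histidine must be positive")
  alanine / histidine
}

#' ROC cut-point search for a continuous marker
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' values; the marker is positive when value > threshold. Returns the
#' threshold maximizing the c-statistic, ties broken toward the smallest
#' threshold.
#'
#' @param values named numeric vector per infant
#' @param outcomes named "NEC"/"control" vector
#' @param criterion label for the returned result
#' @return list(threshold, result = [evaluate_binary()] at that threshold)
#' @export
roc_cutpoint <- function(values, outcomes, criterion = "ROC cut-point") {
  u <- sort(unique(values))
  if (length(u) < 2) stop("all marker values identical; no cut-point")
  thr <- (u[-length(u)] + u[-1]) / 2
  cs <- vapply(thr, function(th) {
    evaluate_binary(stats::setNames(values > th, names(values)),
                    outcomes, criterion)$c_statistic
  }, 0)
  best <- thr[which.max(cs)]  # which.max takes the first (smallest) maximizer
  list(threshold = best,
       result = evaluate_binary(stats::setNames(values > best, names(values)),
                                outcomes, criterion))
}

#' The six-row biomarker report
#'
#' Evaluates, against NEC vs control outcomes (non-NEC deaths excluded), the
#' six predictors: (1) Firmicutes dysbiosis in days 4-9; (2) absence of
#' Propionibacterium in days 4-9; (3) Proteobacteria dysbiosis in days 10-16;
#' (4) either form of dysbiosis, restricted to infants with samples in both
#' windows; (5) criterion 2 AND 4, same restriction; (6) urinary
#' alanine:histidine ratio above the cut-point (fixed 4, or ROC-optimized),
#' using each infant's first urine sample in days 4-9. Denominators are
#' derived from per-criterion sample availability.
#'
#' @param calls a [classify_dysbiosis()] result
#' @param metabolites [metabolite_records()] (urine)
#' @param windows study windows
#' @param ratio_cutpoint numeric fixed cut-point (default 4) or `"roc"` to
#'   optimize in-sample
#' @return data.frame of class `biomarker_report`, one row per criterion,
#'   with the underlying `biomarker_result` list as attribute `results`
#' @export
table3_report <- function(calls, metabolites, windows = study_windows(),
                          ratio_cutpoint = 4) {
  cc <- calls[calls$group %in% c("NEC", "control"), , drop = FALSE]
  outcomes <- stats::setNames(cc$group, cc$infant_id)
  f <- function(x) stats::setNames(as.logical(x), cc$infant_id)

  res <- list(
    evaluate_binary(f(cc$firmicutes_dysbiosis_w1), outcomes,
                    "High Firmicutes dysbiosis (days 4-9)"),
    evaluate_binary(f(cc$propionibacterium_absent_w1), outcomes,
                    "No Propionibacterium (days 4-9)"),
    evaluate_binary(f(cc$proteobacteria_dysbiosis_w2), outcomes,
                    "High Proteobacteria dysbiosis (days 10-16)"),
    evaluate_binary(f(cc$either_dysbiosis), outcomes,
                    "Dysbiosis (criterion 1 or 3)"),
    evaluate_binary(f(cc$combined_criterion), outcomes,
                    "No Propionibacterium + dysbiosis"))

  # criterion 6: first urine sample per infant inside window 1
  m <- metabolites[metabolites$day_of_life >= windows$w1$first_day &
                     metabolites$day_of_life <= windows$w1$last_day, ,
                   drop = FALSE]
  m <- m[order(m$infant_id, m$day_of_life), , drop = FALSE]
  m <- m[!duplicated(m$infant_id), , drop = FALSE]
  m <- m[m$infant_id %in% cc$infant_id, , drop = FALSE]
  ratio <- stats::setNames(alanine_histidine_ratio(m), m$infant_id)
  thr <- ratio_cutpoint
  if (identical(ratio_cutpoint, "roc")) {
    rc <- roc_cutpoint(ratio, outcomes[names(ratio)],
                       "Urinary alanine:histidine ratio (ROC cut-point)")
    thr <- rc$threshold
    res[[6]] <- rc$result
  } else {
    res[[6]] <- evaluate_binary(stats::setNames(ratio > thr, names(ratio)),
                                outcomes[names(ratio)],
                                sprintf("Urinary alanine:histidine ratio >%g (days 4-9)", thr))
  }

  out <- do.call(rbind, lapply(seq_along(res), function(i) {
    r <- res[[i]]
    data.frame(criterion = i, description = r$criterion,
               nec_positive = r$table$a, nec_total = r$table$a + r$table$b,
               control_positive = r$table$c,
               control_total = r$table$c + r$table$d,
               p_value = r$p_value, c_statistic = r$c_statistic,
               sensitivity = r$sensitivity, specificity = r$specificity,
               n_excluded = r$n_excluded, stringsAsFactors = FALSE)
  }))
  attr(out, "results") <- res
  attr(out, "ratio_threshold") <- thr
  class(out) <- c("biomarker_report", "data.frame")
  out
}
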
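test_that("binary evaluation reproduces sensitivity/specificity/c identities", {
  r <- evaluate_counts(two_by_two(4, 5, 0, 18))
  expect_equal(r$sensitivity, 4 / 9)
  expect_equal(r$specificity, 1)
  expect_equal(r$c_statistic, (4 / 9 + 1) / 2)

  r2 <- evaluate_counts(two_by_two(7, 0, 4, 12))
  expect_equal(r2$c_statistic, 0.875)

  # uninformative predictor: everyone flagged
  flags <- setNames(rep(TRUE, 6), paste0("i", 1:6))
  outcomes <- setNames(rep(c("NEC", "control"), each = 3), paste0("i", 1:6))
  r3 <- evaluate_binary(flags, outcomes)
  expect_equal(r3$sensitivity, 1)
  expect_equal(r3$specificity, 0)
  expect_equal(r3$c_statistic, 0.5)

  # NA flags excluded and counted
  flags[5] <- NA
  r4 <- evaluate_binary(flags, outcomes)
  expect_equal(r4$n_excluded, 1)
  expect_equal(r4$table$c + r4$table$d, 2)

  expect_error(evaluate_binary(setNames(TRUE, "x"), setNames("NEC", "x")),
               "controls")
  expect_error(evaluate_binary(flags, setNames(rep("death", 6), names(flags))),
               "NEC/control")
})

test_that("the binary c-statistic equals the rank-based AUC", {
  set.seed(55)
  for (rep in 1:20) {
    n <- 12
    flags <- setNames(runif(n) > 0.5, paste0("i", 1:n))
    outcomes <- setNames(rep(c("NEC", "control"), each = n / 2),
                         paste0("i", 1:n))
    r <- tryCatch(evaluate_binary(flags, outcomes), error = function(e) NULL)
    if (is.null(r)) next
    x <- as.numeric(flags[outcomes == "NEC"])
    y <- as.numeric(flags[outcomes == "control"])
    auc <- mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$c_statistic, auc)
  }
})

test_that("fisher_exact agrees with the enumeration oracle over all margins <= 40", {
  set.seed(66)
  for (rep in 1:200) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || c + d == 0) next
    expect_equal(fisher_exact(two_by_two(a, b, c, d)),
                 oracle_fisher(a, b, c, d), tolerance = 1e-9)
  }
  expect_equal(fisher_exact(two_by_two(1, 1, 1, 1)), 1)
})

test_that("alanine:histidine ratio is guarded and vectorized", {
  expect_equal(alanine_histidine_ratio(3.34, 0.59), 3.34 / 0.59, tolerance = 1e-12)
  expect_equal(alanine_histidine_ratio(2, 2), 1)
  expect_true(alanine_histidine_ratio(4.1, 1.0) > 4)
  expect_error(alanine_histidine_ratio(1, 0), "positive")
  m <- metabolite_records("A", 5, 3.34, 0.59, 1)
  expect_equal(alanine_histidine_ratio(m), 3.34 / 0.59)
})

test_that("roc_cutpoint maximizes the c-statistic with smallest-threshold ties", {
  values <- setNames(c(5, 6, 7, 9, 1, 2, 3, 8), paste0("i", 1:8))
  outcomes <- setNames(rep(c("NEC", "control"), each = 4), paste0("i", 1:8))
  rc <- roc_cutpoint(values, outcomes)
  expect_gt(rc$threshold, 3); expect_lt(rc$threshold, 5)
  expect_equal(rc$result$sensitivity, 1)
  expect_equal(rc$result$specificity, 0.75)
  expect_equal(rc$result$c_statistic, oracle_roc_best_c(values, outcomes))

  # perfectly separated groups
  v2 <- setNames(c(10, 11, 1, 2), paste0("i", 1:4))
  o2 <- setNames(c("NEC", "NEC", "control", "control"), paste0("i", 1:4))
  expect_equal(roc_cutpoint(v2, o2)$result$c_statistic, 1)

  expect_error(roc_cutpoint(setNames(rep(1, 4), paste0("i", 1:4)), o2),
               "identical")

  # random instances vs exhaustive oracle
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(6:20, 1)
    v <- setNames(round(rnorm(n), 2), paste0("i", 1:n))
    o <- setNames(sample(rep(c("NEC", "control"), length.out = n)),
                  paste0("i", 1:n))
    if (length(unique(v)) < 2) next
    rc <- roc_cutpoint(v, o)
    expect_equal(rc$result$c_statistic, oracle_roc_best_c(v, o),
                 tolerance = 1e-12)
  }
})

test_that("the six-criterion report derives denominators from availability", {
  co <- generate_cohort(cohort_design(seed = 6))
  calls <- classify_dysbiosis(co$otu, co$taxonomy, co$samples)
  t3 <- table3_report(calls, co$metabolites)
  expect_equal(nrow(t3), 6)
  expect_equal(t3$criterion, 1:6)
  # criteria 4 and 5 are restricted to infants with both windows
  both <- sum(!is.na(calls$either_dysbiosis) &
                calls$group %in% c("NEC", "control"))
  expect_equal(t3$nec_total[4] + t3$control_total[4], both)
  expect_equal(t3$nec_total[5] + t3$control_total[5], both)
  # criterion 5 is never less specific than criterion 4
  expect_gte(t3$specificity[5], t3$specificity[4])
  # ROC mode returns a threshold
  t3r <- table3_report(calls, co$metabolites, ratio_cutpoint = "roc")
  expect_true(is.numeric(attr(t3r, "ratio_threshold")))
})

test_that("a cohort with planted perfect signal yields perfect criterion 5", {
  co <- generate_cohort(cohort_design(seed = 14))
  calls <- classify_dysbiosis(co$otu, co$taxonomy, co$samples)
  # construct the perfect-signal configuration: no control dysbiotic, no case
  # with Propionibacterium
  calls$proteobacteria_dysbiosis_w2[calls$group == "control"] <- FALSE
  calls$firmicutes_dysbiosis_w1[calls$group == "control"] <- FALSE
  both <- !is.na(calls$w1_sample) & !is.na(calls$w2_sample)
  calls$either_dysbiosis <- ifelse(both, calls$firmicutes_dysbiosis_w1 |
                                     calls$proteobacteria_dysbiosis_w2, NA)
  calls$combined_criterion <- ifelse(both, calls$propionibacterium_absent_w1 &
                                       calls$either_dysbiosis, NA)
  t3 <- table3_report(calls, co$metabolites)
  expect_equal(t3$sensitivity[5], 1)
  expect_equal(t3$specificity[5], 1)
})
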
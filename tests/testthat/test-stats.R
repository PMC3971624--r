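test_that("Kruskal-Wallis matches the rank-formula and permutation oracles", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  r <- kruskal_wallis(g)
  expect_equal(r$statistic,
               oracle_kw_h(unlist(g), rep(1:2, each = 3)), tolerance = 1e-12)
  # exact permutation p: 2 of the 20 group assignments are as extreme
  re <- kruskal_wallis(g, exact = TRUE)
  expect_equal(re$p_value, 0.1, tolerance = 1e-12)
  expect_equal(re$p_value,
               oracle_kw_perm_p(unlist(g), rep(1:2, each = 3)))

  # identical groups: no separation
  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")

  # random small instances vs the enumeration oracle
  set.seed(12)
  for (rep in 1:5) {
    x <- sample(1:20, 6)
    g2 <- rep(1:2, each = 3)
    r1 <- kruskal_wallis(split(x, g2), exact = TRUE)
    expect_equal(r1$p_value, oracle_kw_perm_p(x, g2), tolerance = 1e-12)
    expect_equal(r1$statistic, oracle_kw_h(x, g2), tolerance = 1e-12)
  }
})

test_that("two-group Kruskal-Wallis tracks the Wilcoxon rank-sum statistic", {
  set.seed(19)
  x <- rnorm(8); y <- rnorm(8) + 1
  h <- kruskal_wallis(list(x, y))$statistic
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  z <- qnorm(w$p.value / 2)
  expect_equal(h, z^2, tolerance = 1e-6)
})

test_that("Spearman matches the rank-formula oracle and rejects constants", {
  x <- c(1, 3, 7, 9)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(23)
  for (rep in 1:10) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(spearman_cor(a, b)$rho, oracle_spearman_rho(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "n >= 3")
})

test_that("BH adjustment follows the step-up rule and inflates element-wise", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed staggered case: p_(i) * m / i, cummin from the top
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bh_adjust(p), c(0.02, 0.0533333333333333, 0.0533333333333333, 0.8),
               tolerance = 1e-10)
  set.seed(3)
  q <- runif(20)
  expect_true(all(bh_adjust(q) >= q))
  expect_true(all(bh_adjust(q) <= 1))
  # order preserved
  expect_equal(order(bh_adjust(sort(q))), 1:20)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  # rejections at 0.05 equal the classic step-up rejection set
  m <- length(q)
  k <- max(c(0, which(sort(q) <= (seq_len(m) / m) * 0.05)))
  classic <- q <= if (k == 0) -1 else sort(q)[k]
  expect_equal(bh_adjust(q) <= 0.05, classic)
})

test_that("Welch t-test handles null, extreme and degenerate inputs", {
  same <- welch_t(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- welch_t(list(c(0, 0, 0, 1e-6), c(10, 10, 10, 10 + 1e-6)))
  expect_lt(far$p_value, 0.001)
  expect_error(welch_t(list(c(1, 1), c(2, 2))), "zero variance")
  expect_error(welch_t(list(1, 1:3)), "n >= 2")
  # agreement with a direct Welch computation
  set.seed(9)
  a <- rnorm(6); b <- rnorm(8, 1)
  r <- welch_t(list(a, b))
  se <- sqrt(var(a) / 6 + var(b) / 8)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 6)^2 / 5 + (var(b) / 8)^2 / 7)
  expect_equal(r$statistic, tstat, tolerance = 1e-12)
  expect_equal(r$df, df, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("tests are invariant under permutation of input order", {
  set.seed(30)
  x <- rnorm(9); y <- rnorm(9)
  p <- sample(9)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(x[p], y[p])$rho)
  g <- list(x[1:4], x[5:9])
  gp <- list(x[1:4][sample(4)], x[5:9][sample(5)])
  expect_equal(kruskal_wallis(g)$statistic, kruskal_wallis(gp)$statistic)
})

test_that("the metabolite report has the expected shape", {
  co <- generate_cohort(cohort_design(seed = 5))
  calls <- classify_dysbiosis(co$otu, co$taxonomy, co$samples)
  t2 <- table2_report(calls, co$metabolites)
  expect_equal(nrow(t2), 3 * (3 + 5))
  expect_setequal(unique(t2$metabolite), c("alanine", "histidine", "ratio"))
  sp <- t2[t2$type == "spearman", ]
  expect_true(all(abs(sp$estimate[!is.na(sp$estimate)]) <= 1))
  expect_true(all(t2$p_adjusted >= t2$p_value, na.rm = TRUE))
})

test_that("metabolites independent of communities show no strong correlation", {
  # null cohort: zero planted effect sizes
  hits <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_design(seed = 100 + s, alanine_shift = 0,
                                        histidine_shift = 0))
    calls <- classify_dysbiosis(co$otu, co$taxonomy, co$samples)
    t2 <- table2_report(calls, co$metabolites)
    sp <- t2[t2$type == "spearman", ]
    all(abs(sp$estimate[!is.na(sp$estimate)]) < 0.4)
  })
  expect_gte(mean(hits), 0.8)
})
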
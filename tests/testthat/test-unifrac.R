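test_that("rare-OTU filter keeps exactly the 2-sample / 5-read OTUs", {
  m <- rbind(s1 = c(100L, 2L, 3L, 1L, 0L),
             s2 = c(0L,   2L, 2L, 1L, 4L),
             s3 = c(0L,   0L, 0L, 2L, 5L))
  colnames(m) <- paste0("O", 1:5)
  t <- otu_table(m)
  f <- filter_rare_otus(t)
  # O1: 1 sample (removed); O2: 2 samples, 4 reads (removed);
  # O3: 2 samples, 5 reads (kept); O4: 3 samples, 4 reads (removed);
  # O5: 2 samples, 9 reads (kept)
  expect_equal(colnames(f), c("O3", "O5"))
  expect_equal(rownames(f), rownames(t))
  expect_error(filter_rare_otus(otu_table(rbind(s1 = c(O1 = 3L)))),
               "every OTU")
})

test_that("weighted UniFrac equals the two-leaf closed form and is zero on identity", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", p)
  tr <- read_tree(p)
  t <- otu_table(rbind(s1 = c(A = 1L, B = 0L), s2 = c(A = 0L, B = 1L),
                       s3 = c(A = 1L, B = 0L)))
  d <- weighted_unifrac(t, tr)
  expect_equal(d["s1", "s2"], 2)    # (b_A + b_B) * |1 - 0|
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s1"], 0)
  expect_equal(d, t(d))
})

test_that("weighted UniFrac agrees with the branch-enumeration oracle on random trees", {
  set.seed(202)
  max_err <- 0
  for (rep in 1:200) {
    tr <- random_otu_tree(sample(4:8, 1))
    t <- random_two_samples(tr)
    got <- weighted_unifrac(t, tr)["A", "B"]
    want <- oracle_unifrac(tr, t["A", ], t["B", ])
    max_err <- max(max_err, abs(got - want))
  }
  expect_lt(max_err, 1e-10)
})

test_that("weighted UniFrac satisfies the metric axioms on random instances", {
  set.seed(77)
  for (rep in 1:30) {
    tr <- random_otu_tree(6)
    n <- length(tr$tip.label)
    m <- matrix(rpois(3 * n, 6) + 1L, nrow = 3,
                dimnames = list(c("x", "y", "z"), tr$tip.label))
    d <- weighted_unifrac(otu_table(m), tr)
    expect_equal(diag(d), c(x = 0, y = 0, z = 0))
    expect_equal(d, t(d))
    expect_lte(d["x", "z"], d["x", "y"] + d["y", "z"] + 1e-12)
    expect_true(all(d >= 0))
  }
})

test_that("splitting an OTU across zero-length sibling leaves leaves UniFrac unchanged", {
  p1 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):0.5,C:1.5):0;", p1)
  tr1 <- read_tree(p1)
  p2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(((A1:0,A2:0):1,B:2):0.5,C:1.5):0;", p2)
  tr2 <- read_tree(p2)
  t1 <- otu_table(rbind(s1 = c(A = 6L, B = 2L, C = 2L),
                        s2 = c(A = 1L, B = 5L, C = 4L)))
  t2 <- otu_table(rbind(s1 = c(A1 = 4L, A2 = 2L, B = 2L, C = 2L),
                        s2 = c(A1 = 1L, A2 = 0L, B = 5L, C = 4L)))
  expect_equal(weighted_unifrac(t1, tr1)["s1", "s2"],
               weighted_unifrac(t2, tr2)["s1", "s2"])
})

test_that("an OTU with reads but no tree leaf is reported by name", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", p)
  tr <- read_tree(p)
  t <- otu_table(rbind(s1 = c(A = 1L, Z = 2L), s2 = c(A = 2L, Z = 1L)))
  expect_error(weighted_unifrac(t, tr), "Z")
})

test_that("raw weighted UniFrac matches phyloseq on binary trees", {
  skip_if_not_installed("phyloseq")
  set.seed(58)
  tr <- random_otu_tree(10)
  m <- matrix(rpois(50, 8) + 1L, nrow = 5,
              dimnames = list(paste0("s", 1:5), tr$tip.label))
  t <- otu_table(m)
  got <- weighted_unifrac(t, tr)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(unclass(t), taxa_are_rows = FALSE),
    phyloseq::phy_tree(tr))
  want <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = FALSE))
  expect_equal(unclass(got), want[rownames(got), colnames(got)],
               tolerance = 1e-8, ignore_attr = TRUE)
})
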
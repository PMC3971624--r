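test_that("cohort generation is deterministic and respects degenerate designs", {
  d <- cohort_design(n_nec1 = 2, n_nec2 = 2, n_controls = 5, n_deaths = 1,
                     seed = 4)
  c1 <- generate_cohort(d); c2 <- generate_cohort(d)
  expect_identical(unclass(c1$otu), unclass(c2$otu))
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$metabolites, c2$metabolites)

  all_ctl <- generate_cohort(cohort_design(n_nec1 = 0, n_nec2 = 0,
                                           n_controls = 6, n_deaths = 0,
                                           seed = 2))
  expect_true(all(all_ctl$samples$group == "control"))
  expect_true(all(is.na(all_ctl$samples$onset_day)))
})

test_that("design invariants are enforced", {
  expect_error(cohort_design(read_depth_range = c(1000, 5000)), "2000")
  expect_error(cohort_design(n_controls = -1), ">= 0")
  expect_error(cohort_design(otus_per_genus = 0), "otus_per_genus")
})

test_that("planted NEC-I communities are Bacilli-dominated in window 1", {
  co <- generate_cohort(cohort_design(seed = 1))
  w1 <- select_analysis_samples(co$samples, study_windows()$w1)
  nec1 <- co$truth$infant_id[co$truth$truth == "NEC-I"]
  ids <- w1$sample_id[w1$infant_id %in% nec1]
  bacilli <- aggregate_relative_abundance(co$otu, co$taxonomy, "class",
                                          "Bacilli")[ids]
  expect_gte(median(bacilli), 0.98)
  # cases never carry Propionibacterium
  propi <- aggregate_relative_abundance(co$otu, co$taxonomy, "genus",
                                        "Propionibacterium")
  case_samples <- co$samples$sample_id[co$samples$group == "NEC"]
  expect_true(all(propi[case_samples] == 0))
})

test_that("onset days fall in the planted ranges", {
  co <- generate_cohort(cohort_design(seed = 8))
  tr <- co$truth
  expect_true(all(tr$onset_day[tr$truth == "NEC-I"] %in% 7:21))
  expect_true(all(tr$onset_day[tr$truth == "NEC-II"] %in% 19:39))
  # every sample of a case precedes its onset
  s <- co$samples[co$samples$group != "control", ]
  expect_true(all(s$day_of_life < s$onset_day))
})

test_that("archetype draws match their Dirichlet means at the phylum level", {
  for (arch in default_archetypes()[c("control_w1", "nec1_w1", "nec2_w2")]) {
    t <- sample_archetype(arch, n = 200, depth = 3000, seed = 7)
    tax <- synthetic_taxonomy(3)
    shares <- sapply(c("Proteobacteria", "Firmicutes"), function(ph)
      mean(aggregate_relative_abundance(t, tax, "phylum", ph)))
    want <- archetype_phylum_means(arch)
    # Propionibacterium masking removes mass relative to the raw mean, so
    # compare against the mean with its weight handled explicitly
    expect_lt(abs(shares["Proteobacteria"] - want["Proteobacteria"]), 0.03)
    expect_lt(abs(shares["Firmicutes"] - want["Firmicutes"]), 0.03)
  }
})

test_that("the genus tree groups genera within phyla", {
  tr <- generate_genus_tree(otus_per_genus = 1, seed = 3)
  expect_equal(length(tr$tip.label), 10)
  d <- ape::cophenetic.phylo(tr)
  pool <- genus_pool()
  tip_phylum <- pool$phylum[match(sub("_1$", "", rownames(d)), pool$genus)]
  same <- d[outer(tip_phylum, tip_phylum, "==") & upper.tri(d)]
  diff <- d[outer(tip_phylum, tip_phylum, "!=") & upper.tri(d)]
  expect_lt(max(same), min(diff))

  tr3 <- generate_genus_tree(otus_per_genus = 3, seed = 3)
  expect_equal(length(tr3$tip.label), 30)
  # round-trips through Newick
  p <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr3, p)
  expect_setequal(read_tree(p)$tip.label, tr3$tip.label)
})

test_that("Propionibacterium presence is a structural per-infant trait", {
  co <- generate_cohort(cohort_design(n_controls = 40, seed = 21))
  calls <- classify_dysbiosis(co$otu, co$taxonomy, co$samples)
  ctl <- calls[calls$group == "control", ]
  present <- !ctl$propionibacterium_absent_w1
  # binomial(40, .56) within 4 sd, detection losses included
  expect_gt(mean(present), 0.56 - 4 * sqrt(0.56 * 0.44 / 40) - 0.05)
  expect_lt(mean(present), 0.56 + 4 * sqrt(0.56 * 0.44 / 40))
})
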
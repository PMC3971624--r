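make_typing_fixture <- function() {
  # 3 OTUs: one Enterobacter (Proteobacteria), one Staphylococcus
  # (Firmicutes), one Propionibacterium (Actinobacteria)
  tax <- taxonomy_map(
    c("ent1", "sta1", "pro1"),
    c("k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales; f__Enterobacteriaceae; g__Enterobacter",
      "k__Bacteria; p__Firmicutes; c__Bacilli; o__Bacillales; f__Staphylococcaceae; g__Staphylococcus",
      "k__Bacteria; p__Actinobacteria; c__Actinobacteria; o__Actinomycetales; f__Propionibacteriaceae; g__Propionibacterium"))
  m <- rbind(
    A_d5  = c(ent1 = 7L,   sta1 = 993L, pro1 = 0L),   # Firmicutes 0.993
    A_d12 = c(ent1 = 500L, sta1 = 500L, pro1 = 0L),
    B_d6  = c(ent1 = 800L, sta1 = 150L, pro1 = 50L),
    B_d11 = c(ent1 = 895L, sta1 = 105L, pro1 = 0L),   # Proteobacteria 0.895
    C_d5  = c(ent1 = 979L, sta1 = 20L,  pro1 = 1L))   # no window-2 sample
  t <- otu_table(m)
  rec <- sample_records(
    sample_id = rownames(m),
    infant_id = c("A", "A", "B", "B", "C"),
    day_of_life = c(5, 12, 6, 11, 5),
    group = c("NEC", "NEC", "control", "control", "control"),
    onset_day = c(20, 20, NA, NA, NA))
  list(t = t, tax = tax, rec = rec)
}

test_that("taxon aggregation sums assigned OTUs only", {
  f <- make_typing_fixture()
  firm <- aggregate_relative_abundance(f$t, f$tax, "phylum", "Firmicutes")
  expect_equal(unname(firm["A_d5"]), 0.993)
  # single-taxon sample at a rank
  one <- otu_table(rbind(s = c(ent1 = 10L)))
  expect_equal(unname(aggregate_relative_abundance(
    one, f$tax, "phylum", "Proteobacteria")), 1)
  # absent taxon -> 0
  expect_equal(unname(aggregate_relative_abundance(
    f$t, f$tax, "genus", "Propionibacterium")["A_d5"]), 0)
  expect_error(aggregate_relative_abundance(f$t, f$tax, "species", "x"),
               "unknown rank")
  # unassigned ranks contribute to no taxon: shares over phyla sum to the
  # assigned fraction
  tax2 <- taxonomy_map(c("ent1", "sta1", "pro1"),
                       c("k__Bacteria; p__Proteobacteria", "k__Bacteria",
                         "k__Bacteria; p__Actinobacteria"))
  s <- sapply(c("Proteobacteria", "Actinobacteria"), function(ph)
    aggregate_relative_abundance(f$t, tax2, "phylum", ph)["B_d6"])
  expect_equal(sum(s), 850 / 1000)
})

test_that("dysbiosis flags honour thresholds, windows and missing samples", {
  f <- make_typing_fixture()
  calls <- classify_dysbiosis(f$t, f$tax, f$rec)
  a <- calls[calls$infant_id == "A", ]
  b <- calls[calls$infant_id == "B", ]
  cc <- calls[calls$infant_id == "C", ]
  expect_true(a$firmicutes_dysbiosis_w1)         # 0.993 >= 0.98
  expect_false(b$proteobacteria_dysbiosis_w2)    # 0.895 < 0.90
  expect_true(is.na(cc$proteobacteria_dysbiosis_w2))  # no window-2 sample
  expect_true(is.na(cc$either_dysbiosis))        # requires both windows
  expect_true(a$propionibacterium_absent_w1)
  expect_false(b$propionibacterium_absent_w1)
  expect_equal(a$subtype, "NEC-I-like")
  # invariant: combined = propi-absent AND either
  both <- calls[!is.na(calls$either_dysbiosis), ]
  expect_equal(both$combined_criterion,
               both$propionibacterium_absent_w1 & both$either_dysbiosis)
})

test_that("classification is monotone in the thresholds", {
  f <- make_typing_fixture()
  hi <- classify_dysbiosis(f$t, f$tax, f$rec,
                           firmicutes_threshold = 0.98,
                           proteobacteria_threshold = 0.90)
  lo <- classify_dysbiosis(f$t, f$tax, f$rec,
                           firmicutes_threshold = 0.90,
                           proteobacteria_threshold = 0.80)
  for (col in c("firmicutes_dysbiosis_w1", "proteobacteria_dysbiosis_w2")) {
    was_true <- which(hi[[col]])
    expect_true(all(lo[[col]][was_true]))
  }
})

test_that("cluster-based sub-typing labels the planted clusters", {
  f <- make_typing_fixture()
  calls <- classify_dysbiosis(f$t, f$tax, f$rec)
  labels_w1 <- c(A_d5 = 1L, B_d6 = 2L, C_d5 = 2L)
  labels_w2 <- c(A_d12 = 1L, B_d11 = 2L)
  out <- assign_subtypes(calls, labels_w1, labels_w2)
  expect_equal(out$subtype_cluster[out$infant_id == "A"], "NEC-I-like")
  # no infant carries the w2 flag here, so no NEC-II cluster is labelled
  expect_true(all(out$subtype_cluster[out$infant_id != "A"] == "unclassified"))
})
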
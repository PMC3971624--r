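#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 4 NEC-I infants (Firmicutes dysbiosis,
# onset days 7-21), 6 NEC-II infants (Enterobacteriaceae dysbiosis, onset
# days 19-39), 18 controls (~80/20 Proteobacteria/Firmicutes,
# Propionibacterium in ~56%), 3 non-NEC deaths. One stool sample per infant
# per postnatal window (days 4-9, 10-16; pre-onset only) plus one urine
# metabolite record per infant.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(necdysbiosis))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

design <- cohort_design(seed = seed)
cohort <- generate_cohort(design)
write_cohort(cohort, "results/cohort")
write.table(cohort$truth, "results/cohort/truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(cohort)
cat(sprintf("seed: %d\n", seed))
cat(sprintf("samples written to results/cohort/ (%d stool, %d urine)\n",
            nrow(cohort$samples), nrow(cohort$metabolites)))
w1 <- select_analysis_samples(cohort$samples, study_windows()$w1)
cat(sprintf("window-1 analysis set: %d infants\n", nrow(w1)))
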
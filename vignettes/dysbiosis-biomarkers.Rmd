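---
title: "Early intestinal dysbiosis and biomarkers of necrotizing enterocolitis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early intestinal dysbiosis and biomarkers of necrotizing enterocolitis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necdysbiosis)
```

# The scientific problem

Necrotizing enterocolitis (NEC) is the most common intestinal emergency of
very preterm infants. This package implements an analysis pipeline for a
case–control design in which stool samples are collected over two early
postnatal windows — days of life 4–9 and 10–16, with birth counted as day 0 —
and profiled by 16S rRNA OTU counts, alongside urinary metabolites measured
on a relative NMR scale. The question is whether *dysbiosis*, extreme
single-taxon dominance of the early community, precedes NEC and can serve as
a predictive biomarker, and whether urinary metabolites act as non-invasive
surrogates.

The pipeline takes five inputs: an OTU count table (samples × OTUs), a
Greengenes-style taxonomy, a rooted phylogeny over the OTUs, sample metadata
(infant, day of life, outcome group, onset day for cases), and urinary
metabolite records. Because the raw sequence data are not part of this
artifact, a synthetic-cohort generator produces all five inputs with the
planted structure the analysis is designed to detect, so every stage is
testable end to end.

# Analysis-sample selection

Two rules protect validity. Statistical independence: at most one sample per
infant per window, the earliest in the window. Prediction rather than
description: for NEC cases (and non-NEC deaths) only samples collected
*strictly before* onset (death) are eligible; a sample on the onset day is
excluded. Day numbering is a convention the source data never fix; we count
birth as day 0 and treat the windows [4, 9] and [10, 16] as inclusive on
both ends. Both windows and the convention are configurable via `window()`.

# Community analysis

**Rare-OTU filter.** OTUs present in fewer than 2 samples or with fewer
than 5 reads in the whole table are removed before any between-sample
computation; per-sample proportions are renormalized afterwards.

**Alpha diversity.** Each sample is rarefied (subsampled without
replacement) to 2,000 reads — one draw per sample, seed logged — and two
indices are computed on the rarefied counts: bias-corrected Chao1 richness,
$S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))$ with $F_1$, $F_2$ the singleton
and doubleton counts (defined even when $F_2 = 0$; the classic
$F_1^2 / 2F_2$ form is available by flag), and the Simpson index reported as
$1 - \sum_i p_i^2$ so that larger means more diverse ($D$ and $1/D$
variants by flag). Samples shallower than the rarefaction depth are flagged
and excluded, never silently kept.

**Weighted UniFrac.** Between-sample dissimilarity is the raw
(unnormalized) weighted UniFrac distance
$d(A,B) = \sum_i b_i \, |p_i^A - p_i^B|$, summing over all branches $i$ of
the rooted tree, where $b_i$ is the branch length and $p_i^X$ the fraction
of sample $X$'s reads descending from the branch. The raw form is the
default because the source analysis names the metric without qualification;
the normalized variant (divided by the abundance-weighted mean root-to-tip
depth) is a flag. Proportions are computed after the rare-OTU filter,
matching the stated order of operations. The implementation is validated in
the test suite against a branch-enumeration oracle and against phyloseq on
binary trees; it handles multifurcating nodes directly.

**NMDS.** Ordination is non-metric multidimensional scaling in $k = 3$
dimensions minimizing Kruskal stress-1,
$100 \sqrt{\sum (\delta_{ij} - \hat d_{ij})^2 / \sum \delta_{ij}^2}$, where
$\delta$ are configuration distances and $\hat d$ is the monotone
(pool-adjacent-violators) regression of $\delta$ on the ranks of the input
dissimilarities, with the primary approach to ties (stable ordering; tied
dissimilarities may receive unequal fitted values). Each of `n_starts`
(default 20) random starts draws a standard-normal configuration; one
additional deterministic start uses classical metric scaling of the input
with a seeded $10^{-4}$ jitter to escape rank-deficient starts. Within a
start, steepest descent with step halving guarantees a non-increasing
stress trace (convergence at relative change $< 10^{-6}$ or 300
iterations). The best start's configuration is centered and rotated to
principal axes so variance is maximized along axis 1. The ×100 scale
matches how stress is conventionally reported for these data. Note that
stress-1 with a free monotone transform can reward near-degenerate
configurations on small noisy inputs; NMDS is used here for visualization
and diagnostics only — clustering operates on the UniFrac matrix itself.

**Ward clustering and the number of clusters.** Hierarchical clustering
uses the Ward minimum-variance objective: each merge minimizes the increase
in total within-cluster sum of squares, where a cluster's sum of squares is
computed from squared pairwise distances, $W(C) = \sum_{i<j \in C}
d_{ij}^2 / |C|$. This is realized by the Lance–Williams recurrence on
squared input distances (`stats::hclust`, `method = "ward.D"` on $d^2$),
which the tests verify against an explicit greedy sum-of-squares oracle.
Cluster-count diagnostics follow the classical pseudo-F (Calinski–Harabasz
form computed from the same squared-distance sums of squares) and pseudo-T²
(for the merge forming the $k$-partition from clusters $A$ and $B$:
$(W_{AB} - W_A - W_B) / ((W_A + W_B)/(n_A + n_B - 2))$; when two singletons
merge, the statistic is defined as the merge's sum-of-squares increase).
Reading a scree plot is human judgment; the package replaces it with a
stated deterministic rule in `choose_k()`: among local maxima of pseudo-F,
prefer those whose next merge (from $k$ to $k-1$) carries a pseudo-T² at or
above the median of all merges, and return the largest pseudo-F among them,
ties toward smaller $k$; a monotone-decreasing pseudo-F yields $k = 2$. A
per-window override is always available, because the original cluster
counts (4 in window 1; 3 plus an outlier in window 2) are properties of the
study's data, not of the rule. Size-1 clusters are reported as outliers
rather than special-cased.

# Dysbiosis classification and sub-types

Three per-infant flags are evaluated on unrarefied counts:

* **Firmicutes dysbiosis (window 1)**: phylum-level Firmicutes share
  ≥ 0.98 in the window-1 analysis sample;
* **Proteobacteria dysbiosis (window 2)**: phylum-level Proteobacteria
  share ≥ 0.90 in the window-2 analysis sample;
* **Propionibacterium absence (window 1)**: fewer than 1 read (configurable
  floor) of the genus in the window-1 sample.

A flag whose window lacks a sample is `NA`, not `FALSE`; the derived flags
`either_dysbiosis` (1 OR 3) and `combined_criterion` (absence AND either)
are only defined for infants with samples in both windows, which is also
how the per-criterion denominators arise. Sub-types are assigned from the
clustering, mirroring how the original analysis read its ordinations: the
window-1 cluster holding the majority of Firmicutes-flagged infants is
NEC-I-like; when any infant carries the window-2 flag, the window-2
non-singleton cluster with the highest median Enterobacteriaceae share is
NEC-II-like; window-1 membership takes precedence. A purely threshold-based
sub-type is also reported (`subtype` vs `subtype_cluster`).

# Biomarker evaluation

Each binary criterion is summarized by its 2×2 table against NEC vs control
outcomes (non-NEC deaths are retained in ordination as a secondary
comparator but excluded here), sensitivity $a/(a+b)$, specificity
$d/(c+d)$, and the *c-statistic* $(\text{sens} + \text{spec})/2$ — the area
under the two-point ROC curve of a binary predictor. This identity is the
definition used for the published predictive values: it reproduces all six
printed values from the printed counts, which no other standard summary
(accuracy, PPV, NPV) does. P-values are two-sided Fisher exact tests under
the point-probability ordering (the sum of hypergeometric probabilities of
tables no more probable than the observed one, with relative tolerance
1e-7 for ties) — the convention that reproduces the printed 0.007 / 0.009 /
0.001 values, as opposed to doubling the one-sided tail.

For the continuous urinary marker, the alanine:histidine ratio, positivity
is strictly-greater-than the cut-point. `roc_cutpoint()` scans the
midpoints between consecutive sorted unique values, maximizes the
c-statistic and breaks ties toward the smallest threshold; the pipeline
default uses the fixed cut-point 4, with in-sample ROC optimization as an
option (the original cut-point was itself in-sample, so the same optimism
applies and is documented rather than removed).

Metabolite associations use one value per infant (the first urine sample in
window 1): Spearman correlations (Pearson on mid-ranks, t approximation
with $n-2$ df; constant input is an error rather than $\rho = 0$) of each
of alanine, histidine and the ratio against window-1 Firmicutes,
Proteobacteria and Propionibacterium shares, and Kruskal–Wallis contrasts
(tie-corrected H, chi-squared approximation by default, exact enumeration
by flag at small n) across five groupings: window-1 cluster I vs rest,
window-2 cluster II vs rest, and NEC / NEC-I / NEC-II vs rest excluding
deaths. Benjamini–Hochberg adjustment is provided as a column. Welch
t-tests are available for two-group comparisons of metabolites; the
original dual t-test + GEE analysis is reduced to the t-test path because
the one-sample-per-infant restriction removes the repeated-measures
motivation for GEE.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
consumes — not reads, sequencing error, chimeras or primer bias. Counts are
Dirichlet-multinomial: each sample draws genus-level proportions from a
Dirichlet whose mean is an *archetype* over a fixed ten-genus pool
(Enterobacter, Escherichia; Staphylococcus, Enterococcus, Leuconostoc,
Lactococcus, Streptococcus, Clostridium; Propionibacterium,
Bifidobacterium) and whose total concentration controls overdispersion,
then a multinomial at a uniform 3,000–6,000 read depth (the lower bound
stays above the 2,000-read rarefaction depth by construction). Genus
weights are split over `otus_per_genus` OTUs in decreasing halves so some
OTUs are rare and Chao1 has singletons to work with.

Default archetypes encode the study conditions: controls at roughly 78%
Proteobacteria / 19% Firmicutes in window 1 drifting to ~84% Proteobacteria
in window 2 (concentrations 12 and 10, giving the substantial
infant-to-infant spread that makes ~30–40% of controls exceed the 0.90
Proteobacteria threshold, as observed in the source cohort); a
Firmicutes-dominated archetype at mean Bacilli share ≈ 0.995 (concentration
600 — the sub-group is reported with median above 99% and all members at or
above 98%); an Enterobacteriaceae-dominated archetype at mean ≈ 0.975
(concentration 400); and a less extreme Bacilli-heavy archetype for the
non-NEC deaths, which co-located with the Firmicutes sub-group in the
original ordination. Propionibacterium presence is a per-infant Bernoulli
trait (probability 0.56 in controls and 0.2 in deaths, 0 in cases) masking
its Dirichlet weight, yielding true structural zeros — the biomarker is
presence/absence, not abundance; its control weight (0.05) is set so that
detection at the simulated depths tracks the planted Bernoulli closely.
Onset days are uniform on 7–21 (NEC-I), 19–39 (NEC-II) and 10–40 (deaths);
window days are drawn uniformly inside each window subject to preceding
onset, so every NEC-I infant has a pre-onset window-1 sample and every
NEC-II infant a pre-onset window-2 sample, while later samples may be
censored by onset — reproducing the varying per-criterion denominators.

Metabolites are log-normal (noise sd 0.35 on the log scale) with
infant-level coupling: log-alanine increases with the infant's realized
window-1 Firmicutes share (default shift 1.1 per unit share above the
control mean — anchored to the observed medians, ~1.5 in controls vs ~3.3
under Firmicutes dominance); log-histidine decreases for NEC-II infants in
proportion to days between urine collection and onset (default shift 1.0
per 30 days, anchoring the NEC-II median near 0.25 vs 0.52 elsewhere and
producing the strong inverse association with time-to-onset); pyridoxine
tracks alanine weakly. Only orderings and signs of the published metabolite
medians are meaningful — they are on an instrument-specific relative scale —
so tests assert sign patterns, not values.

What passing tests on these cohorts do **not** show: recovery of
the published real-data magnitudes (Chao1 medians, abundance medians,
metabolite medians, the published stress value of a particular ordination),
robustness to sequencing artifacts, or transferability of the in-sample ROC
cut-point. Those quantities depend on the original data and instruments and
are deliberately outside the synthetic conditions.

# Numerical choices and degenerate inputs

* Seeds: every stochastic stage derives its seed from the master seed by a
  fixed integer hash (`derive_seed()`), so adding a stage never shifts
  another stage's randomness; generators save and restore the caller's RNG
  state.
* Rarefaction uses one draw per sample; an infeasible depth is an explicit
  error upstream and a `depth_ok = FALSE` flag in the alpha table.
* `filter_rare_otus()` errors when it would remove every OTU (ordination
  impossible) or leave a sample empty.
* NMDS errors on non-symmetric or all-zero dissimilarities and on
  $n < k + 1$; stress on a degenerate all-equal configuration is defined
  as 1 (×100: 100).
* Ward diagnostics report `Inf` pseudo-F when all within-cluster sums of
  squares are zero (duplicate points), and zero-distance duplicates merge
  first at height 0.
* Fisher's test, Kruskal–Wallis, Spearman, BH and Welch delegate to the
  corresponding base R routines (`fisher.test`, `kruskal.test`, `cor.test`,
  `p.adjust`, `t.test`) behind the package's interfaces, with the package
  enforcing the stricter contracts (constant-input errors, p-value domain
  checks); each is cross-validated against an independent enumeration or
  closed-form oracle in the test suite.

# Problem sizes used in the checks

The stochastic acceptance checks run the full pipeline on 20 cohorts at the
default design (4 NEC-I, 6 NEC-II, 18 controls, 3 deaths; ~55 samples, 30
OTUs), with 5 NMDS starts in the scripted runs — the ordination does not
feed the clustering or classification, so extra starts only refine the
reported stress. Oracle suites use 200 random 4–8-leaf trees for UniFrac,
n ≤ 8 for the Ward oracle, n ≤ 7 for exact permutation enumeration, and
margins ≤ 40 for the Fisher enumeration.

# Known limitations

* The c-statistic applies to binary predictors; no confidence intervals are
  reported for sensitivity/specificity (none were published).
* The ROC cut-point is optimized and evaluated in-sample.
* `choose_k()` is a deterministic stand-in for expert scree reading; on
  diffuse data its pseudo-F curve can be nearly flat, which is why the
  override exists and why sub-type labels are anchored to flagged infants
  rather than to a particular k.
* The generator plants independent Dirichlet draws per sample; real
  longitudinal stool series are autocorrelated within infants beyond the
  archetype level.
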
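Package: necdysbiosis
Title: Early Intestinal Dysbiosis and Biomarkers of Necrotizing Enterocolitis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for inferring early intestinal dysbiosis in
    preterm infants and evaluating microbial and urinary-metabolite biomarkers
    of necrotizing enterocolitis (NEC). From per-sample OTU counts, a
    phylogeny, and urinary metabolite values it computes rarefied alpha
    diversity (Chao1, Simpson), weighted UniFrac distances, non-metric
    multidimensional scaling with Kruskal stress, Ward minimum-variance
    clustering with pseudo-F/pseudo-T2 diagnostics, dysbiosis sub-type calls
    (Firmicutes-dominated and Proteobacteria-dominated), and 2x2 biomarker
    evaluation (sensitivity, specificity, c-statistic, exact tests) including
    the urinary alanine:histidine ratio. A synthetic-cohort generator with
    planted community structure supports testing every stage without
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
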
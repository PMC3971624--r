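# Synthetic cohorts with planted dysbiosis structure.
#
# The generator emulates the statistical structure of an early-life preterm
# gut cohort: two postnatal sampling windows (days 4-9 and 10-16), control
# communities of roughly 80% Proteobacteria / 20% Firmicutes, a
# Firmicutes-dominated (class Bacilli, >= 98%) sub-group preceding early NEC,
# a Proteobacteria-dominated (family Enterobacteriaceae, >= 90%) sub-group
# preceding late NEC, Propionibacterium present in about half of controls and
# in no cases, and urinary metabolite shifts coupled to the communities
# (alanine up with Firmicutes dominance; histidine down, scaling with
# days-to-onset, in the Proteobacteria sub-group). Counts are
# Dirichlet-multinomial; it does not simulate reads, sequencing error or
# chimeras.

.GENUS_TAX <- data.frame(
  genus  = c("Enterobacter", "Escherichia", "Staphylococcus", "Enterococcus",
             "Leuconostoc", "Lactococcus", "Streptococcus", "Clostridium",
             "Propionibacterium", "Bifidobacterium"),
  family = c("Enterobacteriaceae", "Enterobacteriaceae", "Staphylococcaceae",
             "Enterococcaceae", "Leuconostocaceae", "Streptococcaceae",
             "Streptococcaceae", "Clostridiaceae", "Propionibacteriaceae",
             "Bifidobacteriaceae"),
  order  = c("Enterobacteriales", "Enterobacteriales", "Bacillales",
             "Lactobacillales", "Lactobacillales", "Lactobacillales",
             "Lactobacillales", "Clostridiales", "Actinomycetales",
             "Bifidobacteriales"),
  class  = c("Gammaproteobacteria", "Gammaproteobacteria", "Bacilli",
             "Bacilli", "Bacilli", "Bacilli", "Bacilli", "Clostridia",
             "Actinobacteria", "Actinobacteria"),
  phylum = c("Proteobacteria", "Proteobacteria", "Firmicutes", "Firmicutes",
             "Firmicutes", "Firmicutes", "Firmicutes", "Firmicutes",
             "Actinobacteria", "Actinobacteria"),
  stringsAsFactors = FALSE)

#' The fixed genus pool of the synthetic cohort
#' @return data.frame with genus, family, order, class, phylum
#' @export
genus_pool <- function() .GENUS_TAX

#' Community archetype
#'
#' Dirichlet concentration weights over the ten-genus pool, plus the
#' probability that Propionibacterium is present at all (a per-infant
#' Bernoulli mask producing true structural zeros: the biomarker of interest
#' is its presence/absence, not its abundance).
#'
#' @param name archetype label
#' @param weights named numeric vector over `genus_pool()$genus`; relative
#'   Dirichlet means (need not sum to 1)
#' @param concentration total Dirichlet concentration (larger = less
#'   sample-to-sample overdispersion)
#' @param propionibacterium_presence_prob probability in \[0,1\]
#' @export
archetype <- function(name, weights, concentration,
                      propionibacterium_presence_prob) {
  stopifnot(all(names(weights) %in% .GENUS_TAX$genus))
  w <- stats::setNames(numeric(nrow(.GENUS_TAX)), .GENUS_TAX$genus)
  w[names(weights)] <- weights
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0 with at least one > 0")
  p <- propionibacterium_presence_prob
  if (!is.finite(p) || p < 0 || p > 1) stop("presence prob must be in [0,1]")
  if (!is.finite(concentration) || concentration <= 0)
    stop("concentration must be > 0")
  structure(list(name = name, weights = w / sum(w),
                 concentration = concentration,
                 propionibacterium_presence_prob = p),
            class = "archetype")
}

#' Expected phylum shares of an archetype
#' @param arch an [archetype()]
#' @return named numeric vector of Dirichlet-mean phylum shares
#' @export
archetype_phylum_means <- function(arch) {
  tapply(arch$weights, .GENUS_TAX$phylum, sum)
}

#' Default archetypes of the study conditions
#'
#' Controls: ~78% Proteobacteria / ~19% Firmicutes in days 4-9, drifting to
#' ~84% Proteobacteria in days 10-16, Propionibacterium present in 56% of
#' infants. NEC-I (window 1): >= 98% Firmicutes, class Bacilli, dominated by
#' Staphylococcus and Enterococcus. NEC-II (window 2): >= 90% Proteobacteria,
#' family Enterobacteriaceae (Enterobacter, Escherichia). Non-NEC deaths:
#' Bacilli-heavy but less extreme. Cases never carry Propionibacterium.
#'
#' @return named list of archetypes
#' @export
default_archetypes <- function() {
  list(
    control_w1 = archetype("control_w1", c(
      Enterobacter = 0.44, Escherichia = 0.31, Staphylococcus = 0.06,
      Enterococcus = 0.05, Leuconostoc = 0.015, Lactococcus = 0.015,
      Streptococcus = 0.04, Clostridium = 0.01, Propionibacterium = 0.05,
      Bifidobacterium = 0.01), concentration = 12, 0.56),
    control_w2 = archetype("control_w2", c(
      Enterobacter = 0.495, Escherichia = 0.32, Staphylococcus = 0.04,
      Enterococcus = 0.035, Leuconostoc = 0.01, Lactococcus = 0.01,
      Streptococcus = 0.03, Clostridium = 0.01, Propionibacterium = 0.04,
      Bifidobacterium = 0.01), concentration = 10, 0.56),
    nec1_w1 = archetype("nec1_w1", c(
      Staphylococcus = 0.52, Enterococcus = 0.45, Streptococcus = 0.02,
      Leuconostoc = 0.003, Lactococcus = 0.002, Clostridium = 0.001,
      Enterobacter = 0.002, Escherichia = 0.001, Bifidobacterium = 0.001),
      concentration = 600, 0),
    nec2_w2 = archetype("nec2_w2", c(
      Enterobacter = 0.62, Escherichia = 0.355, Staphylococcus = 0.005,
      Enterococcus = 0.005, Streptococcus = 0.008, Leuconostoc = 0.001,
      Lactococcus = 0.001, Clostridium = 0.003, Bifidobacterium = 0.002),
      concentration = 400, 0),
    death_w1 = archetype("death_w1", c(
      Staphylococcus = 0.45, Enterococcus = 0.35, Streptococcus = 0.05,
      Enterobacter = 0.08, Escherichia = 0.05, Clostridium = 0.01,
      Propionibacterium = 0.005, Bifidobacterium = 0.005),
      concentration = 30, 0.2)
  )
}

#' Cohort design
#'
#' Parameterizes [generate_cohort()]. Defaults are the study conditions:
#' 4 NEC-I infants (onset days 7-21), 6 NEC-II infants (onset days 19-39),
#' 18 controls, 3 non-NEC deaths; read depths uniform on 3,000-6,000 (so a
#' 2,000-read rarefaction is always possible); metabolite effect sizes
#' calibrated to the observed medians (control alanine ~1.5 vs ~3.3 under
#' Firmicutes dominance; histidine ~0.52 vs ~0.25 in the Proteobacteria
#' sub-group).
#'
#' @param n_nec1,n_nec2,n_controls,n_deaths non-negative infant counts
#' @param read_depth_range integer c(lo, hi), lo >= 2000
#' @param otus_per_genus integer >= 1
#' @param seed integer master seed for the cohort draw
#' @param alanine_shift added to log-alanine per unit window-1 Firmicutes
#'   share above the control mean
#' @param histidine_shift subtracted from log-histidine per 30 days between
#'   urine collection and onset, NEC-II infants only
#' @param noise_sdlog log-normal noise sd for metabolites
#' @param concentration_scale multiplier on archetype concentrations
#'   (>1 = tighter communities)
#' @return list of class `cohort_design`
#' @export
cohort_design <- function(n_nec1 = 4, n_nec2 = 6, n_controls = 18,
                          n_deaths = 3, read_depth_range = c(3000L, 6000L),
                          otus_per_genus = 3, seed = 1,
                          alanine_shift = 1.1, histidine_shift = 1.0,
                          noise_sdlog = 0.35, concentration_scale = 1) {
  d <- list(n_nec1 = as.integer(n_nec1), n_nec2 = as.integer(n_nec2),
            n_controls = as.integer(n_controls), n_deaths = as.integer(n_deaths),
            read_depth_range = as.integer(read_depth_range),
            otus_per_genus = as.integer(otus_per_genus),
            seed = as.integer(seed), alanine_shift = alanine_shift,
            histidine_shift = histidine_shift, noise_sdlog = noise_sdlog,
            concentration_scale = concentration_scale)
  if (any(unlist(d[1:4]) < 0)) stop("infant counts must be >= 0")
  if (length(d$read_depth_range) != 2 || d$read_depth_range[1] < 2000 ||
      d$read_depth_range[1] > d$read_depth_range[2])
    stop("read_depth_range must be c(lo, hi) with lo >= 2000")
  if (d$otus_per_genus < 1) stop("otus_per_genus must be >= 1")
  if (!all(is.finite(c(d$alanine_shift, d$histidine_shift, d$noise_sdlog,
                       d$concentration_scale))) || d$noise_sdlog < 0 ||
      d$concentration_scale <= 0)
    stop("effect sizes must be finite (noise_sdlog >= 0, scale > 0)")
  class(d) <- "cohort_design"
  d
}

# run expr with a local RNG seeded at `seed`, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# per-OTU Dirichlet alphas for an archetype; weight of a genus is split over
# its OTUs in decreasing halves so some OTUs are rare (Chao1 has singletons)
.otu_alphas <- function(arch, otus_per_genus, propi_present, scale = 1) {
  split <- 2^-(seq_len(otus_per_genus) - 1)
  split <- split / sum(split)
  w <- arch$weights
  if (!propi_present) w["Propionibacterium"] <- 0
  alpha <- as.vector(outer(split, w * arch$concentration * scale))
  names(alpha) <- as.vector(outer(seq_len(otus_per_genus), names(w),
                                  function(i, g) paste0(g, "_", i)))
  alpha
}

.rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# one Dirichlet-multinomial community draw
.draw_counts <- function(alpha, depth) {
  p <- .rdirichlet1(alpha)
  as.integer(stats::rmultinom(1, size = depth, prob = p))
}

#' Draw repeated communities from one archetype
#'
#' Mainly for calibration checks: `n` independent Dirichlet-multinomial
#' draws at fixed depth, Propionibacterium masked per draw.
#'
#' @param arch an [archetype()]
#' @param n number of samples
#' @param depth reads per sample
#' @param otus_per_genus OTUs per genus
#' @param seed integer
#' @return [otu_table()] with `n` rows
#' @export
sample_archetype <- function(arch, n, depth, otus_per_genus = 3, seed = 1) {
  with_local_seed(seed, {
    counts <- t(vapply(seq_len(n), function(i) {
      present <- stats::runif(1) < arch$propionibacterium_presence_prob
      .draw_counts(.otu_alphas(arch, otus_per_genus, present), depth)
    }, integer(otus_per_genus * nrow(.GENUS_TAX))))
    rownames(counts) <- sprintf("%s_s%03d", arch$name, seq_len(n))
    colnames(counts) <- names(.otu_alphas(arch, otus_per_genus, TRUE))
    otu_table(counts)
  })
}

#' Taxonomy map for the synthetic OTU set
#' @param otus_per_genus OTUs per genus
#' @return a `taxonomy_map` over all synthetic OTU ids
#' @export
synthetic_taxonomy <- function(otus_per_genus = 3) {
  g <- .GENUS_TAX[rep(seq_len(nrow(.GENUS_TAX)), each = otus_per_genus), ]
  ids <- paste0(g$genus, "_", rep(seq_len(otus_per_genus), nrow(.GENUS_TAX)))
  lin <- sprintf("k__Bacteria; p__%s; c__%s; o__%s; f__%s; g__%s",
                 g$phylum, g$class, g$order, g$family, g$genus)
  taxonomy_map(ids, lin)
}

#' Generate the synthetic phylogeny over the genus pool
#'
#' Rooted tree with one internal node per phylum and one per genus: OTUs of a
#' genus attach to the genus node, genera of a phylum to the phylum node, and
#' phyla to the root. Branch lengths are base lengths (phylum 0.40, genus
#' 0.25, leaf 0.10) plus a small uniform jitter so no two branches are
#' exactly equal; within-phylum leaf pairs are therefore always closer than
#' cross-phylum pairs. Deterministic given the seed.
#'
#' @param otus_per_genus OTUs per genus (>= 1)
#' @param seed integer
#' @return validated `phylo` tree whose leaves are the synthetic OTU ids
#' @export
generate_genus_tree <- function(otus_per_genus = 3, seed = 1) {
  stopifnot(otus_per_genus >= 1)
  with_local_seed(seed, {
    j <- function() stats::runif(1, 0, 0.05)
    genus_nwk <- vapply(seq_len(nrow(.GENUS_TAX)), function(i) {
      g <- .GENUS_TAX$genus[i]
      leaves <- paste0(g, "_", seq_len(otus_per_genus), ":",
                       format(0.10 + vapply(seq_len(otus_per_genus),
                                            function(k) j(), 0), digits = 8))
      if (otus_per_genus == 1)
        # single OTU: collapse the genus node into one longer pendant branch
        paste0(leaves, collapse = ",")
      else paste0("(", paste0(leaves, collapse = ","), ")")
    }, "")
    phyla <- unique(.GENUS_TAX$phylum)
    phylum_nwk <- vapply(phyla, function(ph) {
      idx <- which(.GENUS_TAX$phylum == ph)
      kids <- paste0(genus_nwk[idx], ":", format(0.25 + vapply(idx, function(k) j(), 0),
                                                 digits = 8))
      paste0("(", paste0(kids, collapse = ","), ")")
    }, "")
    nwk <- paste0("(", paste0(phylum_nwk, ":",
                              format(0.40 + vapply(phyla, function(p) j(), 0),
                                     digits = 8), collapse = ","), "):0;")
    validate_tree(ape::read.tree(text = nwk))
  })
}

#' Generate a full synthetic cohort
#'
#' Draws, per infant, one stool sample per postnatal window (days 4-9 and
#' 10-16; only samples collected strictly before NEC onset / death exist),
#' plus one urine metabolite record at the infant's window-1 day. NEC-I
#' infants draw window-1 communities from the Firmicutes-dominated archetype
#' and onset days uniform on 7-21; NEC-II infants draw window-2 communities
#' from the Enterobacteriaceae-dominated archetype and onset days uniform on
#' 19-39; controls and (less extreme) deaths draw from the control/death
#' archetypes. Propionibacterium presence is a per-infant Bernoulli trait
#' (0.56 in controls, 0 in cases). Fully reproducible from `design$seed`.
#'
#' @param design a [cohort_design()]
#' @param archetypes archetype list, see [default_archetypes()]
#' @return list of class `cohort` with elements `otu` ([otu_table()]),
#'   `taxonomy`, `tree`, `samples` ([sample_records()]),
#'   `metabolites` ([metabolite_records()]), `design`, and `truth`
#'   (data.frame of planted per-infant labels)
#' @export
generate_cohort <- function(design = cohort_design(),
                            archetypes = default_archetypes()) {
  if (!inherits(design, "cohort_design")) design <- do.call(cohort_design, design)
  a <- archetypes
  with_local_seed(design$seed, {
    infants <- data.frame(
      infant_id = c(sprintf("I%02d", seq_len(design$n_nec1 + design$n_nec2)),
                    sprintf("C%02d", seq_len(design$n_controls)),
                    sprintf("D%02d", seq_len(design$n_deaths))),
      truth = c(rep("NEC-I", design$n_nec1), rep("NEC-II", design$n_nec2),
                rep("control", design$n_controls),
                rep("death", design$n_deaths)),
      stringsAsFactors = FALSE)
    n_inf <- nrow(infants)
    if (n_inf == 0) stop("design yields no infants")

    tax <- synthetic_taxonomy(design$otus_per_genus)
    pick <- function(v) if (length(v) == 1) v else sample(v, 1)
    depth <- function() pick(design$read_depth_range[1]:design$read_depth_range[2])

    rows <- list(); counts <- list(); met <- list()
    truth <- infants; truth$onset_day <- NA_integer_
    truth$propionibacterium_present <- FALSE
    truth$firmicutes_share_w1 <- NA_real_

    for (i in seq_len(n_inf)) {
      id <- infants$infant_id[i]; tr <- infants$truth[i]
      onset <- switch(tr,
                      "NEC-I" = pick(7:21), "NEC-II" = pick(19:39),
                      "death" = pick(10:40), NA_integer_)
      group <- switch(tr, "NEC-I" = , "NEC-II" = "NEC",
                      "death" = "non_NEC_death", "control")
      propi_prob <- switch(tr, "control" = a$control_w1$propionibacterium_presence_prob,
                           "death" = a$death_w1$propionibacterium_presence_prob, 0)
      propi <- stats::runif(1) < propi_prob
      arch_w1 <- switch(tr, "NEC-I" = a$nec1_w1, "death" = a$death_w1, a$control_w1)
      arch_w2 <- switch(tr, "NEC-II" = a$nec2_w2, a$control_w2)

      d1_max <- if (is.na(onset)) 9L else min(9L, onset - 1L)
      day1 <- pick(4:d1_max)
      day2 <- pick(10:16)
      have2 <- is.na(onset) || day2 < onset

      s1 <- .draw_counts(.otu_alphas(arch_w1, design$otus_per_genus, propi,
                                     design$concentration_scale), depth())
      counts[[length(counts) + 1]] <- s1
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("%s_d%02d", id, day1), infant_id = id,
        day_of_life = day1, group = group, onset_day = onset,
        stringsAsFactors = FALSE)
      if (have2) {
        s2 <- .draw_counts(.otu_alphas(arch_w2, design$otus_per_genus, propi,
                                       design$concentration_scale), depth())
        counts[[length(counts) + 1]] <- s2
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_d%02d", id, day2), infant_id = id,
          day_of_life = day2, group = group, onset_day = onset,
          stringsAsFactors = FALSE)
      }

      # metabolites: one urine record at the window-1 stool day
      firm <- sum(s1[tax$phylum == "Firmicutes"]) / sum(s1)
      mu_ala <- log(1.5) + design$alanine_shift * (firm - 0.19)
      mu_his <- log(0.52)
      if (tr == "NEC-II")
        mu_his <- mu_his - design$histidine_shift * (onset - day1) / 30
      mu_pyr <- log(1.0) + 0.6 * (firm - 0.19)
      met[[length(met) + 1]] <- data.frame(
        infant_id = id, day_of_life = day1,
        alanine = stats::rlnorm(1, mu_ala, design$noise_sdlog),
        histidine = stats::rlnorm(1, mu_his, design$noise_sdlog),
        pyridoxine = stats::rlnorm(1, mu_pyr, design$noise_sdlog),
        stringsAsFactors = FALSE)

      truth$onset_day[i] <- onset
      truth$propionibacterium_present[i] <- propi
      truth$firmicutes_share_w1[i] <- firm
    }

    meta <- do.call(rbind, rows)
    cm <- do.call(rbind, counts)
    rownames(cm) <- meta$sample_id
    colnames(cm) <- names(.otu_alphas(a$control_w1, design$otus_per_genus, TRUE))
    metdf <- do.call(rbind, met)

    cohort <- list(
      otu = otu_table(cm),
      taxonomy = tax,
      tree = generate_genus_tree(design$otus_per_genus,
                                 seed = design$seed + 7919L),
      samples = sample_records(meta$sample_id, meta$infant_id,
                               meta$day_of_life, meta$group, meta$onset_day),
      metabolites = metabolite_records(metdf$infant_id, metdf$day_of_life,
                                       metdf$alanine, metdf$histidine,
                                       metdf$pyridoxine),
      design = design, truth = truth)
    class(cohort) <- "cohort"
    cohort
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d infants, %d samples, %d OTUs (seed %d)\n",
              nrow(x$truth), nrow(x$samples), ncol(x$otu), x$design$seed))
  print(table(x$truth$truth))
  invisible(x)
}

#' Write a cohort's five files into a directory
#' @param cohort a [generate_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(cohort$otu, file.path(dir, "otu_table.tsv"))
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tree(cohort$tree, file.path(dir, "tree.nwk"))
  write_sample_metadata(cohort$samples, file.path(dir, "samples.tsv"))
  write_metabolites(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory containing the five files
#' @return list with otu, taxonomy, tree, samples, metabolites
#' @export
read_cohort <- function(dir) {
  out <- list(otu = read_otu_table(file.path(dir, "otu_table.tsv")),
              taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
              tree = read_tree(file.path(dir, "tree.nwk")),
              samples = read_sample_metadata(file.path(dir, "samples.tsv")),
              metabolites = read_metabolites(file.path(dir, "metabolites.tsv")))
  check_consistency(out$otu, out$taxonomy, out$tree)
  out
}
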
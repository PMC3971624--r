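# Taxon-level relative abundance and dysbiosis sub-type assignment.

#' Relative abundance of a taxon in each sample
#'
#' Sums a sample's relative abundances over the OTUs whose lineage at `rank`
#' equals `taxon`. OTUs unassigned at that rank contribute to no taxon.
#'
#' @param t an [otu_table()]
#' @param tax a `taxonomy_map` covering the table's OTUs
#' @param rank one of kingdom, phylum, class, order, family, genus
#' @param taxon taxon name at that rank
#' @param sample optional single sample id; default all samples
#' @return named numeric vector of shares in \[0,1\]
#' @export
aggregate_relative_abundance <- function(t, tax, rank, taxon, sample = NULL) {
  if (!rank %in% .RANKS) stop("unknown rank: ", rank)
  check_consistency(t, tax = tax)
  if (!is.null(sample)) {
    if (!sample %in% rownames(t)) stop("unknown sample: ", sample)
    t <- t[sample, , drop = FALSE]
  }
  lv <- stats::setNames(tax[[rank]], tax$otu_id)[colnames(t)]
  hit <- !is.na(lv) & lv == taxon
  rowSums(t[, hit, drop = FALSE]) / rowSums(t)
}

#' Classify dysbiosis per infant
#'
#' Evaluates the three biomarker flags on each infant's analysis samples
#' (earliest pre-onset sample per window, see [select_analysis_samples()]):
#' Firmicutes dominance at or above `firmicutes_threshold` (phylum rank,
#' window-1 sample), Proteobacteria dominance at or above
#' `proteobacteria_threshold` (phylum rank, window-2 sample), and absence of
#' Propionibacterium (genus-level reads below `detection_floor` in the
#' unrarefied window-1 sample). Flags whose window lacks a sample are NA, not
#' FALSE. `either_dysbiosis` and `combined_criterion` require samples in both
#' windows. The threshold-based `subtype` is NEC-I-like when the Firmicutes
#' flag is on, else NEC-II-like when the Proteobacteria flag is on, else
#' unclassified; a cluster-based alternative is [assign_subtypes()].
#'
#' @param t full (unrarefied, unfiltered) [otu_table()]
#' @param tax taxonomy map
#' @param samples [sample_records()]
#' @param windows list from [study_windows()]
#' @param firmicutes_threshold,proteobacteria_threshold dominance cut-offs,
#'   defaults 0.98 and 0.90
#' @param detection_floor minimum reads counting as "present", default 1
#' @return data.frame of class `dysbiosis_calls`, one row per infant with a
#'   sample in at least one window
#' @export
classify_dysbiosis <- function(t, tax, samples, windows = study_windows(),
                               firmicutes_threshold = 0.98,
                               proteobacteria_threshold = 0.90,
                               detection_floor = 1) {
  s1 <- select_analysis_samples(samples, windows$w1)
  s2 <- select_analysis_samples(samples, windows$w2)
  infants <- unique(c(s1$infant_id, s2$infant_id))
  grp <- stats::setNames(samples$group, samples$infant_id)

  firm <- aggregate_relative_abundance(t, tax, "phylum", "Firmicutes")
  prot <- aggregate_relative_abundance(t, tax, "phylum", "Proteobacteria")
  ent <- aggregate_relative_abundance(t, tax, "family", "Enterobacteriaceae")
  propi_ids <- tax$otu_id[!is.na(tax$genus) & tax$genus == "Propionibacterium"]
  propi_reads <- rowSums(t[, intersect(propi_ids, colnames(t)), drop = FALSE])
  propi_share <- propi_reads / rowSums(t)

  w1_of <- stats::setNames(s1$sample_id, s1$infant_id)
  w2_of <- stats::setNames(s2$sample_id, s2$infant_id)

  out <- data.frame(infant_id = infants, group = grp[infants],
                    w1_sample = w1_of[infants], w2_sample = w2_of[infants],
                    stringsAsFactors = FALSE)
  out$firmicutes_w1 <- ifelse(is.na(out$w1_sample), NA, firm[out$w1_sample])
  out$proteobacteria_w1 <- ifelse(is.na(out$w1_sample), NA, prot[out$w1_sample])
  out$proteobacteria_w2 <- ifelse(is.na(out$w2_sample), NA, prot[out$w2_sample])
  out$enterobacteriaceae_w2 <- ifelse(is.na(out$w2_sample), NA, ent[out$w2_sample])
  out$propionibacterium_w1 <- ifelse(is.na(out$w1_sample), NA,
                                     propi_share[out$w1_sample])
  out$firmicutes_dysbiosis_w1 <- out$firmicutes_w1 >= firmicutes_threshold
  out$proteobacteria_dysbiosis_w2 <-
    out$proteobacteria_w2 >= proteobacteria_threshold
  out$propionibacterium_absent_w1 <- ifelse(
    is.na(out$w1_sample), NA,
    propi_reads[out$w1_sample] < detection_floor)
  both <- !is.na(out$w1_sample) & !is.na(out$w2_sample)
  out$either_dysbiosis <- ifelse(
    both, out$firmicutes_dysbiosis_w1 | out$proteobacteria_dysbiosis_w2, NA)
  out$combined_criterion <- ifelse(
    both, out$propionibacterium_absent_w1 & out$either_dysbiosis, NA)
  out$subtype <- ifelse(
    !is.na(out$firmicutes_dysbiosis_w1) & out$firmicutes_dysbiosis_w1,
    "NEC-I-like",
    ifelse(!is.na(out$proteobacteria_dysbiosis_w2) &
             out$proteobacteria_dysbiosis_w2, "NEC-II-like", "unclassified"))
  rownames(out) <- NULL
  class(out) <- c("dysbiosis_calls", "data.frame")
  out
}

#' Cluster-based sub-type assignment
#'
#' Labels the window-1 cluster containing the majority of infants with the
#' Firmicutes-dysbiosis flag as NEC-I-like, and — when any infant carries the
#' Proteobacteria-dysbiosis flag — the window-2 cluster with the highest
#' median Enterobacteriaceae share as NEC-II-like. An infant's sub-type is
#' NEC-I-like when its window-1 sample falls in the NEC-I-like cluster,
#' otherwise NEC-II-like when its window-2 sample falls in the NEC-II-like
#' cluster, otherwise unclassified. Size-1 clusters are reported as outliers,
#' not special-cased.
#'
#' @param calls a [classify_dysbiosis()] result
#' @param labels_w1,labels_w2 cluster labels named by sample id
#'   (see [cluster_labels()]); either may be NULL
#' @return `calls` with a `subtype_cluster` column (and the two labelling
#'   clusters as attributes `nec1_cluster`, `nec2_cluster`)
#' @export
assign_subtypes <- function(calls, labels_w1 = NULL, labels_w2 = NULL) {
  sub <- rep("unclassified", nrow(calls))
  nec1_cl <- NA; nec2_cl <- NA
  if (!is.null(labels_w1)) {
    flagged <- calls$w1_sample[!is.na(calls$firmicutes_dysbiosis_w1) &
                                 calls$firmicutes_dysbiosis_w1]
    flagged <- flagged[flagged %in% names(labels_w1)]
    if (length(flagged) > 0) {
      tab <- table(labels_w1[flagged])
      nec1_cl <- names(tab)[which.max(tab)]
      ink <- !is.na(calls$w1_sample) & calls$w1_sample %in% names(labels_w1) &
        labels_w1[calls$w1_sample] == as.integer(nec1_cl)
      sub[ink] <- "NEC-I-like"
    }
  }
  if (!is.null(labels_w2) &&
      any(calls$proteobacteria_dysbiosis_w2, na.rm = TRUE)) {
    med <- tapply(
      calls$enterobacteriaceae_w2[match(names(labels_w2), calls$w2_sample)],
      labels_w2, stats::median, na.rm = TRUE)
    # size-1 clusters are outliers, not candidate sub-type clusters
    sizes <- table(labels_w2)
    med[names(sizes)[sizes < 2]] <- -Inf
    nec2_cl <- names(med)[which.max(med)]
    ink <- !is.na(calls$w2_sample) & calls$w2_sample %in% names(labels_w2) &
      labels_w2[calls$w2_sample] == as.integer(nec2_cl) &
      sub != "NEC-I-like"
    sub[ink] <- "NEC-II-like"
  }
  calls$subtype_cluster <- sub
  attr(calls, "nec1_cluster") <- nec1_cl
  attr(calls, "nec2_cluster") <- nec2_cl
  calls
}
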
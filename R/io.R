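#' Construct and validate an OTU count table
#'
#' The central data container: a samples-by-OTUs matrix of non-negative
#' integer read counts. All community computations (rarefaction, diversity
#' indices, UniFrac, taxon aggregation) consume this object.
#'
#' @param counts numeric matrix (samples in rows, OTUs in columns) of
#'   non-negative integer counts.
#' @param sample_ids,otu_ids character vectors of unique identifiers; taken
#'   from `dimnames(counts)` when omitted.
#' @return An object of class `otu_table`: the validated integer matrix with
#'   sample ids as rownames and OTU ids as colnames.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("otu_table requires sample and OTU identifiers")
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1])
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1])
  if (nrow(counts) != length(sample_ids) || ncol(counts) != length(otu_ids))
    stop("counts dimensions do not match identifier lengths")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at sample '%s', OTU '%s': %s",
                 sample_ids[bad[1, 1]], otu_ids[bad[1, 2]],
                 counts[bad[1, , drop = FALSE]]))
  zero <- which(rowSums(counts) == 0)
  if (length(zero) > 0)
    stop("sample with zero total reads: ", sample_ids[zero[1]])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table from a tab-separated file
#'
#' @param path file path. First column holds sample ids (or OTU ids when
#'   `samples_in_rows = FALSE`), header row holds the other dimension's ids.
#' @param samples_in_rows logical; set `FALSE` for OTUs-in-rows orientation.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, samples_in_rows = TRUE) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = list(ids, colnames(m))))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("%s: invalid count '%s' at row '%s', column '%s'",
                 path, m[bad[1, , drop = FALSE]],
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  if (!samples_in_rows) num <- t(num)
  otu_table(num)
}

#' Write an OTU table as TSV (samples in rows)
#' @param t an [otu_table()]
#' @param path output file
#' @export
write_otu_table <- function(t, path) {
  df <- data.frame(sample_id = rownames(t), unclass(t), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
.RANK_PREFIX <- c(kingdom = "k", phylum = "p", class = "c",
                  order = "o", family = "f", genus = "g")

#' Parse a Greengenes-style lineage string
#'
#' `"k__Bacteria; p__Firmicutes; c__Bacilli; o__; f__; g__"` becomes a named
#' character vector over the six ranks kingdom..genus, with `NA` for ranks
#' left unassigned (empty prefix or missing field).
#'
#' @param lineage a single lineage string
#' @param prefixed logical; `FALSE` accepts plain `"Bacteria; Firmicutes"`
#'   strings without rank prefixes.
#' @return named character vector of length 6 (NA = unassigned).
#' @export
parse_lineage <- function(lineage, prefixed = TRUE) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  if (length(parts) > 6) stop("lineage has more than 6 ranks: ", lineage)
  out <- stats::setNames(rep(NA_character_, 6), .RANKS)
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (prefixed) {
      want <- paste0(.RANK_PREFIX[i], "__")
      if (substr(p, 1, 3) != want)
        stop(sprintf("malformed rank prefix '%s' (expected '%s') in: %s",
                     p, want, lineage))
      p <- substr(p, 4, nchar(p))
    }
    if (nzchar(p)) out[i] <- p
  }
  # ranks must be contiguous from kingdom down to the deepest assigned one
  assigned <- !is.na(out)
  if (any(assigned) && any(is.na(out[seq_len(max(which(assigned)))])))
    stop("lineage assigns a rank below an unassigned one: ", lineage)
  out
}

#' Read an OTU -> lineage taxonomy table
#'
#' @param path 2-column TSV: OTU id, lineage string.
#' @param prefixed see [parse_lineage()].
#' @return A `taxonomy_map`: data.frame with columns `otu_id`,
#'   `kingdom` .. `genus` (`NA` = unassigned).
#' @export
read_taxonomy <- function(path, prefixed = TRUE) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) < 2) stop(path, ": taxonomy file needs OTU id + lineage columns")
  taxonomy_map(df[[1]], df[[2]], prefixed = prefixed)
}

#' Build a taxonomy map from OTU ids and lineage strings
#' @param otu_ids character vector
#' @param lineages character vector of lineage strings, same length
#' @param prefixed see [parse_lineage()]
#' @export
taxonomy_map <- function(otu_ids, lineages, prefixed = TRUE) {
  if (any(!nzchar(otu_ids)) || anyNA(otu_ids)) stop("missing OTU id in taxonomy")
  if (anyDuplicated(otu_ids)) stop("duplicate OTU id in taxonomy")
  ranks <- t(vapply(lineages, parse_lineage, character(6), prefixed = prefixed))
  out <- data.frame(otu_id = as.character(otu_ids), ranks,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}

#' Serialize a taxonomy map back to Greengenes lineage strings
#' @param tax a `taxonomy_map`
#' @param path output TSV
#' @export
write_taxonomy <- function(tax, path) {
  lin <- apply(tax[.RANKS], 1, function(r) {
    paste0(.RANK_PREFIX, "__", ifelse(is.na(r), "", r), collapse = "; ")
  })
  utils::write.table(data.frame(otu_id = tax$otu_id, lineage = lin),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' Wraps [ape::read.tree()] and enforces the contract UniFrac needs: rooted,
#' every non-root edge carries a finite branch length >= 0.
#'
#' @param path Newick file
#' @return an [ape::read.tree()] `phylo` object, validated
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(path, ": unparseable Newick")
  validate_tree(tr)
}

#' Validate a phylo object for UniFrac use
#' @param tr a `phylo` object
#' @return the tree, invisibly checked
#' @export
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths")
  if (length(tr$edge.length) != nrow(tr$edge) ||
      any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("every non-root branch needs a finite length >= 0")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names in tree")
  tr
}

#' Write a tree as Newick
#' @param tr a `phylo` object
#' @param path output file
#' @export
write_tree <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Check OTU table / taxonomy / tree consistency
#'
#' Errors when an OTU of the table is missing from the taxonomy or is not a
#' leaf of the tree, naming the offending OTU.
#'
#' @param t an [otu_table()]
#' @param tax a `taxonomy_map` or NULL
#' @param tree a `phylo` or NULL
#' @return TRUE invisibly
#' @export
check_consistency <- function(t, tax = NULL, tree = NULL) {
  ids <- colnames(t)
  if (!is.null(tax)) {
    miss <- setdiff(ids, tax$otu_id)
    if (length(miss) > 0) stop("OTU missing from taxonomy: ", miss[1])
  }
  if (!is.null(tree)) {
    miss <- setdiff(ids, tree$tip.label)
    if (length(miss) > 0) stop("OTU missing from tree: ", miss[1])
  }
  invisible(TRUE)
}

#' Sample metadata records
#'
#' One row per stool sample: infant, postnatal day of collection (birth =
#' day 0), outcome group, and for NEC cases the day of NEC onset (for
#' non-NEC deaths, the day of death).
#'
#' @param sample_id,infant_id character vectors
#' @param day_of_life integer >= 0
#' @param group one of "NEC", "control", "non_NEC_death"
#' @param onset_day integer (NA for controls); onset/death day
#' @return data.frame of class `sample_records`
#' @export
sample_records <- function(sample_id, infant_id, day_of_life, group,
                           onset_day = NA_integer_) {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("NEC", "control", "non_NEC_death"))
  if (length(bad) > 0) stop("unknown outcome group: ", bad[1])
  df <- data.frame(sample_id = as.character(sample_id),
                   infant_id = as.character(infant_id),
                   day_of_life = as.integer(day_of_life),
                   group = group,
                   onset_day = as.integer(onset_day),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample id in metadata")
  if (any(df$day_of_life < 0)) stop("negative day_of_life")
  need <- df$group != "control"
  if (any(need & is.na(df$onset_day)))
    stop("onset_day required for NEC and non-NEC-death records")
  if (any(!is.na(df$onset_day) & df$onset_day <= 0))
    stop("onset_day must be > 0")
  class(df) <- c("sample_records", "data.frame")
  df
}

#' @rdname sample_records
#' @param path TSV with header sample_id, infant_id, day_of_life, group, onset_day
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  sample_records(df$sample_id, df$infant_id, df$day_of_life, df$group,
                 df$onset_day)
}

#' @rdname sample_records
#' @param records a `sample_records` data.frame
#' @export
write_sample_metadata <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Urinary metabolite records
#'
#' Relative (NMR-scale) urinary values; all must be positive so that the
#' alanine:histidine ratio is defined.
#'
#' @param infant_id character; @param day_of_life integer
#' @param alanine,histidine,pyridoxine positive reals
#' @return data.frame of class `metabolite_records`
#' @export
metabolite_records <- function(infant_id, day_of_life, alanine, histidine,
                               pyridoxine) {
  df <- data.frame(infant_id = as.character(infant_id),
                   day_of_life = as.integer(day_of_life),
                   alanine = as.numeric(alanine),
                   histidine = as.numeric(histidine),
                   pyridoxine = as.numeric(pyridoxine),
                   stringsAsFactors = FALSE)
  vals <- as.matrix(df[c("alanine", "histidine", "pyridoxine")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("metabolite values must be positive and finite")
  class(df) <- c("metabolite_records", "data.frame")
  df
}

#' @rdname metabolite_records
#' @param path TSV with header infant_id, day_of_life, alanine, histidine, pyridoxine
#' @export
read_metabolites <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  metabolite_records(df$infant_id, df$day_of_life, df$alanine, df$histidine,
                     df$pyridoxine)
}

#' @rdname metabolite_records
#' @param records a `metabolite_records` data.frame
#' @export
write_metabolites <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The two postnatal analysis windows
#'
#' Days of life 4-9 and 10-16, inclusive on both ends, with birth counted as
#' day 0. These bound which stool sample represents an infant in each
#' analysis period.
#'
#' @return named list of two windows, each `list(label, first_day, last_day)`
#' @export
study_windows <- function() {
  list(w1 = window("w1", 4L, 9L), w2 = window("w2", 10L, 16L))
}

#' @rdname study_windows
#' @param label window name
#' @param first_day,last_day inclusive integer bounds
#' @export
window <- function(label, first_day, last_day) {
  first_day <- as.integer(first_day); last_day <- as.integer(last_day)
  if (is.na(first_day) || is.na(last_day) || first_day > last_day)
    stop("window requires first_day <= last_day")
  list(label = label, first_day = first_day, last_day = last_day)
}

#' Select the analysis sample per infant for a window
#'
#' Statistical independence is enforced by keeping at most one sample per
#' infant: the earliest within the window. For NEC cases only samples
#' collected strictly before onset are eligible (onset-day samples are
#' dropped); the same pre-event rule is applied to non-NEC deaths.
#'
#' @param records a `sample_records` data.frame
#' @param window a [window()] (e.g. `study_windows()$w1`)
#' @return a `sample_records` subset, one row per retained infant
#' @export
select_analysis_samples <- function(records, window) {
  r <- records[records$day_of_life >= window$first_day &
               records$day_of_life <= window$last_day, , drop = FALSE]
  pre <- is.na(r$onset_day) | r$day_of_life < r$onset_day
  r <- r[pre, , drop = FALSE]
  if (nrow(r) == 0) return(r)
  r <- r[order(r$infant_id, r$day_of_life), , drop = FALSE]
  out <- r[!duplicated(r$infant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
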
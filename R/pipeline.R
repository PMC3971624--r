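# End-to-end orchestration: sample selection -> rare-OTU filter -> alpha
# diversity -> weighted UniFrac -> NMDS -> Ward clustering + diagnostics ->
# dysbiosis calls -> biomarker and metabolite reports.

#' Pipeline configuration
#'
#' @param rarefaction_depth reads per sample for alpha diversity (default 2000)
#' @param min_samples,min_total rare-OTU filter thresholds (defaults 2, 5)
#' @param unifrac_normalized use the normalized UniFrac variant
#' @param nmds_k,nmds_starts,nmds_max_iter,nmds_tol NMDS settings
#' @param k_override_w1,k_override_w2 fixed cluster counts per window (NULL =
#'   choose by pseudo-F/pseudo-T2 rule), @param k_max diagnostic range
#' @param firmicutes_threshold,proteobacteria_threshold dysbiosis cut-offs
#' @param detection_floor reads for Propionibacterium presence
#' @param ratio_cutpoint fixed alanine:histidine cut-point or "roc"
#' @param seed master seed; stage seeds derive from it (see [derive_seed()])
#' @param output_dir directory for stage outputs, or NULL for none
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(rarefaction_depth = 2000, min_samples = 2,
                            min_total = 5, unifrac_normalized = FALSE,
                            nmds_k = 3, nmds_starts = 20,
                            nmds_max_iter = 300, nmds_tol = 1e-6,
                            k_override_w1 = NULL, k_override_w2 = NULL,
                            k_max = 8,
                            firmicutes_threshold = 0.98,
                            proteobacteria_threshold = 0.90,
                            detection_floor = 1, ratio_cutpoint = 4,
                            seed = 1, output_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(rarefaction_depth > 0, min_samples >= 1, min_total >= 1,
            nmds_k >= 1, nmds_starts >= 1,
            firmicutes_threshold > 0, firmicutes_threshold <= 1,
            proteobacteria_threshold > 0, proteobacteria_threshold <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# one window's community analysis: subset, filter, distances, ordination,
# clustering
.analyze_window <- function(otu, tree, selected, cfg, wlab, stage_seed) {
  sub <- otu_table(unclass(otu)[selected$sample_id, , drop = FALSE])
  filt <- filter_rare_otus(sub, cfg$min_samples, cfg$min_total)
  dmat <- weighted_unifrac(filt, tree, normalized = cfg$unifrac_normalized)
  ord <- NULL
  if (nrow(dmat) >= cfg$nmds_k + 1 && any(dmat > 0))
    ord <- nmds(dmat, k = cfg$nmds_k, n_starts = cfg$nmds_starts,
                seed = stage_seed, max_iter = cfg$nmds_max_iter,
                tol = cfg$nmds_tol)
  tree_w <- ward_cluster(dmat)
  diag <- cluster_diagnostics(tree_w, dmat,
                              k_max = min(cfg$k_max, nrow(dmat) - 1))
  k_over <- if (wlab == "w1") cfg$k_override_w1 else cfg$k_override_w2
  k <- choose_k(diag, k_over)
  labels <- cluster_labels(tree_w, k)
  list(window = wlab, table = filt, dist = dmat, nmds = ord,
       cluster_tree = tree_w, diagnostics = diag, k = k, labels = labels)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort (either a [generate_cohort()] object or
#' a list with `otu`, `taxonomy`, `tree`, `samples`, `metabolites`, e.g. from
#' [read_cohort()]): per-window analysis sample selection, rare-OTU
#' filtering, rarefied alpha diversity, weighted UniFrac, NMDS, Ward
#' clustering with pseudo-F/pseudo-T2 diagnostics, dysbiosis classification
#' and cluster-based sub-typing, the six-criterion biomarker report, and the
#' metabolite association report. When `config$output_dir` is set, every
#' stage's tables are written there and a JSON run manifest (config snapshot,
#' derived seeds, file checksums) is saved.
#'
#' @param cohort cohort list
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result`
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  check_consistency(cohort$otu, cohort$taxonomy, cohort$tree)
  windows <- study_windows()
  sel <- lapply(windows, function(w)
    select_analysis_samples(cohort$samples, w))
  if (nrow(sel$w1) == 0 && nrow(sel$w2) == 0)
    stop("stage select: no analysis samples in either window")

  # alpha diversity on each window's analysis samples (rarefied)
  alpha <- lapply(names(windows), function(wl) {
    s <- sel[[wl]]
    if (nrow(s) == 0) return(NULL)
    tab <- otu_table(unclass(cohort$otu)[s$sample_id, , drop = FALSE])
    a <- alpha_diversity_table(tab, depth = config$rarefaction_depth,
                               seed = derive_seed(config$seed, 1L))
    a$window <- wl
    a
  })
  alpha <- do.call(rbind, alpha)

  win_res <- list()
  for (wl in names(windows)) {
    if (nrow(sel[[wl]]) < 2) next
    win_res[[wl]] <- .analyze_window(cohort$otu, cohort$tree, sel[[wl]],
                                     config, wl,
                                     derive_seed(config$seed,
                                                 2L + match(wl, names(windows))))
  }

  calls <- classify_dysbiosis(
    cohort$otu, cohort$taxonomy, cohort$samples, windows,
    firmicutes_threshold = config$firmicutes_threshold,
    proteobacteria_threshold = config$proteobacteria_threshold,
    detection_floor = config$detection_floor)
  calls <- assign_subtypes(calls,
                           labels_w1 = if (!is.null(win_res$w1)) win_res$w1$labels,
                           labels_w2 = if (!is.null(win_res$w2)) win_res$w2$labels)

  table3 <- tryCatch(
    table3_report(calls, cohort$metabolites, windows,
                  ratio_cutpoint = config$ratio_cutpoint),
    error = function(e) { warning("stage table3: ", conditionMessage(e)); NULL })
  table2 <- tryCatch(
    table2_report(calls, cohort$metabolites, windows),
    error = function(e) { warning("stage table2: ", conditionMessage(e)); NULL })

  res <- list(config = config, selected = sel, alpha = alpha,
              windows = win_res, calls = calls, table3 = table3,
              table2 = table2)
  class(res) <- "pipeline_result"
  if (!is.null(config$output_dir)) res$manifest <- write_results(res, config$output_dir)
  res
}

#' Write pipeline outputs and a run manifest
#' @param res a `pipeline_result`
#' @param dir output directory
#' @return the manifest list, invisibly
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- character()
  if (!is.null(res$alpha)) paths <- c(paths, w(res$alpha, "alpha_diversity.tsv"))
  for (wl in names(res$windows)) {
    wr <- res$windows[[wl]]
    dmat <- data.frame(sample_id = rownames(wr$dist), as.data.frame(unclass(wr$dist)),
                       check.names = FALSE)
    paths <- c(paths, w(dmat, sprintf("unifrac_%s.tsv", wl)))
    if (!is.null(wr$nmds)) {
      pts <- data.frame(sample_id = rownames(wr$nmds$points), wr$nmds$points)
      paths <- c(paths, w(pts, sprintf("nmds_%s.tsv", wl)))
    }
    paths <- c(paths, w(wr$diagnostics, sprintf("cluster_diagnostics_%s.tsv", wl)))
    lab <- data.frame(sample_id = names(wr$labels), cluster = unname(wr$labels))
    paths <- c(paths, w(lab, sprintf("cluster_labels_%s.tsv", wl)))
  }
  paths <- c(paths, w(res$calls, "dysbiosis_calls.tsv"))
  if (!is.null(res$table3)) {
    paths <- c(paths, w(res$table3, "table3.tsv"))
    jsonlite::write_json(res$table3, file.path(dir, "table3.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$table2)) paths <- c(paths, w(res$table2, "table2.tsv"))
  manifest <- list(
    config = res$config[!vapply(res$config, is.null, TRUE)],
    nmds_stress = lapply(res$windows, function(wr)
      if (is.null(wr$nmds)) NULL else wr$nmds$stress),
    chosen_k = lapply(res$windows, `[[`, "k"),
    checksums = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
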
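#' Pipeline configuration
#'
#' Gathers every threshold of the analysis: the LCB fold threshold and
#' nominal alpha of the regulated-transcript rule, the stricter alpha used
#' to build the target-enriched set, the over-representation threshold,
#' the confidence level of the fold-change intervals and the
#' tissue-tropism abundance threshold, plus the test flavor and marker
#' timepoint switches and the simulation config driving synthetic runs.
#'
#' @param sim a [sim_config()] describing the synthetic experiment (or
#'   `NULL` when the probe data are supplied directly to
#'   [run_pipeline()]).
#' @param fold_threshold LCB threshold for regulated calls (default 1.5).
#' @param alpha_regulated nominal alpha of the regulated rule (0.05).
#' @param alpha_enriched_set alpha for the target-enriched set (0.01).
#' @param go_threshold over-representation p threshold (0.001).
#' @param ci_level fold-change confidence level (0.90).
#' @param tau tropism abundance threshold (3.0).
#' @param flavor t-test flavor (`"welch"` or `"student"`).
#' @param p_adjust `"none"` or `"BH"` multiple-testing layer.
#' @param marker_timepoint treated timepoint scored by the marker panel.
#' @param seed integer seed (defaults to the simulation seed).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            fold_threshold = 1.5,
                            alpha_regulated = 0.05,
                            alpha_enriched_set = 0.01,
                            go_threshold = 0.001,
                            ci_level = 0.90,
                            tau = 3.0,
                            flavor = c("welch", "student"),
                            p_adjust = c("none", "BH"),
                            marker_timepoint = "D14",
                            seed = NULL) {
  flavor <- match.arg(flavor); p_adjust <- match.arg(p_adjust)
  chk01 <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      stop(sprintf("pipeline config: '%s' must lie in [%s, %s]", nm, lo, hi),
           call. = FALSE)
  }
  chk01(alpha_regulated, "alpha_regulated")
  chk01(alpha_enriched_set, "alpha_enriched_set")
  chk01(go_threshold, "go_threshold")
  chk01(ci_level, "ci_level")
  if (fold_threshold < 0) stop("fold_threshold must be >= 0", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (is.null(seed)) seed <- if (!is.null(sim)) sim$seed else 1L
  structure(list(sim = sim, fold_threshold = fold_threshold,
                 alpha_regulated = alpha_regulated,
                 alpha_enriched_set = alpha_enriched_set,
                 go_threshold = go_threshold, ci_level = ci_level,
                 tau = tau, flavor = flavor, p_adjust = p_adjust,
                 marker_timepoint = marker_timepoint,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full reprogramming-quantification pipeline
#'
#' Chains the stages end-to-end: simulate (or accept) probe-level data,
#' normalize to the median-intensity array, fit the model-based
#' expression index, compute the differential table and regulated calls,
#' build the target-enriched set, score reprogramming completeness
#' (path-completion, overlap and marker panel), classify the activated
#' set's tissue tropism against the atlas, and test ontology
#' over-representation.  With `out_dir` set, every stage table is written
#' (TSV/GMT/JSON) together with a run manifest recording the config, seed
#' and stage row counts; a rerun with identical inputs is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param probes optional [probe_matrix()]; when `NULL` the synthetic
#'   generator produces the data from `config$sim`.
#' @param atlas,annotation,markers optional inputs; defaulted from the
#'   synthetic truth when simulating (markers default to the
#'   endocrine-block genes, a stand-in for a conserved target-state marker
#'   panel).
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return list with `report` (a `reprog_report`), `calls`, `activated`,
#'   `enriched_set`, `tropism`, `enrichment`, `expr`, `truth` (when
#'   simulated) and `manifest`.
#' @export
run_pipeline <- function(config, probes = NULL, atlas = NULL,
                         annotation = NULL, markers = NULL,
                         out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  truth <- NULL
  if (is.null(probes)) {
    if (is.null(config$sim))
      stop("run_pipeline: no probe data and no simulation config",
           call. = FALSE)
    say("simulating probe-level data (seed %d)", config$sim$seed)
    sim <- generate_experiment(config$sim)
    probes <- sim$probes; truth <- sim$truth
    if (is.null(atlas)) atlas <- generate_atlas(config$sim, truth)
    if (is.null(annotation)) annotation <- generate_annotation(config$sim, truth)
    if (is.null(markers)) {
      # stand-in for a conserved target-state marker panel: genes both
      # endocrine-specific and abundant in the target state
      blk <- truth$tissue_block
      markers <- gene_set("endocrine_block_markers",
                          intersect(names(blk)[blk == "endocrine"],
                                    truth$target_enriched_ids))
    }
  }

  say("normalizing %d arrays", ncol(probes$pm))
  probes <- normalize_to_median_array(probes)
  say("fitting expression indices")
  expr <- fit_expression_index(probes)

  say("differential calls")
  tab <- differential_table(expr, level = config$ci_level,
                            flavor = config$flavor)
  calls <- call_regulated(tab, fold_threshold = config$fold_threshold,
                          alpha = config$alpha_regulated,
                          p_adjust = config$p_adjust)
  act_ids <- calls$transcript_id[calls$call == "up"]
  activated <- gene_set("activated",
                        if (!is.null(expr$gene_map))
                          collapse_to_genes(act_ids, expr) else act_ids)

  say("target-enriched set")
  enriched <- build_enriched_set(expr,
                                 fold_threshold = config$fold_threshold,
                                 alpha = config$alpha_enriched_set,
                                 level = config$ci_level,
                                 flavor = config$flavor)
  enriched_genes <- gene_set("target_enriched",
                             if (!is.null(expr$gene_map))
                               collapse_to_genes(enriched$ids, expr)
                             else enriched$ids)

  report <- if (length(enriched_genes) > 0)
    path_fraction(activated, enriched_genes)
  else structure(list(n_activated = length(activated),
                      n_target_enriched = 0L, n_overlap = 0L,
                      path_fraction = NA_real_, overlap_fraction = NA_real_,
                      path_pct_display = NA_real_,
                      overlap_pct_display = NA_real_,
                      overlap_ids = character(0), marker_panel = NULL),
                 class = "reprog_report")

  if (!is.null(markers)) {
    gene_expr <- as_gene_level(expr)
    gene_calls <- calls
    if (!is.null(expr$gene_map)) {
      gene_calls$transcript_id <- unname(
        expr$gene_map[gene_calls$transcript_id])
    }
    mrep <- marker_panel_score(markers, gene_calls, gene_expr, gene_expr,
                               timepoint = config$marker_timepoint)
    report <- merge_reports(report, mrep)
  }

  tropism <- NULL
  if (!is.null(atlas) && length(activated) > 0) {
    say("tissue tropism of %d activated genes", length(activated))
    in_atlas <- activated$ids[toupper(activated$ids) %in%
                              toupper(rownames(atlas$values))]
    if (length(in_atlas) > 0)
      tropism <- assign_tropism(in_atlas, atlas, tau = config$tau)
  }

  enrichment <- NULL
  if (!is.null(annotation) && length(activated) > 0) {
    say("ontology over-representation")
    enrichment <- hypergeom_enrichment(activated, annotation,
                                       threshold = config$go_threshold,
                                       p_adjust = config$p_adjust)
  }

  manifest <- list(
    seed = config$seed,
    thresholds = list(fold_threshold = config$fold_threshold,
                      alpha_regulated = config$alpha_regulated,
                      alpha_enriched_set = config$alpha_enriched_set,
                      go_threshold = config$go_threshold,
                      ci_level = config$ci_level, tau = config$tau),
    flags = list(flavor = config$flavor, p_adjust = config$p_adjust,
                 marker_timepoint = config$marker_timepoint),
    counts = list(n_transcripts = nrow(expr$theta),
                  n_samples = ncol(expr$theta),
                  n_calls = nrow(calls),
                  n_activated = length(activated),
                  n_enriched = length(enriched_genes),
                  n_tropism = if (is.null(tropism)) 0L else nrow(tropism),
                  n_terms = if (is.null(enrichment)) 0L else nrow(enrichment)))

  result <- list(report = report, calls = calls, activated = activated,
                 enriched_set = enriched_genes, tropism = tropism,
                 enrichment = enrichment, expr = expr, truth = truth,
                 manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Write every stage table; a failed write renames what it produced to
# *.partial so an aborted run is distinguishable from a complete one.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  safe_write <- function(fun, obj, path, ...) {
    tryCatch(fun(obj, path, ...),
             error = function(e) {
               if (file.exists(path))
                 file.rename(path, paste0(path, ".partial"))
               stop(sprintf("stage output '%s' failed: %s", basename(path),
                            conditionMessage(e)), call. = FALSE)
             })
  }
  safe_write(write_expression_matrix, result$expr, p("expression.tsv"))
  safe_write(write_tsv_raw, result$calls, p("differential_calls.tsv"))
  safe_write(write_gmt, list(result$activated, result$enriched_set),
             p("gene_sets.gmt"))
  if (!is.null(result$tropism))
    safe_write(write_tsv_raw, result$tropism, p("tropism.tsv"))
  if (!is.null(result$enrichment))
    safe_write(write_tsv_raw, as.data.frame(result$enrichment),
               p("enrichment.tsv"))
  if (!is.null(result$truth))
    safe_write(write_truth, result$truth, p("truth.json"))
  safe_write(write_report, result$report, p("report.json"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
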
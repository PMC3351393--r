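#' Gene set
#'
#' A named set of gene identifiers.  Ids are trimmed and upper-cased so
#' that sets from sources with mixed symbol casing intersect correctly.
#'
#' @param name set name.
#' @param ids character vector of gene ids (duplicates dropped).
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, ids) {
  ids <- unique(toupper(trimws(as.character(ids))))
  ids <- ids[nzchar(ids)]
  structure(list(name = name, ids = ids), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d ids\n", x$name, length(x$ids)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Intersection of two gene sets
#'
#' Exact id intersection after case normalization.
#'
#' @param a,b [gene_set()] objects (or character vectors).
#' @return a `gene_set` named `"<a> & <b>"`.
#' @export
common_genes <- function(a, b) {
  if (!inherits(a, "gene_set")) a <- gene_set("a", a)
  if (!inherits(b, "gene_set")) b <- gene_set("b", b)
  gene_set(paste(a$name, "&", b$name), intersect(a$ids, b$ids))
}

#' Path-completion and overlap fractions
#'
#' Quantifies reprogramming completeness against the target-enriched
#' reference set: `path_fraction = |activated -intersect- target| / |target|`
#' (the share of the required duct-to-endocrine path completed) and
#' `overlap_fraction = |overlap| / |activated|` (the share of activated
#' transcripts that belong to the target programme).
#'
#' @param activated [gene_set()] of treatment-activated transcripts.
#' @param target_enriched [gene_set()] of target-enriched transcripts
#'   (must be non-empty).
#' @return object of class `reprog_report` carrying counts, unrounded
#'   fractions and integer-percent display values.
#' @export
path_fraction <- function(activated, target_enriched) {
  if (!inherits(activated, "gene_set")) activated <- gene_set("activated", activated)
  if (!inherits(target_enriched, "gene_set"))
    target_enriched <- gene_set("target_enriched", target_enriched)
  if (length(target_enriched) == 0)
    stop("path undefined: target-enriched set is empty", call. = FALSE)
  ov <- common_genes(activated, target_enriched)
  n_act <- length(activated); n_tgt <- length(target_enriched)
  n_ov <- length(ov)
  structure(list(
    n_activated = n_act,
    n_target_enriched = n_tgt,
    n_overlap = n_ov,
    path_fraction = n_ov / n_tgt,
    overlap_fraction = if (n_act > 0) n_ov / n_act else 0,
    path_pct_display = round(100 * n_ov / n_tgt),
    overlap_pct_display = if (n_act > 0) round(100 * n_ov / n_act) else 0,
    overlap_ids = ov$ids,
    marker_panel = NULL
  ), class = "reprog_report")
}

#' Conserved marker-panel signal score
#'
#' For a panel of conserved target-state marker genes, measures how far
#' each treatment-activated marker's expression has moved towards the
#' target state: `signal_fraction = mean treated expression / mean
#' target-cell expression` (expression indices, not logs; values above 1
#' are retained).  Markers absent from either matrix are excluded and
#' counted.
#'
#' @param marker_ids [gene_set()] (or character vector) of marker genes.
#' @param calls a [call_regulated()] table for the treated-vs-control
#'   comparison.
#' @param treated_expr `expression_index` holding the treated samples.
#' @param target_expr `expression_index` holding the target-cell samples
#'   (may be the same object).
#' @param timepoint treated timepoint whose signal is scored (default
#'   `"D14"`).
#' @param target_condition condition label of the target-cell samples.
#' @return object of class `reprog_report` with the `marker_panel` element
#'   populated: per-marker signal fractions, mean/min/max over activated
#'   markers, and the fraction of panel markers not regulated.
#' @export
marker_panel_score <- function(marker_ids, calls, treated_expr, target_expr,
                               timepoint = "D14",
                               target_condition = "target") {
  if (!inherits(marker_ids, "gene_set"))
    marker_ids <- gene_set("markers", marker_ids)
  trt_cols <- group_cols(treated_expr$samples, "treated", timepoint)
  tgt_cols <- group_cols(target_expr$samples, target_condition)
  if (length(trt_cols) == 0 || length(tgt_cols) == 0)
    stop("treated or target samples not found", call. = FALSE)

  ids_trt <- toupper(rownames(treated_expr$theta))
  ids_tgt <- toupper(rownames(target_expr$theta))
  present <- marker_ids$ids[marker_ids$ids %in% ids_trt &
                            marker_ids$ids %in% ids_tgt]
  n_excluded <- length(marker_ids) - length(present)

  call_ids <- toupper(calls$transcript_id[calls$call == "up"])
  activated <- present[present %in% call_ids]

  sf <- rep(NA_real_, length(activated))
  names(sf) <- activated
  if (length(activated) > 0) {
    trt_mu <- rowMeans(treated_expr$theta[match(activated, ids_trt),
                                          trt_cols, drop = FALSE])
    tgt_mu <- rowMeans(target_expr$theta[match(activated, ids_tgt),
                                         tgt_cols, drop = FALSE])
    sf <- trt_mu / tgt_mu
    names(sf) <- activated
  }
  n_mark <- length(present)
  n_act <- length(activated)
  panel <- list(
    n_markers = n_mark,
    n_markers_activated = n_act,
    n_excluded = n_excluded,
    signal_fraction = sf,
    mean_signal_fraction = if (n_act > 0) mean(sf) else NA_real_,
    min_signal_fraction = if (n_act > 0) min(sf) else NA_real_,
    max_signal_fraction = if (n_act > 0) max(sf) else NA_real_,
    fraction_markers_unregulated = if (n_mark > 0) 1 - n_act / n_mark else NA_real_
  )
  structure(list(n_activated = NA_integer_, n_target_enriched = NA_integer_,
                 n_overlap = NA_integer_, path_fraction = NA_real_,
                 overlap_fraction = NA_real_,
                 path_pct_display = NA_real_, overlap_pct_display = NA_real_,
                 overlap_ids = NULL, marker_panel = panel),
            class = "reprog_report")
}

#' @export
print.reprog_report <- function(x, ...) {
  cat("Reprogramming completeness report\n")
  if (!is.na(x$n_target_enriched)) {
    cat(sprintf("  target-enriched set : %d transcripts\n", x$n_target_enriched))
    cat(sprintf("  activated set       : %d transcripts\n", x$n_activated))
    cat(sprintf("  overlap             : %d\n", x$n_overlap))
    cat(sprintf("  path completion     : %d%% (%.4f)\n",
                x$path_pct_display, x$path_fraction))
    cat(sprintf("  overlap fraction    : %d%% (%.4f)\n",
                x$overlap_pct_display, x$overlap_fraction))
  }
  mp <- x$marker_panel
  if (!is.null(mp)) {
    cat(sprintf("  marker panel        : %d markers, %d activated (%d absent)\n",
                mp$n_markers, mp$n_markers_activated, mp$n_excluded))
    if (mp$n_markers_activated > 0)
      cat(sprintf("  marker signal       : mean %.0f%% (range %.0f-%.0f%%)\n",
                  100 * mp$mean_signal_fraction,
                  100 * mp$min_signal_fraction, 100 * mp$max_signal_fraction))
    cat(sprintf("  markers unregulated : %.0f%%\n",
                100 * mp$fraction_markers_unregulated))
  }
  invisible(x)
}

# Merge a path_fraction report and a marker_panel_score report.
merge_reports <- function(path_rep, marker_rep) {
  path_rep$marker_panel <- marker_rep$marker_panel
  path_rep
}
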
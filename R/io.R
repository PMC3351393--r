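# File formats: TSV for matrices and tables, GMT for gene sets, JSON for
# truth/report/manifest.  All writers emit full precision (15 significant
# digits) so that write -> read -> write round-trips byte-identically.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE)
  }, character(1))
  out
}

write_tsv_raw <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv_raw <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write / read a probe-level matrix as TSV
#'
#' Long-by-probe layout: columns `probeset_id`, `probe_index`, then one
#' `PM_<sample>` and one `MM_<sample>` column per array.  Sample metadata
#' travels in a companion TSV (`sample_id`, `condition`, `timepoint`,
#' `replicate`).
#'
#' @param probes a [probe_matrix()].
#' @param path output TSV path for intensities.
#' @param samples_path output TSV path for sample metadata (default:
#'   `path` with a `.samples.tsv` suffix).
#' @return `path`, invisibly.
#' @export
write_probe_matrix <- function(probes, path,
                               samples_path = paste0(path, ".samples.tsv")) {
  pm <- as.data.frame(probes$pm)
  mm <- as.data.frame(probes$mm)
  names(pm) <- paste0("PM_", probes$samples$sample_id)
  names(mm) <- paste0("MM_", probes$samples$sample_id)
  df <- cbind(data.frame(probeset_id = probes$probeset_id,
                         probe_index = probes$probe_index), pm, mm)
  write_tsv_raw(df, path)
  write_tsv_raw(probes$samples, samples_path)
  if (!is.null(probes$gene_map))
    write_tsv_raw(data.frame(probeset_id = names(probes$gene_map),
                             gene_id = unname(probes$gene_map)),
                  paste0(path, ".genes.tsv"))
  invisible(path)
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(path,
                              samples_path = paste0(path, ".samples.tsv")) {
  df <- read_tsv_raw(path)
  samples <- read_tsv_raw(samples_path)
  samples$timepoint <- as.character(samples$timepoint)
  pm_cols <- grep("^PM_", names(df), value = TRUE)
  mm_cols <- grep("^MM_", names(df), value = TRUE)
  gm <- NULL
  gm_path <- paste0(path, ".genes.tsv")
  if (file.exists(gm_path)) {
    g <- read_tsv_raw(gm_path)
    gm <- stats::setNames(g$gene_id, g$probeset_id)
  }
  probe_matrix(pm = as.matrix(df[pm_cols]), mm = as.matrix(df[mm_cols]),
               probeset_id = df$probeset_id, probe_index = df$probe_index,
               samples = samples, gene_map = gm)
}

#' Write / read an expression matrix as TSV
#'
#' Transcripts x samples table with a parallel `*_se.tsv` table of
#' standard errors and a companion sample-metadata TSV.
#'
#' @param expr an `expression_index`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- cbind(data.frame(transcript_id = rownames(expr$theta)),
              as.data.frame(expr$theta))
  write_tsv_raw(df, path)
  se <- cbind(data.frame(transcript_id = rownames(expr$se)),
              as.data.frame(expr$se))
  write_tsv_raw(se, sub("\\.tsv$", "_se.tsv", path))
  write_tsv_raw(expr$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_raw(path)
  se <- read_tsv_raw(sub("\\.tsv$", "_se.tsv", path))
  samples <- read_tsv_raw(paste0(path, ".samples.tsv"))
  samples$timepoint <- as.character(samples$timepoint)
  theta <- as.matrix(df[-1]); rownames(theta) <- df$transcript_id
  sem <- as.matrix(se[-1]); rownames(sem) <- se$transcript_id
  expression_index(theta, samples, se = sem)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param sets a [gene_set()] or list of them.
#' @param path file path.
#' @return `path` (write) or named list of `gene_set` objects (read).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$ids), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gene_set(parts[1], parts[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write / read a tissue atlas as TSV
#'
#' Genes x tissues value table plus a two-column tissue-category TSV.
#'
#' @param atlas an [atlas_matrix()].
#' @param path value-table path.
#' @param category_path tissue-category path.
#' @return `path` (write) or an `atlas_matrix` (read).
#' @export
write_atlas <- function(atlas, path,
                        category_path = paste0(path, ".categories.tsv")) {
  df <- cbind(data.frame(gene_id = rownames(atlas$values)),
              as.data.frame(atlas$values))
  write_tsv_raw(df, path)
  write_tsv_raw(data.frame(tissue = names(atlas$tissue_category),
                           category = unname(atlas$tissue_category)),
                category_path)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path, category_path = paste0(path, ".categories.tsv")) {
  df <- read_tsv_raw(path)
  cat_df <- read_tsv_raw(category_path)
  vals <- as.matrix(df[-1]); rownames(vals) <- df$gene_id
  atlas_matrix(vals, stats::setNames(cat_df$category, cat_df$tissue))
}

#' Read a two-column gene/term annotation TSV
#'
#' @param path TSV with columns gene, term (header optional but expected).
#' @param universe optional universe of assayable genes.
#' @return an [annotation_map()].
#' @export
read_annotation <- function(path, universe = NULL) {
  df <- read_tsv_raw(path)
  annotation_map(df[, 1:2], universe = universe)
}

#' Write an annotation map as two-column TSV
#' @param ann an [annotation_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  df <- data.frame(
    gene = unlist(ann$terms, use.names = FALSE),
    term = rep(names(ann$terms), lengths(ann$terms)))
  write_tsv_raw(df, path)
  invisible(path)
}

#' Serialize the ground truth of a synthetic experiment as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- truth
  x$config <- unclass(x$config)
  x$temporal_pattern <- as.list(x$temporal_pattern)
  x$tissue_block <- as.list(x$tissue_block)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a reprogramming report as JSON
#' @param report a `reprog_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
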
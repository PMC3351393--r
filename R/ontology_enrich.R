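#' Gene -> ontology-term annotation map
#'
#' A flat annotation: each term is a set of member genes drawn from a
#' stated universe (by default, all genes appearing in any term).  No
#' ontology-graph propagation is performed; terms are flat sets.
#'
#' @param terms named list of character vectors (term id -> member genes),
#'   or a two-column data.frame `(gene, term)`.
#' @param universe character vector of all assayable genes; annotated
#'   genes outside it are dropped with a warning.
#' @param labels optional named character vector of term labels.
#' @return object of class `annotation_map`.
#' @export
annotation_map <- function(terms, universe = NULL, labels = NULL) {
  if (is.data.frame(terms)) {
    stopifnot(ncol(terms) >= 2)
    terms <- split(toupper(trimws(terms[[1]])), terms[[2]])
  }
  terms <- lapply(terms, function(g) unique(toupper(trimws(g))))
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  universe <- unique(toupper(trimws(universe)))
  stray <- setdiff(unique(unlist(terms, use.names = FALSE)), universe)
  if (length(stray)) {
    warning(sprintf("%d annotated gene(s) outside the universe dropped",
                    length(stray)), call. = FALSE)
    terms <- lapply(terms, intersect, y = universe)
  }
  structure(list(terms = terms, universe = universe, labels = labels),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms over a universe of %d genes\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the query gene set contains
#' more term members than expected under random sampling from the
#' universe: the upper-tail hypergeometric probability
#' `P[X >= k]` with `N` universe genes, `K` term members, `n` query genes
#' and `k` hits.  Query genes outside the universe are dropped (and
#' counted); results are sorted by p-value, ties broken by term id.  No
#' multiple-testing correction is applied by default, matching the raw
#' `P < 0.001` practice; an optional Benjamini-Hochberg layer is
#' available.
#'
#' @param query [gene_set()] or character vector of query genes.
#' @param ann an [annotation_map()].
#' @param threshold enrichment-flag threshold on the (adjusted) p-value.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `enrichment_results` with columns
#'   `term`, `k`, `n`, `K`, `N`, `p_value`, (`p_adjusted`,) `enriched`;
#'   attribute `"n_dropped"` counts query genes outside the universe.
#' @export
hypergeom_enrichment <- function(query, ann, threshold = 0.001,
                                 p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (inherits(query, "gene_set")) query <- query$ids
  query <- unique(toupper(trimws(as.character(query))))
  if (length(ann$universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query set", call. = FALSE)
  inside <- query %in% ann$universe
  n_dropped <- sum(!inside)
  query <- query[inside]
  if (length(query) == 0)
    stop("no query gene is in the universe", call. = FALSE)

  N <- length(ann$universe)
  n <- length(query)
  K <- vapply(ann$terms, length, integer(1))
  k <- vapply(ann$terms, function(g) sum(query %in% g), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(ann$terms), k = k, n = n, K = K, N = N,
                    p_value = p, stringsAsFactors = FALSE)
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
    out$enriched <- out$p_adjusted < threshold
  } else {
    out$enriched <- out$p_value < threshold
  }
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("enrichment_results", "data.frame")
  out
}
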
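#' Multi-tissue expression atlas container
#'
#' @param values numeric matrix, genes x tissues, finite and >= 0, with
#'   dimnames.
#' @param tissue_category named character vector mapping every tissue
#'   (column) to one of `"endocrine"`, `"cns"`, `"other"`.
#' @return object of class `atlas_matrix`.
#' @export
atlas_matrix <- function(values, tissue_category) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("atlas needs gene and tissue names", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("atlas values must be finite and >= 0", call. = FALSE)
  missing <- setdiff(colnames(values), names(tissue_category))
  if (length(missing))
    stop("tissues without category: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(tissue_category %in% c("endocrine", "cns", "other")))
    stop("tissue categories must be endocrine, cns or other", call. = FALSE)
  structure(list(values = values,
                 tissue_category = tissue_category[colnames(values)]),
            class = "atlas_matrix")
}

#' @export
print.atlas_matrix <- function(x, ...) {
  tab <- table(x$tissue_category)
  cat(sprintf("atlas_matrix: %d genes x %d tissues (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Ratio of the mean over tissues in `category` to the mean over the rest.
category_abundance <- function(genes, atlas, category, eps = 1e-8) {
  idx <- match(toupper(genes), toupper(rownames(atlas$values)))
  if (anyNA(idx))
    stop("gene(s) absent from atlas: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  inside <- atlas$tissue_category == category
  if (!any(inside) || all(inside))
    stop(sprintf("atlas needs both '%s' and other tissues", category),
         call. = FALSE)
  mu_in <- rowMeans(atlas$values[idx, inside, drop = FALSE])
  mu_out <- rowMeans(atlas$values[idx, !inside, drop = FALSE])
  stats::setNames(mu_in / pmax(mu_out, eps), genes)
}

#' Endocrine abundance score
#'
#' Relative mRNA abundance in endocrine tissues compared to all other
#' tissues profiled: the ratio of a gene's mean expression over
#' endocrine-category tissues to its mean over the remaining tissues
#' (denominator floored at `eps`).
#'
#' @param genes gene id(s).
#' @param atlas an [atlas_matrix()].
#' @param eps denominator floor.
#' @return named numeric vector of abundance ratios.
#' @export
endocrine_abundance <- function(genes, atlas, eps = 1e-8)
  category_abundance(genes, atlas, "endocrine", eps)

#' Central-nervous-system abundance score
#'
#' Defined symmetrically to [endocrine_abundance()] over cns-category
#' tissues.
#' @inheritParams endocrine_abundance
#' @return named numeric vector of abundance ratios.
#' @export
cns_abundance <- function(genes, atlas, eps = 1e-8)
  category_abundance(genes, atlas, "cns", eps)

#' Classify genes by neuro-endocrine tissue tropism
#'
#' Labels each gene by where its expression is selectively abundant:
#' `A` (endocrine-specific) when `endocrine_abundance >= tau` and
#' `cns_abundance < tau`; `B` (neural) when the reverse holds; `C`
#' (neuro-endocrine, comparable abundance in both) when both ratios reach
#' `tau`; `MISC` otherwise.
#'
#' @param genes [gene_set()] or character vector of gene ids (non-empty).
#' @param atlas an [atlas_matrix()].
#' @param tau abundance-ratio threshold (default 3).
#' @return data.frame with columns `gene_id`, `label`,
#'   `endocrine_abundance`, `cns_abundance`; the per-label composition
#'   fractions of the input set are attached as attribute
#'   `"composition"`.
#' @export
assign_tropism <- function(genes, atlas, tau = 3.0) {
  if (inherits(genes, "gene_set")) genes <- genes$ids
  genes <- unique(as.character(genes))
  if (length(genes) == 0)
    stop("empty gene set", call. = FALSE)
  ea <- endocrine_abundance(genes, atlas)
  ca <- cns_abundance(genes, atlas)
  label <- ifelse(ea >= tau & ca < tau, "A",
           ifelse(ca >= tau & ea < tau, "B",
           ifelse(ea >= tau & ca >= tau, "C", "MISC")))
  out <- data.frame(gene_id = genes, label = unname(label),
                    endocrine_abundance = unname(ea),
                    cns_abundance = unname(ca),
                    stringsAsFactors = FALSE)
  comp <- table(factor(out$label, levels = c("A", "B", "C", "MISC")))
  attr(out, "composition") <- as.numeric(comp) / length(genes)
  names(attr(out, "composition")) <- names(comp)
  out
}

#' Hierarchical clustering of tissue profiles (correlation, centroid)
#'
#' Agglomerative clustering of per-gene tissue profiles with distance
#' `1 - Pearson correlation` and centroid linkage: at every step the two
#' clusters whose mean standardized profiles correlate best are merged.
#' Profiles are z-scored across tissues first; a constant profile (zero
#' variance) is assigned correlation 0 to everything and recorded in
#' attribute `"constant_genes"`.  Ties in merge distance are broken by the
#' lexicographically smallest leaf labels, making the tree invariant under
#' input-order permutation.  Centroid linkage can produce inversions
#' (a merge lower than an earlier one); these are tolerated and counted in
#' attribute `"n_inversions"`.
#'
#' @param atlas an [atlas_matrix()], typically restricted to a gene set of
#'   interest (>= 2 genes).
#' @param genes optional gene ids to restrict to.
#' @return an object of class `hclust` (usable with [stats::cutree()],
#'   `plot()` etc.) with extra attributes `n_inversions` and
#'   `constant_genes`.
#' @export
profile_hclust <- function(atlas, genes = NULL) {
  vals <- atlas$values
  if (!is.null(genes)) {
    if (inherits(genes, "gene_set")) genes <- genes$ids
    idx <- match(toupper(genes), toupper(rownames(vals)))
    if (anyNA(idx))
      stop("gene(s) absent from atlas: ",
           paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
    vals <- vals[idx, , drop = FALSE]
  }
  n <- nrow(vals)
  if (n < 2) stop("need at least 2 genes to cluster", call. = FALSE)

  # canonical lexicographic order => permutation-invariant tie-breaking
  ord <- order(rownames(vals))
  vals <- vals[ord, , drop = FALSE]
  labels <- rownames(vals)

  sds <- apply(vals, 1L, stats::sd)
  constant <- labels[sds == 0]
  z <- (vals - rowMeans(vals)) / ifelse(sds > 0, sds, 1)

  # active clusters: centroids of z-profiles; id < 0 marks singleton -i,
  # id > 0 marks the cluster formed at merge step id (hclust convention)
  centroids <- z
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  min_label <- labels
  alive <- rep(TRUE, n + n - 1)[seq_len(n)]
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  cor_dist <- function(a, b) {
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) return(1) # correlation 0 convention
    1 - stats::cor(a, b)
  }

  n_inv <- 0L
  for (step in seq_len(n - 1)) {
    act <- which(alive)
    k <- length(act)
    best <- NULL; best_d <- Inf
    for (ii in seq_len(k - 1)) {
      for (jj in (ii + 1):k) {
        a <- act[ii]; b <- act[jj]
        d <- cor_dist(centroids[a, ], centroids[b, ])
        pick <- FALSE
        if (d < best_d - 1e-12) pick <- TRUE
        else if (abs(d - best_d) <= 1e-12 && !is.null(best)) {
          # tie: smallest lexicographic pair of minimal leaf labels
          cand <- sort(c(min_label[a], min_label[b]))
          cur <- sort(c(min_label[best[1]], min_label[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
            pick <- TRUE
        }
        if (pick) { best <- c(a, b); best_d <- d }
      }
    }
    a <- best[1]; b <- best[2]
    merge[step, ] <- sort(c(ids[a], ids[b]))
    height[step] <- best_d
    if (step > 1 && best_d < height[step - 1] - 1e-12) n_inv <- n_inv + 1L
    # merged centroid = mean profile over all member genes
    mem <- c(members[[a]], members[[b]])
    centroids[a, ] <- colMeans(z[mem, , drop = FALSE])
    members[[a]] <- mem
    ids[a] <- step
    min_label[a] <- min(min_label[a], min_label[b])
    alive[b] <- FALSE
  }

  order_leaves <- function(m) {
    rec <- function(i) {
      if (i < 0) return(-i)
      c(rec(m[i, 1]), rec(m[i, 2]))
    }
    rec(nrow(m))
  }
  hc <- structure(list(merge = merge, height = height,
                       order = order_leaves(merge), labels = labels,
                       method = "centroid",
                       dist.method = "1-pearson",
                       call = match.call()),
                  class = "hclust")
  attr(hc, "n_inversions") <- n_inv
  attr(hc, "constant_genes") <- constant
  hc
}

#' Export a dendrogram as Newick-like nested text
#'
#' @param hc an `hclust` object (e.g. from [profile_hclust()]).
#' @param digits branch-length digits.
#' @return single character string in Newick format.
#' @export
dendrogram_newick <- function(hc, digits = 6) {
  m <- hc$merge; h <- hc$height; lab <- hc$labels
  node_h <- function(i) if (i < 0) 0 else h[i]
  rec <- function(i, parent_h) {
    bl <- format(max(parent_h - node_h(i), 0), digits = digits)
    if (i < 0) return(paste0(lab[-i], ":", bl))
    paste0("(", rec(m[i, 1], h[i]), ",", rec(m[i, 2], h[i]), "):", bl)
  }
  top <- nrow(m)
  paste0("(", rec(m[top, 1], h[top]), ",", rec(m[top, 2], h[top]), ");")
}
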
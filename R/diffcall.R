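#' Unpaired two-sample test on expression indices
#'
#' Two-sided unpaired t-test, Welch (unequal variance) by default, applied
#' to log-transformed expression indices.  When both groups have zero
#' variance the p-value degenerates to 1 for equal means and 0 otherwise.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param flavor `"welch"` (default) or `"student"` (pooled variance).
#' @param log_scale test on `log(pmax(x, eps))` (default TRUE).
#' @param eps floor applied before the log transform.
#' @return two-sided p-value.
#' @export
unpaired_test <- function(group_a, group_b, flavor = c("welch", "student"),
                          log_scale = TRUE, eps = 1) {
  flavor <- match.arg(flavor)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (log_scale) {
    group_a <- log(pmax(group_a, eps))
    group_b <- log(pmax(group_b, eps))
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0)
    return(if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1 else 0)
  stats::t.test(group_a, group_b,
                var.equal = (flavor == "student"))$p.value
}

# Vectorized row-wise unpaired t-test between two matrices of replicates.
# Returns a p-value per row; rows with any NA give NA.
row_unpaired_p <- function(a, b, flavor = "welch", log_scale = TRUE, eps = 1) {
  if (log_scale) {
    a <- log(pmax(a, eps)); b <- log(pmax(b, eps))
  }
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  p <- rep(NA_real_, nrow(a))
  both_zero <- !is.na(va) & !is.na(vb) & va == 0 & vb == 0
  if (flavor == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(tt))
  } else {
    s2 <- va / na + vb / nb
    tt <- (ma - mb) / sqrt(s2)
    df <- s2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  ok <- !both_zero & is.finite(tt) & is.finite(df) & df > 0
  p[ok] <- 2 * stats::pt(-abs(tt[ok]), df[ok])
  p[both_zero] <- ifelse(abs(ma[both_zero] - mb[both_zero]) < 1e-12, 1, 0)
  p
}

# Columns of the expression matrix belonging to one condition/timepoint.
group_cols <- function(samples, condition, timepoint = NULL) {
  sel <- samples$condition == condition
  if (!is.null(timepoint)) sel <- sel & samples$timepoint %in% timepoint
  which(sel & !is.na(sel))
}

# Row-wise group moments (mean and combined SE), vectorized counterpart of
# group_moments().
row_group_moments <- function(theta, se, cols, se_mode = "combined") {
  x <- theta[, cols, drop = FALSE]
  n <- ncol(x)
  m <- rowMeans(x)
  v_between <- if (n > 1) rowSums((x - m)^2) / (n - 1) else 0
  v_within <- if (!is.null(se) && se_mode == "combined")
    rowMeans(se[, cols, drop = FALSE]^2) else 0
  v_within[!is.finite(v_within)] <- 0
  list(mean = m, se = sqrt((v_between + v_within) / n), n = n)
}

# One treated-vs-reference contrast on every transcript: fold change, CI in
# both directions, p-value.
row_contrast <- function(expr, ref_cols, trt_cols, level, flavor, se_mode) {
  gr <- row_group_moments(expr$theta, expr$se, ref_cols, se_mode)
  gt <- row_group_moments(expr$theta, expr$se, trt_cols, se_mode)
  z <- stats::qnorm(1 - (1 - level) / 2)
  fc <- gt$mean / gr$mean
  lcb <- pmax(0, gt$mean - z * gt$se) / (gr$mean + z * gr$se)
  den <- gr$mean - z * gr$se
  ucb <- ifelse(!is.na(den) & den <= 0, Inf, (gt$mean + z * gt$se) / den)
  # reciprocal comparison (reference/treated), for down-calls
  rlcb <- pmax(0, gr$mean - z * gr$se) / (gt$mean + z * gt$se)
  p <- row_unpaired_p(expr$theta[, ref_cols, drop = FALSE],
                      expr$theta[, trt_cols, drop = FALSE], flavor = flavor)
  data.frame(fc = fc, lcb = lcb, ucb = ucb, rlcb = rlcb, p = p)
}

#' Per-transcript differential table for the two-timepoint design
#'
#' Computes, for every transcript, the treated-vs-control fold change with
#' its confidence interval (both directions) and unpaired p-value at each
#' timepoint, plus the treated and control time-course contrasts
#' (D14 vs D3) used by the rescue clause of [call_regulated()].
#'
#' @param expr an `expression_index` containing control/treated samples at
#'   timepoints D3 and D14.
#' @param level confidence level of the fold-change intervals.
#' @param flavor t-test flavor, `"welch"` or `"student"`.
#' @param se_mode group-SE pooling mode, see [group_fold_change_ci()].
#' @return data.frame with one row per transcript, columns
#'   `fc/lcb/ucb/rlcb/p` suffixed `_d3`, `_d14`, `_tc` (treated D14 vs D3)
#'   and `_tcc` (control D14 vs D3).
#' @export
differential_table <- function(expr, level = 0.90,
                               flavor = c("welch", "student"),
                               se_mode = c("combined", "scatter")) {
  flavor <- match.arg(flavor); se_mode <- match.arg(se_mode)
  s <- expr$samples
  cols <- list(
    ctrl_d3 = group_cols(s, "control", "D3"),
    trt_d3 = group_cols(s, "treated", "D3"),
    ctrl_d14 = group_cols(s, "control", "D14"),
    trt_d14 = group_cols(s, "treated", "D14"))
  if (any(lengths(cols) < 2))
    stop("need >= 2 replicates in every condition x timepoint group",
         call. = FALSE)
  d3 <- row_contrast(expr, cols$ctrl_d3, cols$trt_d3, level, flavor, se_mode)
  d14 <- row_contrast(expr, cols$ctrl_d14, cols$trt_d14, level, flavor, se_mode)
  tc <- row_contrast(expr, cols$trt_d3, cols$trt_d14, level, flavor, se_mode)
  tcc <- row_contrast(expr, cols$ctrl_d3, cols$ctrl_d14, level, flavor, se_mode)
  names(d3) <- paste0(names(d3), "_d3")
  names(d14) <- paste0(names(d14), "_d14")
  names(tc) <- paste0(names(tc), "_tc")
  names(tcc) <- paste0(names(tcc), "_tcc")
  out <- cbind(data.frame(transcript_id = rownames(expr$theta),
                          stringsAsFactors = FALSE), d3, d14, tc, tcc)
  rownames(out) <- NULL
  out
}

#' Apply the compound regulated-transcript rule
#'
#' A transcript is called up-regulated when the fold-change lower
#' confidence bound (LCB) reaches `fold_threshold` with unpaired
#' `p < alpha` at day 3 and/or day 14; down-regulation is judged
#' symmetrically on the LCB of the reciprocal (control/treated)
#' comparison.  Transcripts failing both clauses are rescued when the
#' treated time-course contrast (D14 vs D3) passes the same LCB + p rule
#' while the control time-course does not; the call direction then follows
#' the time course.  `call_basis` lists every clause that fired.
#'
#' @param tab a [differential_table()].
#' @param fold_threshold LCB threshold (default 1.5).
#' @param alpha significance threshold (default 0.05).
#' @param p_adjust optional multiple-testing correction applied to the
#'   per-contrast p-values before thresholding (`"none"`, default, or
#'   `"BH"`).
#' @return the table with added columns `call` (`up`/`down`/`none`) and
#'   `call_basis` (comma-separated subset of `D3,D14,timecourse`).
#' @export
call_regulated <- function(tab, fold_threshold = 1.5, alpha = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  padj <- function(p) if (p_adjust == "BH") stats::p.adjust(p, "BH") else p
  p_d3 <- padj(tab$p_d3); p_d14 <- padj(tab$p_d14)
  p_tc <- padj(tab$p_tc); p_tcc <- padj(tab$p_tcc)

  ok <- function(x) !is.na(x)
  up3 <- ok(tab$lcb_d3) & ok(p_d3) & tab$lcb_d3 >= fold_threshold & p_d3 < alpha
  up14 <- ok(tab$lcb_d14) & ok(p_d14) & tab$lcb_d14 >= fold_threshold & p_d14 < alpha
  dn3 <- ok(tab$rlcb_d3) & ok(p_d3) & tab$rlcb_d3 >= fold_threshold & p_d3 < alpha
  dn14 <- ok(tab$rlcb_d14) & ok(p_d14) & tab$rlcb_d14 >= fold_threshold & p_d14 < alpha

  tc_up <- ok(tab$lcb_tc) & ok(p_tc) & tab$lcb_tc >= fold_threshold & p_tc < alpha
  tc_dn <- ok(tab$rlcb_tc) & ok(p_tc) & tab$rlcb_tc >= fold_threshold & p_tc < alpha
  ctrl_pass <- (ok(tab$lcb_tcc) & ok(p_tcc) &
                  tab$lcb_tcc >= fold_threshold & p_tcc < alpha) |
               (ok(tab$rlcb_tcc) & ok(p_tcc) &
                  tab$rlcb_tcc >= fold_threshold & p_tcc < alpha)

  call <- rep("none", nrow(tab))
  call[up3 | up14] <- "up"
  call[dn3 | dn14] <- "down"
  rescue <- call == "none" & (tc_up | tc_dn) & !ctrl_pass
  call[rescue & tc_up] <- "up"
  call[rescue & tc_dn] <- "down"

  basis <- character(nrow(tab))
  direct <- call != "none" & !rescue
  if (any(direct))
    basis[direct] <- mapply(
      function(a, b) paste(c("D3", "D14")[c(a, b)], collapse = ","),
      (up3 | dn3)[direct], (up14 | dn14)[direct], USE.NAMES = FALSE)
  basis[rescue & call != "none"] <- "timecourse"

  tab$call <- call
  tab$call_basis <- basis
  tab
}

#' Build the target-enriched reference gene set
#'
#' Transcripts whose target-vs-source fold-change LCB reaches
#' `fold_threshold` with unpaired `p < alpha` form the set that a complete
#' source-to-target conversion would have to activate (the denominator of
#' the path-completion fraction).
#'
#' @param expr an `expression_index` containing source and target samples.
#' @param fold_threshold LCB threshold (default 1.5).
#' @param alpha significance threshold (default 0.01).
#' @param level confidence level of the fold-change interval.
#' @param target_condition,source_condition condition labels in the sample
#'   metadata.
#' @param flavor,se_mode see [differential_table()].
#' @param name name of the returned gene set.
#' @return a [gene_set()] of enriched transcript ids, with the underlying
#'   per-transcript statistics attached as attribute `"stats"`.
#' @export
build_enriched_set <- function(expr, fold_threshold = 1.5, alpha = 0.01,
                               level = 0.90,
                               target_condition = "target",
                               source_condition = "source",
                               flavor = c("welch", "student"),
                               se_mode = c("combined", "scatter"),
                               name = "target_enriched") {
  flavor <- match.arg(flavor); se_mode <- match.arg(se_mode)
  src <- group_cols(expr$samples, source_condition)
  tgt <- group_cols(expr$samples, target_condition)
  if (length(src) < 2 || length(tgt) < 2)
    stop("need >= 2 samples in both source and target groups", call. = FALSE)
  ct <- row_contrast(expr, src, tgt, level, flavor, se_mode)
  sel <- !is.na(ct$lcb) & !is.na(ct$p) &
    ct$lcb >= fold_threshold & ct$p < alpha
  gs <- gene_set(name, rownames(expr$theta)[sel])
  attr(gs, "stats") <- cbind(
    data.frame(transcript_id = rownames(expr$theta)), ct)
  gs
}

#' Collapse probeset-level calls to genes
#'
#' Where several probesets interrogate one gene, gene-level counting keeps
#' the probeset with the largest mean expression index across the given
#' samples.
#'
#' @param ids character vector of probeset ids.
#' @param expr the `expression_index` the ids came from (must carry a
#'   `gene_map`).
#' @return character vector of gene ids (one per represented gene).
#' @export
collapse_to_genes <- function(ids, expr) {
  gm <- expr$gene_map
  if (is.null(gm)) return(unique(ids))
  genes <- gm[ids]
  genes[is.na(genes)] <- ids[is.na(genes)]
  if (!anyDuplicated(genes)) return(unname(genes))
  mu <- rowMeans(expr$theta[ids, , drop = FALSE], na.rm = TRUE)
  keep <- tapply(seq_along(ids), genes, function(k) k[which.max(mu[k])])
  unname(genes[unlist(keep)])
}

#' Gene-level view of a probeset-level expression matrix
#'
#' Re-indexes an `expression_index` by gene id using its probeset-to-gene
#' map; where several probesets interrogate one gene, the probeset with
#' the largest mean expression is kept.
#'
#' @param expr an `expression_index`.
#' @return an `expression_index` whose rows are gene ids (unchanged when
#'   no gene map is attached).
#' @export
as_gene_level <- function(expr) {
  gm <- expr$gene_map
  if (is.null(gm)) return(expr)
  ids <- rownames(expr$theta)
  genes <- gm[ids]
  genes[is.na(genes)] <- ids[is.na(genes)]
  mu <- rowMeans(expr$theta, na.rm = TRUE)
  keep <- as.integer(tapply(seq_along(ids), genes,
                            function(k) k[which.max(mu[k])]))
  out <- expr
  out$theta <- expr$theta[keep, , drop = FALSE]
  out$se <- expr$se[keep, , drop = FALSE]
  rn <- unname(genes[keep])
  rownames(out$theta) <- rownames(out$se) <- rn
  out$unreliable <- stats::setNames(expr$unreliable[keep], rn)
  out$gene_map <- NULL
  out$phi <- NULL
  out$outlier_mask <- NULL
  out
}
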
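#' Probe-level intensity container
#'
#' Holds perfect-match (PM) and mismatch (MM) intensities for a set of
#' arrays, with probes grouped into probesets and per-array sample
#' metadata.
#'
#' @param pm,mm numeric matrices, probes x arrays, identical shape, finite
#'   and >= 0.
#' @param probeset_id character, one entry per probe row.
#' @param probe_index integer probe position within its probeset.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `timepoint`, `replicate`; one row per array column.
#' @param gene_map optional named character vector probeset_id -> gene_id.
#' @return object of class `probe_matrix`.
#' @export
probe_matrix <- function(pm, mm, probeset_id, probe_index, samples,
                         gene_map = NULL) {
  pm <- as.matrix(pm); mm <- as.matrix(mm)
  if (!identical(dim(pm), dim(mm)))
    stop("PM and MM must have identical shape", call. = FALSE)
  if (any(!is.finite(pm)) || any(!is.finite(mm)) ||
      any(pm < 0) || any(mm < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  if (length(probeset_id) != nrow(pm) || length(probe_index) != nrow(pm))
    stop("probeset_id/probe_index must match probe rows", call. = FALSE)
  if (nrow(samples) != ncol(pm))
    stop("samples must have one row per array", call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique", call. = FALSE)
  ord <- order(match(probeset_id, unique(probeset_id)), probe_index)
  structure(list(pm = pm[ord, , drop = FALSE], mm = mm[ord, , drop = FALSE],
                 probeset_id = probeset_id[ord],
                 probe_index = probe_index[ord],
                 samples = as.data.frame(samples),
                 gene_map = gene_map),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes in %d probesets x %d arrays\n",
              nrow(x$pm), length(unique(x$probeset_id)), ncol(x$pm)))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize arrays to the median-intensity array
#'
#' The array whose overall mean intensity is the median of the per-array
#' means is taken as the reference; every other array is linearly rescaled
#' so its mean intensity equals the reference mean.  With an even number of
#' arrays the lower-mean array of the middle pair is the reference.  The
#' reference array is returned unchanged and the per-array scale factors
#' are attached as attribute `"scale_factors"`.
#'
#' @param probes a [probe_matrix()].
#' @return a normalized `probe_matrix` with attributes `scale_factors`
#'   (named numeric) and `reference_array` (sample id).
#' @export
normalize_to_median_array <- function(probes) {
  stopifnot(inherits(probes, "probe_matrix"))
  n_arr <- ncol(probes$pm)
  if (n_arr < 1L) stop("need at least one array", call. = FALSE)
  means <- (colMeans(probes$pm) + colMeans(probes$mm)) / 2
  zero <- which(means <= 0)
  if (length(zero))
    stop(sprintf("cannot normalize: array '%s' has zero overall intensity",
                 probes$samples$sample_id[zero[1]]), call. = FALSE)
  ord <- order(means)
  ref <- if (n_arr %% 2L == 1L) ord[(n_arr + 1L) %/% 2L] else ord[n_arr %/% 2L]
  factors <- means[ref] / means
  factors[ref] <- 1 # reference untouched, exactly
  probes$pm <- sweep(probes$pm, 2L, factors, `*`)
  probes$mm <- sweep(probes$mm, 2L, factors, `*`)
  attr(probes, "scale_factors") <-
    stats::setNames(factors, probes$samples$sample_id)
  attr(probes, "reference_array") <- probes$samples$sample_id[ref]
  probes
}

#' Fit the model-based expression index
#'
#' For every probeset, fits the multiplicative model
#' `y_ij = PM_ij - MM_ij ~ theta_i * phi_j` (array i, probe j) by
#' alternating least squares under the identifiability constraint
#' `sum_j phi_j^2 = J`, with iterative outlier exclusion: cells whose
#' residual exceeds `outlier_z` robust standard deviations are masked,
#' then whole probes/arrays with more than half of their cells masked, and
#' the model is refitted (at most `max_rounds` exclusion rounds).  Negative
#' mismatch-corrected differences are floored at `eps_floor`.
#'
#' @param probes a normalized [probe_matrix()].
#' @param eps_floor floor for `PM - MM` (and fitted theta), in intensity
#'   units.
#' @param outlier_z standardized-residual threshold for cell exclusion.
#' @param max_rounds maximum outlier-exclusion rounds.
#' @return object of class `expression_index` with elements `theta`
#'   (transcripts x samples), `se` (same shape), `phi` (per-probe fitted
#'   sensitivities), `outlier_mask` (probe x array exclusion flags),
#'   `unreliable` (per-transcript flag), `samples`, `gene_map`.
#' @export
fit_expression_index <- function(probes, eps_floor = 1, outlier_z = 3,
                                 max_rounds = 5L) {
  stopifnot(inherits(probes, "probe_matrix"))
  y <- probes$pm - probes$mm
  y[y < eps_floor] <- eps_floor
  sets <- unique(probes$probeset_id)
  set_sizes <- as.integer(table(factor(probes$probeset_id, levels = sets)))
  fit <- mbei_fit_cpp(y, set_sizes, outlier_z = outlier_z,
                      max_rounds = as.integer(max_rounds),
                      theta_floor = eps_floor)
  theta <- fit$theta; se <- fit$se
  dimnames(theta) <- dimnames(se) <- list(sets, probes$samples$sample_id)
  theta[fit$unreliable, ] <- NA_real_
  se[fit$unreliable, ] <- NA_real_
  structure(list(theta = theta, se = se,
                 phi = stats::setNames(fit$phi, probes$probeset_id),
                 outlier_mask = fit$mask == 1L,
                 unreliable = stats::setNames(as.logical(fit$unreliable), sets),
                 samples = probes$samples,
                 gene_map = probes$gene_map),
            class = "expression_index")
}

#' @export
print.expression_index <- function(x, ...) {
  cat(sprintf("expression_index: %d transcripts x %d samples (%d unreliable)\n",
              nrow(x$theta), ncol(x$theta), sum(x$unreliable)))
  invisible(x)
}

#' Expression-matrix container from pre-summarized data
#'
#' Wraps an existing transcript x sample matrix (and optional standard
#' errors) as an `expression_index`, for workflows starting from
#' pre-summarized data rather than probe-level intensities.
#'
#' @param theta transcript x sample numeric matrix.
#' @param samples sample metadata data.frame (see [probe_matrix()]).
#' @param se optional matrix of standard errors (defaults to 0).
#' @param gene_map optional probeset -> gene map.
#' @return an `expression_index`.
#' @export
expression_index <- function(theta, samples, se = NULL, gene_map = NULL) {
  theta <- as.matrix(theta)
  if (is.null(se)) se <- matrix(0, nrow(theta), ncol(theta),
                                dimnames = dimnames(theta))
  if (nrow(samples) != ncol(theta))
    stop("samples must have one row per column of theta", call. = FALSE)
  colnames(theta) <- colnames(se) <- samples$sample_id
  structure(list(theta = theta, se = as.matrix(se), phi = NULL,
                 outlier_mask = NULL,
                 unreliable = stats::setNames(rep(FALSE, nrow(theta)),
                                              rownames(theta)),
                 samples = as.data.frame(samples), gene_map = gene_map),
            class = "expression_index")
}

#' Fold-change confidence interval from group moments
#'
#' Computes the ratio of group means with a normal-theory confidence
#' interval whose lower bound (LCB) is the conservative
#' differential-expression measure: with `z` the two-sided normal quantile
#' for the level,
#' `lcb = max(0, trt_mean - z * trt_se) / (ref_mean + z * ref_se)` and
#' `ucb = (trt_mean + z * trt_se) / (ref_mean - z * ref_se)`, the latter
#' `+Inf` when its denominator is floored at zero.  All arguments are
#' vectorized.
#'
#' @param ref_mean,ref_se reference-group mean and standard error.
#' @param trt_mean,trt_se treated-group mean and standard error.
#' @param level confidence level (default 0.90).
#' @return data.frame with columns `fc`, `lcb`, `ucb`, `level`.
#' @export
fold_change_ci <- function(ref_mean, ref_se, trt_mean, trt_se, level = 0.90) {
  if (any(!is.na(ref_mean) & ref_mean <= 0))
    stop("reference group mean must be > 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  fc <- trt_mean / ref_mean
  lcb <- pmax(0, trt_mean - z * trt_se) / (ref_mean + z * ref_se)
  den <- ref_mean - z * ref_se
  ucb <- ifelse(den <= 0, Inf, (trt_mean + z * trt_se) / den)
  data.frame(fc = fc, lcb = lcb, ucb = ucb, level = level)
}

# Group-level standard error of the mean: between-replicate scatter of the
# expression indices combined in quadrature with the mean within-sample
# squared standard error (se_mode = "combined"), or scatter only
# (se_mode = "scatter").
group_moments <- function(values, ses = NULL, se_mode = c("combined", "scatter")) {
  se_mode <- match.arg(se_mode)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) return(c(mean = NA_real_, se = NA_real_, n = 0))
  m <- mean(values)
  v_between <- if (n > 1) stats::var(values) else 0
  v_within <- if (!is.null(ses) && se_mode == "combined")
    mean(ses[!is.na(ses)]^2, na.rm = TRUE) else 0
  if (!is.finite(v_within)) v_within <- 0
  c(mean = m, se = sqrt((v_between + v_within) / n), n = n)
}

#' Fold-change confidence interval between two replicate groups
#'
#' Convenience wrapper around [fold_change_ci()]: computes group means and
#' standard errors from replicate expression indices (optionally combining
#' per-sample standard errors from the probe-model fit in quadrature with
#' the between-replicate scatter) and returns the fold change with its
#' confidence interval.
#'
#' @param ref,trt numeric vectors of per-replicate expression indices.
#' @param ref_se,trt_se optional per-replicate standard errors.
#' @param level confidence level.
#' @param se_mode `"combined"` (scatter + within-sample error, default) or
#'   `"scatter"`.
#' @return one-row data.frame as in [fold_change_ci()].
#' @export
group_fold_change_ci <- function(ref, trt, ref_se = NULL, trt_se = NULL,
                                 level = 0.90,
                                 se_mode = c("combined", "scatter")) {
  se_mode <- match.arg(se_mode)
  if (length(ref) < 1 || length(trt) < 1)
    stop("each group needs at least one value", call. = FALSE)
  gr <- group_moments(ref, ref_se, se_mode)
  gt <- group_moments(trt, trt_se, se_mode)
  fold_change_ci(gr["mean"], gr["se"], gt["mean"], gt["se"], level = level)
}
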
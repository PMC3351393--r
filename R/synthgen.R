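#' Simulation configuration for a synthetic reprogramming experiment
#'
#' Builds and validates the parameter set that drives the synthetic
#' probe-level data generator.  Defaults emulate the study design the
#' analysis was built for: three replicate arrays per condition, a
#' control/treated contrast sampled at 3 and 14 days post transduction,
#' untransduced source-cell (duct) and target-cell (islet endocrine)
#' profiles, a target-enriched set of transcripts higher in the target
#' state, and a designated ground-truth activated set covering a fraction
#' `reprogramming_fraction_f` of the target-enriched set.
#'
#' @param n_transcripts number of transcripts (one probeset per transcript
#'   by default).
#' @param probes_per_set probe pairs per probeset.
#' @param n_replicates replicate arrays per condition x timepoint.
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   per-transcript baseline expression index.
#' @param probe_sensitivity_sd log-sd of multiplicative probe sensitivities.
#' @param noise_sd log-scale sd of the per-cell measurement noise.
#' @param target_enriched_size number of transcripts enriched in the target
#'   (endocrine) state relative to the source (duct) state.
#' @param n_activated number of transcripts activated by the treatment.
#' @param n_suppressed number of transcripts suppressed by the treatment.
#' @param reprogramming_fraction_f fraction of the target-enriched set that
#'   the activated set covers (the quantity the path-completion score
#'   estimates).
#' @param effect_fold_range length-2 numeric, both > 1; treatment folds are
#'   drawn uniformly on the log scale over this range.
#' @param d3_only_frac,d14_only_frac,both_frac temporal mix of activated
#'   (and suppressed) transcripts; must sum to 1.
#' @param block_fracs named numeric with entries `endocrine`, `cns`,
#'   `shared`: tissue-block composition of the activated set (remainder is
#'   background).
#' @param atlas_tissues named character vector: names are tissue labels,
#'   values their category, one of `"endocrine"`, `"cns"`, `"other"`.
#' @param atlas_fold fold elevation of a block gene in its own tissues.
#' @param atlas_noise_sd log-scale noise of atlas values.
#' @param background_intensity additive optical background of the arrays.
#' @param mm_fraction fraction of the background-subtracted PM signal that
#'   leaks into the MM probe.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 20000L,
                       probes_per_set = 11L,
                       n_replicates = 3L,
                       baseline_log_mean = log(150),
                       baseline_log_sd = 1.0,
                       probe_sensitivity_sd = 0.3,
                       noise_sd = 0.2,
                       target_enriched_size = 1128L,
                       n_activated = 140L,
                       n_suppressed = 48L,
                       reprogramming_fraction_f = 63 / 1128,
                       effect_fold_range = c(1.8, 80),
                       d3_only_frac = 35 / 140,
                       d14_only_frac = 72 / 140,
                       both_frac = 33 / 140,
                       block_fracs = c(endocrine = 0.25, cns = 0.25, shared = 0.20),
                       atlas_tissues = default_atlas_tissues(),
                       atlas_fold = 10,
                       atlas_noise_sd = 0.2,
                       background_intensity = 50,
                       mm_fraction = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    probes_per_set = as.integer(probes_per_set),
    n_replicates = as.integer(n_replicates),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    probe_sensitivity_sd = probe_sensitivity_sd,
    noise_sd = noise_sd,
    target_enriched_size = as.integer(target_enriched_size),
    n_activated = as.integer(n_activated),
    n_suppressed = as.integer(n_suppressed),
    reprogramming_fraction_f = reprogramming_fraction_f,
    effect_fold_range = effect_fold_range,
    d3_only_frac = d3_only_frac,
    d14_only_frac = d14_only_frac,
    both_frac = both_frac,
    block_fracs = block_fracs,
    atlas_tissues = atlas_tissues,
    atlas_fold = atlas_fold,
    atlas_noise_sd = atlas_noise_sd,
    background_intensity = background_intensity,
    mm_fraction = mm_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default synthetic tissue panel
#'
#' A compact stand-in for a multi-tissue expression compendium: endocrine
#' tissues, central-nervous-system tissues, and a spread of other organs.
#' @return named character vector mapping tissue label to category.
#' @export
default_atlas_tissues <- function() {
  c(pancreatic_islet = "endocrine", beta_cell_fraction = "endocrine",
    endocrine_pancreas = "endocrine",
    cortex = "cns", cerebellum = "cns", hippocampus = "cns",
    liver = "other", kidney = "other", lung = "other", heart = "other",
    skeletal_muscle = "other", spleen = "other", thymus = "other",
    colon = "other", stomach = "other", testis = "other", ovary = "other",
    adipose = "other", skin = "other", bone_marrow = "other",
    placenta = "other", duct_cells = "other", salivary_gland = "other",
    prostate = "other", adrenal_gland = "other", small_intestine = "other")
}

config_error <- function(field, msg) {
  stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
       call. = FALSE)
}

validate_sim_config <- function(cfg) {
  for (f in c("n_transcripts", "probes_per_set", "n_replicates"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) config_error(f, "must be >= 1")
  for (f in c("target_enriched_size", "n_activated", "n_suppressed"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) config_error(f, "must be >= 0")
  for (f in c("baseline_log_sd", "probe_sensitivity_sd", "noise_sd",
              "atlas_noise_sd"))
    if (cfg[[f]] < 0) config_error(f, "must be >= 0")
  f <- cfg$reprogramming_fraction_f
  if (is.na(f) || f < 0 || f > 1)
    config_error("reprogramming_fraction_f", "must lie in [0, 1]")
  r <- cfg$effect_fold_range
  if (length(r) != 2L || any(r <= 1) || r[1] > r[2])
    config_error("effect_fold_range", "must be two values > 1, increasing")
  mix <- cfg$d3_only_frac + cfg$d14_only_frac + cfg$both_frac
  if (any(c(cfg$d3_only_frac, cfg$d14_only_frac, cfg$both_frac) < 0) ||
      abs(mix - 1) > 1e-9)
    config_error("d3_only_frac/d14_only_frac/both_frac", "must sum to 1")
  bf <- cfg$block_fracs
  if (!all(c("endocrine", "cns", "shared") %in% names(bf)) ||
      any(bf < 0) || sum(bf) > 1 + 1e-9)
    config_error("block_fracs",
                 "needs endocrine/cns/shared entries summing to <= 1")
  at <- cfg$atlas_tissues
  if (length(at) < 1L) config_error("atlas_tissues", "must not be empty")
  if (!all(at %in% c("endocrine", "cns", "other")))
    config_error("atlas_tissues",
                 "categories must be endocrine, cns or other")
  if (cfg$target_enriched_size + cfg$n_suppressed > cfg$n_transcripts ||
      cfg$n_activated > cfg$n_transcripts)
    config_error("n_transcripts", "too small for the configured gene sets")
  n_overlap <- round(cfg$reprogramming_fraction_f * cfg$target_enriched_size)
  if (cfg$n_activated < n_overlap)
    config_error("n_activated",
                 "must be >= reprogramming_fraction_f * target_enriched_size")
  if (cfg$mm_fraction < 0 || cfg$mm_fraction >= 1)
    config_error("mm_fraction", "must lie in [0, 1)")
  invisible(cfg)
}

# Split n into three counts matching (d3, d14, both) fractions; rounding
# remainder goes to the 'both' category, realized counts within 1 of target.
split_temporal <- function(n, cfg) {
  n_d3 <- round(cfg$d3_only_frac * n)
  n_d14 <- round(cfg$d14_only_frac * n)
  n_both <- n - n_d3 - n_d14
  if (n_both < 0) { # rounding overshoot
    n_d14 <- n_d14 + n_both
    n_both <- 0L
  }
  c(d3_only = n_d3, d14_only = n_d14, both = n_both)
}

#' Generate a synthetic probe-level reprogramming experiment
#'
#' Simulates perfect-match/mismatch probe intensities for
#' control/treated arrays at two timepoints plus untransduced source-cell
#' and target-cell arrays, under the multiplicative model
#' `PM - background = theta_gene(array) * phi_probe * exp(noise)`,
#' with `MM = background + mm_fraction * (PM - background)` so that the
#' mismatch-corrected signal `PM - MM` is an unbiased carrier of the
#' simulated expression index.  The returned truth object records exactly
#' which genes carry treatment effects, their per-timepoint folds, their
#' tissue-block membership and the realized reprogramming fraction.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `probes` (a `probe_matrix`) and `truth`
#'   (a `synthetic_truth` list).
#' @export
generate_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_transcripts
  J <- config$probes_per_set
  gene_ids <- sprintf("G%06d", seq_len(n))
  probeset_ids <- sprintf("PS%06d", seq_len(n))

  ## ---- ground-truth sets -------------------------------------------------
  target_idx <- sort(sample.int(n, config$target_enriched_size))
  n_overlap <- round(config$reprogramming_fraction_f *
                     config$target_enriched_size)
  act_in <- if (n_overlap > 0) sort(sample(target_idx, n_overlap)) else integer(0)
  pool_out <- setdiff(seq_len(n), target_idx)
  n_act_out <- config$n_activated - n_overlap
  act_out <- if (n_act_out > 0) sort(sample(pool_out, n_act_out)) else integer(0)
  activated_idx <- sort(c(act_in, act_out))
  pool_sup <- setdiff(seq_len(n), union(target_idx, activated_idx))
  suppressed_idx <- if (config$n_suppressed > 0)
    sort(sample(pool_sup, config$n_suppressed)) else integer(0)

  ## ---- temporal patterns and folds --------------------------------------
  draw_folds <- function(k) {
    lr <- log(config$effect_fold_range)
    exp(stats::runif(k, lr[1], lr[2]))
  }
  assign_effects <- function(idx) {
    k <- length(idx)
    out <- data.frame(idx = idx, pattern = character(k),
                      fold_d3 = rep(1, k), fold_d14 = rep(1, k),
                      stringsAsFactors = FALSE)
    if (k == 0) return(out)
    counts <- split_temporal(k, config)
    pat <- rep(names(counts), counts)
    pat <- sample(pat) # which gene gets which pattern is random
    out$pattern <- pat
    on3 <- pat %in% c("d3_only", "both")
    on14 <- pat %in% c("d14_only", "both")
    out$fold_d3[on3] <- draw_folds(sum(on3))
    out$fold_d14[on14] <- draw_folds(sum(on14))
    out
  }
  eff_act <- assign_effects(activated_idx)
  eff_sup <- assign_effects(suppressed_idx)
  eff_sup$fold_d3 <- 1 / eff_sup$fold_d3   # reciprocal folds for suppression
  eff_sup$fold_d14 <- 1 / eff_sup$fold_d14

  fold_d3 <- rep(1, n); fold_d14 <- rep(1, n)
  fold_d3[eff_act$idx] <- eff_act$fold_d3
  fold_d14[eff_act$idx] <- eff_act$fold_d14
  fold_d3[eff_sup$idx] <- eff_sup$fold_d3
  fold_d14[eff_sup$idx] <- eff_sup$fold_d14

  target_fold <- rep(1, n)
  target_fold[target_idx] <- draw_folds(length(target_idx))

  ## ---- tissue blocks -----------------------------------------------------
  tissue_block <- rep("background", n)
  if (length(activated_idx) > 0) {
    k <- length(activated_idx)
    nb <- c(endocrine = round(config$block_fracs[["endocrine"]] * k),
            cns = round(config$block_fracs[["cns"]] * k),
            shared = round(config$block_fracs[["shared"]] * k))
    while (sum(nb) > k) nb[which.max(nb)] <- nb[which.max(nb)] - 1L
    lab <- c(rep(names(nb), nb), rep("background", k - sum(nb)))
    tissue_block[activated_idx] <- sample(lab)
  }
  # target-enriched genes not activated are endocrine-specific by definition
  tissue_block[setdiff(target_idx, activated_idx)] <- "endocrine"

  ## ---- samples -----------------------------------------------------------
  reps <- seq_len(config$n_replicates)
  samples <- rbind(
    expand.grid(replicate = reps, timepoint = c("D3", "D14"),
                condition = c("control", "treated"),
                stringsAsFactors = FALSE)[, c("condition", "timepoint", "replicate")],
    data.frame(condition = rep(c("source", "target"), each = length(reps)),
               timepoint = NA_character_, replicate = rep(reps, 2L))
  )
  samples$sample_id <- ifelse(
    is.na(samples$timepoint),
    sprintf("%s_r%d", samples$condition, samples$replicate),
    sprintf("%s_%s_r%d", substr(samples$condition, 1, 4), samples$timepoint,
            samples$replicate))
  samples <- samples[, c("sample_id", "condition", "timepoint", "replicate")]
  rownames(samples) <- NULL
  I <- nrow(samples)

  ## ---- expression indices and probe intensities --------------------------
  baseline <- stats::rnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  log_theta <- matrix(baseline, n, I)
  for (i in seq_len(I)) {
    cond <- samples$condition[i]; tp <- samples$timepoint[i]
    if (cond == "treated" && identical(tp, "D3"))
      log_theta[, i] <- log_theta[, i] + log(fold_d3)
    if (cond == "treated" && identical(tp, "D14"))
      log_theta[, i] <- log_theta[, i] + log(fold_d14)
    if (cond == "target")
      log_theta[, i] <- log_theta[, i] + log(target_fold)
  }
  theta_true <- exp(log_theta)

  phi <- exp(stats::rnorm(n * J, 0, config$probe_sensitivity_sd))
  phi <- matrix(phi, n, J)
  phi <- phi / sqrt(rowMeans(phi^2))      # sum_j phi^2 = J per probeset

  gene_row <- rep(seq_len(n), each = J)
  probe_row <- rep(seq_len(J), times = n)
  phi_vec <- phi[cbind(gene_row, probe_row)]

  noise <- if (config$noise_sd > 0)
    matrix(exp(stats::rnorm(n * J * I, 0, config$noise_sd)), n * J, I)
  else 1
  signal <- (theta_true[gene_row, , drop = FALSE] * phi_vec) * noise

  bg <- config$background_intensity
  mmf <- config$mm_fraction
  pm <- bg + signal / (1 - mmf)
  mm <- bg + signal * mmf / (1 - mmf)
  colnames(pm) <- colnames(mm) <- samples$sample_id

  probes <- probe_matrix(pm = pm, mm = mm,
                         probeset_id = probeset_ids[gene_row],
                         probe_index = probe_row,
                         samples = samples,
                         gene_map = stats::setNames(gene_ids, probeset_ids))

  truth <- structure(list(
    activated_ids = gene_ids[activated_idx],
    suppressed_ids = gene_ids[suppressed_idx],
    target_enriched_ids = gene_ids[target_idx],
    per_gene_fold = data.frame(gene_id = gene_ids,
                               fold_d3 = fold_d3, fold_d14 = fold_d14,
                               target_fold = target_fold,
                               stringsAsFactors = FALSE),
    temporal_pattern = stats::setNames(
      c(eff_act$pattern, eff_sup$pattern),
      gene_ids[c(eff_act$idx, eff_sup$idx)]),
    tissue_block = stats::setNames(tissue_block, gene_ids),
    f_realized = if (config$target_enriched_size > 0)
      n_overlap / config$target_enriched_size else NA_real_,
    config = config
  ), class = "synthetic_truth")

  list(probes = probes, truth = truth)
}

#' Generate a synthetic multi-tissue expression atlas
#'
#' Builds a genes x tissues matrix consistent with the tissue-block
#' memberships recorded by [generate_experiment()]: endocrine-block genes
#' are elevated only in endocrine-category tissues, cns-block genes only in
#' cns tissues, shared-block genes in both, background genes are uniform.
#'
#' @param config a [sim_config()] object.
#' @param truth the `synthetic_truth` produced from the same config.
#' @param atlas_base baseline atlas intensity.
#' @return an `atlas_matrix` object.
#' @export
generate_atlas <- function(config, truth, atlas_base = 100) {
  validate_sim_config(config)
  tissues <- config$atlas_tissues
  if (length(tissues) == 0) config_error("atlas_tissues", "must not be empty")
  set.seed(config$seed + 424243L)
  genes <- names(truth$tissue_block)
  n <- length(genes); Tn <- length(tissues)
  vals <- matrix(atlas_base, n, Tn,
                 dimnames = list(genes, names(tissues)))
  endo_t <- tissues == "endocrine"
  cns_t <- tissues == "cns"
  blk <- truth$tissue_block
  vals[blk == "endocrine", endo_t] <- atlas_base * config$atlas_fold
  vals[blk == "cns", cns_t] <- atlas_base * config$atlas_fold
  vals[blk == "shared", endo_t | cns_t] <- atlas_base * config$atlas_fold
  if (config$atlas_noise_sd > 0)
    vals <- vals * matrix(exp(stats::rnorm(n * Tn, 0, config$atlas_noise_sd)),
                          n, Tn)
  atlas_matrix(vals, tissue_category = tissues)
}

#' Generate a synthetic gene -> ontology-term annotation
#'
#' Emulates a flat functional annotation over the simulated chip: terms for
#' hormone secretion (endocrine + shared blocks), neurogenesis (cns + shared
#' blocks), transcriptional regulation (a slice of the activated set), and a
#' collection of random background terms that should not come out enriched.
#'
#' @param config a [sim_config()] object.
#' @param truth matching `synthetic_truth`.
#' @param n_background_terms number of random terms.
#' @param background_term_size genes per random term.
#' @return an `annotation_map` object whose universe is the whole chip.
#' @export
generate_annotation <- function(config, truth, n_background_terms = 25L,
                                background_term_size = 150L) {
  validate_sim_config(config)
  set.seed(config$seed + 77777L)
  genes <- names(truth$tissue_block)
  blk <- truth$tissue_block
  terms <- list(
    HORMONE_SECRETION = genes[blk %in% c("endocrine", "shared")],
    NEUROGENESIS = genes[blk %in% c("cns", "shared")]
  )
  act <- truth$activated_ids
  if (length(act) >= 10)
    terms$TRANSCRIPTION_REGULATION <- sort(sample(act, ceiling(length(act) / 4)))
  for (k in seq_len(n_background_terms)) {
    sz <- min(background_term_size, length(genes))
    terms[[sprintf("BACKGROUND_%02d", k)]] <- sort(sample(genes, sz))
  }
  annotation_map(terms, universe = genes)
}
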
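# Small simulation configs for fast tests; study-scale defaults are only
# exercised where a test needs them.

tiny_config <- function(...) {
  defaults <- list(n_transcripts = 300L, probes_per_set = 5L,
                   target_enriched_size = 50L, n_activated = 30L,
                   n_suppressed = 10L, reprogramming_fraction_f = 0.3,
                   effect_fold_range = c(2.5, 12), noise_sd = 0.15,
                   baseline_log_sd = 0.8, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

noiseless_config <- function(...) {
  tiny_config(noise_sd = 0, probe_sensitivity_sd = 0, atlas_noise_sd = 0,
              effect_fold_range = c(4, 4), ...)
}

# probe_matrix from a plain theta (gene x array) and phi (gene x probe)
# specification, with MM = 0 so y = PM exactly.
manual_probes <- function(theta, phi, conditions = NULL) {
  n <- nrow(theta); J <- ncol(phi); I <- ncol(theta)
  gene_row <- rep(seq_len(n), each = J)
  probe_row <- rep(seq_len(J), times = n)
  pm <- theta[gene_row, , drop = FALSE] * phi[cbind(gene_row, probe_row)]
  mm <- matrix(0, nrow(pm), ncol(pm))
  if (is.null(conditions)) conditions <- rep("control", I)
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(I)),
                        condition = conditions,
                        timepoint = NA_character_,
                        replicate = seq_len(I))
  probe_matrix(pm = pm, mm = mm,
               probeset_id = sprintf("PS%03d", gene_row),
               probe_index = probe_row, samples = samples)
}

true_block_labels <- function(truth, genes) {
  map <- c(endocrine = "A", cns = "B", shared = "C", background = "MISC")
  unname(map[truth$tissue_block[genes]])
}
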
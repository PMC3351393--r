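test_that("config validation names the offending field", {
  expect_error(sim_config(n_transcripts = 0), "n_transcripts")
  expect_error(sim_config(reprogramming_fraction_f = 1.2),
               "reprogramming_fraction_f")
  expect_error(sim_config(d3_only_frac = 0.5, d14_only_frac = 0.5,
                          both_frac = 0.5), "must sum to 1")
  expect_error(sim_config(effect_fold_range = c(0.5, 3)),
               "effect_fold_range")
  expect_error(sim_config(atlas_tissues = character(0)), "atlas_tissues")
  expect_error(tiny_config(n_activated = 5L), "n_activated")
})

test_that("activated/target overlap is forced by f and set sizes", {
  cfg <- tiny_config(n_transcripts = 1000L, target_enriched_size = 200L,
                     reprogramming_fraction_f = 0.3, n_activated = 140L)
  tr <- generate_experiment(cfg)$truth
  ov <- intersect(tr$activated_ids, tr$target_enriched_ids)
  expect_length(ov, 60L)
  expect_equal(tr$f_realized, 60 / 200)
  expect_length(tr$activated_ids, 140L)
  expect_length(intersect(tr$activated_ids, tr$suppressed_ids), 0L)
})

test_that("identical seeds give identical output, different seeds differ", {
  cfg <- tiny_config(seed = 42L)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  d <- generate_experiment(tiny_config(seed = 43L))
  expect_false(identical(a$probes$pm, d$probes$pm))
  expect_identical(generate_atlas(cfg, a$truth)$values,
                   generate_atlas(cfg, b$truth)$values)
})

test_that("realized temporal mix matches configured fractions within 1", {
  cfg <- tiny_config(n_activated = 60L, d3_only_frac = 0.25,
                     d14_only_frac = 0.5, both_frac = 0.25)
  tr <- generate_experiment(cfg)$truth
  pat <- table(tr$temporal_pattern[tr$activated_ids])
  expect_lte(abs(pat[["d3_only"]] - 15), 1)
  expect_lte(abs(pat[["d14_only"]] - 30), 1)
  expect_lte(abs(pat[["both"]] - 15), 1)
  # d3-only genes carry no D14 effect and vice versa
  folds <- tr$per_gene_fold
  d3only <- names(tr$temporal_pattern)[tr$temporal_pattern == "d3_only"]
  expect_true(all(folds$fold_d14[folds$gene_id %in% d3only] == 1))
})

test_that("noiseless PM-MM signal equals baseline times treatment fold", {
  cfg <- noiseless_config()
  sim <- generate_experiment(cfg)
  probes <- sim$probes
  y <- probes$pm - probes$mm
  s <- probes$samples
  ctrl <- which(s$condition == "control" & s$timepoint == "D14")[1]
  trt <- which(s$condition == "treated" & s$timepoint == "D14")[1]
  genes <- probes$gene_map[probes$probeset_id]
  fold <- sim$truth$per_gene_fold$fold_d14[
    match(genes, sim$truth$per_gene_fold$gene_id)]
  expect_equal(log(y[, trt]) - log(y[, ctrl]), log(fold),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("synthetic atlas separates tissue blocks by construction", {
  cfg <- noiseless_config()
  tr <- generate_experiment(cfg)$truth
  atlas <- generate_atlas(cfg, tr)
  blk <- tr$tissue_block
  endo_gene <- names(blk)[blk == "endocrine"][1]
  cns_cols <- atlas$tissue_category == "cns"
  endo_cols <- atlas$tissue_category == "endocrine"
  v <- atlas$values[endo_gene, ]
  expect_true(all(v[cns_cols] < mean(v[endo_cols]) / 5))
  bg_gene <- names(blk)[blk == "background"][1]
  expect_equal(unname(endocrine_abundance(bg_gene, atlas)), 1,
               tolerance = 1e-9)
})

test_that("noiseless end-to-end run recovers the truth sets exactly", {
  cfg <- noiseless_config()
  sim <- generate_experiment(cfg)
  expr <- fit_expression_index(normalize_to_median_array(sim$probes))
  calls <- call_regulated(differential_table(expr))
  up <- collapse_to_genes(calls$transcript_id[calls$call == "up"], expr)
  down <- collapse_to_genes(calls$transcript_id[calls$call == "down"], expr)
  expect_setequal(up, sim$truth$activated_ids)
  expect_setequal(down, sim$truth$suppressed_ids)
})
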
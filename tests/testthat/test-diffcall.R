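# Build a one-row differential table with given statistics; unspecified
# contrasts are inert (fc = 1, lcb below any threshold, p = 1).
fake_record <- function(...) {
  inert <- list(fc = 1, lcb = 0.5, ucb = 2, rlcb = 0.5, p = 1)
  row <- list(transcript_id = "T1")
  for (suf in c("d3", "d14", "tc", "tcc"))
    for (nm in names(inert)) row[[paste0(nm, "_", suf)]] <- inert[[nm]]
  override <- list(...)
  for (nm in names(override)) row[[nm]] <- override[[nm]]
  as.data.frame(row, stringsAsFactors = FALSE)
}

test_that("unpaired test matches the closed-form pooled-variance t", {
  p <- unpaired_test(c(1, 2, 3), c(4, 5, 6), flavor = "student",
                     log_scale = FALSE)
  expect_equal(p, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(round(p, 4), 0.0213)
})

test_that("unpaired test degenerate and symmetry behavior", {
  expect_equal(unpaired_test(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(unpaired_test(c(2, 2), c(5, 5), log_scale = FALSE), 0)
  a <- c(1.2, 3.4, 2.2); b <- c(4.4, 5.1, 6.3)
  expect_equal(unpaired_test(a, b), unpaired_test(b, a))
  expect_error(unpaired_test(1, c(1, 2)), "at least 2")
})

test_that("the compound rule fires on either timepoint clause", {
  rec <- call_regulated(fake_record(lcb_d3 = 1.6, p_d3 = 0.01))
  expect_equal(rec$call, "up")
  expect_equal(rec$call_basis, "D3")

  rec <- call_regulated(fake_record(lcb_d14 = 1.6, p_d14 = 0.2))
  expect_equal(rec$call, "none")

  rec <- call_regulated(fake_record(lcb_d3 = 1.7, p_d3 = 0.01,
                                    lcb_d14 = 2.0, p_d14 = 0.001))
  expect_equal(rec$call_basis, "D3,D14")

  rec <- call_regulated(fake_record(rlcb_d14 = 1.8, p_d14 = 0.02))
  expect_equal(rec$call, "down")
  expect_equal(rec$call_basis, "D14")
})

test_that("the time-course rescue clause requires a quiet control contrast", {
  rec <- call_regulated(fake_record(lcb_d3 = 1.4, lcb_d14 = 1.4,
                                    lcb_tc = 1.7, p_tc = 0.02,
                                    lcb_tcc = 1.0, p_tcc = 0.8))
  expect_equal(rec$call, "up")
  expect_equal(rec$call_basis, "timecourse")

  # same treated time course but the control moves too: no rescue
  rec <- call_regulated(fake_record(lcb_tc = 1.7, p_tc = 0.02,
                                    lcb_tcc = 1.8, p_tcc = 0.01))
  expect_equal(rec$call, "none")

  # downward time course rescues as a down-call
  rec <- call_regulated(fake_record(rlcb_tc = 2.1, p_tc = 0.01))
  expect_equal(rec$call, "down")
  expect_equal(rec$call_basis, "timecourse")
})

test_that("called sets shrink as thresholds tighten", {
  cfg <- tiny_config(seed = 21L)
  expr <- fit_expression_index(
    normalize_to_median_array(generate_experiment(cfg)$probes))
  tab <- differential_table(expr)
  loose <- call_regulated(tab, fold_threshold = 1.2, alpha = 0.10)
  mid <- call_regulated(tab, fold_threshold = 1.5, alpha = 0.05)
  tight <- call_regulated(tab, fold_threshold = 2.0, alpha = 0.01)
  set_of <- function(x) x$transcript_id[x$call != "none"]
  expect_true(all(set_of(mid) %in% set_of(loose)))
  expect_true(all(set_of(tight) %in% set_of(mid)))
})

test_that("enriched set recovers the target block and nests across alpha", {
  cfg <- noiseless_config()
  sim <- generate_experiment(cfg)
  expr <- fit_expression_index(normalize_to_median_array(sim$probes))
  es <- build_enriched_set(expr)
  genes <- collapse_to_genes(es$ids, expr)
  expect_setequal(genes, sim$truth$target_enriched_ids)
  # nesting and the degenerate threshold
  e05 <- build_enriched_set(expr, alpha = 0.05)
  expect_true(all(es$ids %in% e05$ids))
  expect_length(build_enriched_set(expr, fold_threshold = Inf), 0L)
})

test_that("transcripts with missing indices are never called", {
  theta <- matrix(exp(rnorm(5 * 12, 5, 0.1)), 5, 12)
  theta[3, ] <- NA
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:12),
    condition = rep(c("control", "treated"), each = 6),
    timepoint = rep(rep(c("D3", "D14"), each = 3), 2),
    replicate = rep(1:3, 4))
  rownames(theta) <- sprintf("T%d", 1:5)
  expr <- expression_index(theta, samples)
  calls <- call_regulated(differential_table(expr))
  expect_equal(calls$call[3], "none")
})

test_that("probeset-to-gene collapsing keeps the brightest probeset", {
  theta <- matrix(c(10, 12, 11, 100, 110, 105), 2, 3, byrow = TRUE,
                  dimnames = list(c("PS1", "PS2"), NULL))
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        condition = "control", timepoint = NA, replicate = 1:3)
  expr <- expression_index(theta, samples)
  expr$gene_map <- c(PS1 = "GENE1", PS2 = "GENE1")
  expect_identical(collapse_to_genes(c("PS1", "PS2"), expr), "GENE1")
})
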
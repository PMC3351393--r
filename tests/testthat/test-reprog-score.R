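test_that("common_genes is an exact case-insensitive intersection", {
  a <- gene_set("a", c("x", "Y", "z"))
  b <- gene_set("b", c("y", "Z", "w"))
  expect_setequal(common_genes(a, b)$ids, c("Y", "Z"))
  expect_length(common_genes(gene_set("a", "p"), gene_set("b", "q")), 0L)
  sub <- gene_set("s", c("x", "y"))
  sup <- gene_set("S", c("x", "y", "z"))
  expect_setequal(common_genes(sub, sup)$ids, sub$ids)
})

test_that("path and overlap fractions follow the set cardinalities", {
  target <- gene_set("target", sprintf("T%04d", 1:1128))
  activated <- gene_set("act", c(sprintf("T%04d", 1:63),
                                 sprintf("A%04d", 1:77)))
  rep <- path_fraction(activated, target)
  expect_equal(rep$n_overlap, 63L)
  expect_equal(rep$path_fraction, 63 / 1128)
  expect_equal(rep$path_pct_display, 6)
  expect_equal(rep$overlap_fraction, 63 / 140)
  expect_equal(rep$overlap_pct_display, 45)
  expect_lte(rep$n_overlap, min(rep$n_activated, rep$n_target_enriched))

  same <- path_fraction(target, target)
  expect_equal(same$path_fraction, 1)
  expect_equal(same$overlap_fraction, 1)
  expect_error(path_fraction(activated, gene_set("empty", character(0))),
               "path undefined")
})

test_that("fractions are invariant under relabeling of gene ids", {
  ids <- sprintf("G%03d", 1:50)
  act <- gene_set("a", ids[1:20]); tgt <- gene_set("t", ids[11:50])
  r1 <- path_fraction(act, tgt)
  perm <- setNames(sprintf("X%03d", sample(50)), ids)
  r2 <- path_fraction(gene_set("a", perm[act$ids]),
                      gene_set("t", perm[tgt$ids]))
  expect_equal(r2$path_fraction, r1$path_fraction)
  expect_equal(r2$overlap_fraction, r1$overlap_fraction)
})

make_marker_fixture <- function(ratios, called_up = TRUE) {
  n <- length(ratios) + 2
  ids <- sprintf("M%02d", seq_len(n))
  samples <- data.frame(
    sample_id = c("t1", "t2", "t3", "b1", "b2", "b3"),
    condition = rep(c("treated", "target"), each = 3),
    timepoint = c("D14", "D14", "D14", NA, NA, NA),
    replicate = rep(1:3, 2))
  target_val <- rep(100, n)
  treated_val <- c(ratios, 1, 1) * 100
  theta <- cbind(matrix(treated_val, n, 3), matrix(target_val, n, 3))
  rownames(theta) <- ids
  expr <- expression_index(theta, samples)
  calls <- data.frame(
    transcript_id = ids,
    call = c(rep(if (called_up) "up" else "none", length(ratios)),
             "none", "none"))
  list(expr = expr, calls = calls, ids = ids, markers = gene_set("panel", ids))
}

test_that("marker-panel score is the treated/target signal ratio", {
  fx <- make_marker_fixture(c(0.2, 0.5, 0.8))
  rep <- marker_panel_score(fx$markers, fx$calls, fx$expr, fx$expr)
  mp <- rep$marker_panel
  expect_equal(mp$n_markers, 5L)
  expect_equal(mp$n_markers_activated, 3L)
  expect_equal(mp$mean_signal_fraction, 0.5)
  expect_equal(c(mp$min_signal_fraction, mp$max_signal_fraction), c(0.2, 0.8))
  expect_equal(mp$fraction_markers_unregulated, 1 - 3 / 5, tolerance = 1e-12)
})

test_that("signal fractions above one are reported unclipped", {
  fx <- make_marker_fixture(c(0.3, 1.04))
  mp <- marker_panel_score(fx$markers, fx$calls, fx$expr, fx$expr)$marker_panel
  expect_equal(mp$max_signal_fraction, 1.04)
})

test_that("identical treated and target matrices score 100 percent", {
  fx <- make_marker_fixture(c(1, 1, 1))
  mp <- marker_panel_score(fx$markers, fx$calls, fx$expr, fx$expr)$marker_panel
  expect_equal(mp$mean_signal_fraction, 1.0)
})

test_that("an unactivated panel reports a missing mean and full unregulated fraction", {
  fx <- make_marker_fixture(c(0.5, 0.5), called_up = FALSE)
  mp <- marker_panel_score(fx$markers, fx$calls, fx$expr, fx$expr)$marker_panel
  expect_equal(mp$n_markers_activated, 0L)
  expect_true(is.na(mp$mean_signal_fraction))
  expect_equal(mp$fraction_markers_unregulated, 1)
})

test_that("markers absent from a matrix are excluded and counted", {
  fx <- make_marker_fixture(c(0.4, 0.6))
  markers <- gene_set("panel", c(fx$ids, "MISSING1", "MISSING2"))
  mp <- marker_panel_score(markers, fx$calls, fx$expr, fx$expr)$marker_panel
  expect_equal(mp$n_excluded, 2L)
  expect_equal(mp$n_markers, 4L)
})
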
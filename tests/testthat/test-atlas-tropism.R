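mini_atlas <- function() {
  tissues <- c(islet = "endocrine", beta = "endocrine",
               cortex = "cns", cerebellum = "cns",
               liver = "other", kidney = "other", lung = "other",
               heart = "other", spleen = "other", muscle = "other",
               colon = "other", skin = "other")
  o <- rep(10, 8)
  vals <- rbind(
    ENDO1 = c(90, 90, 10, 10, o),
    ENDO2 = c(80, 100, 12, 8, o),
    CNS1 = c(10, 10, 90, 90, o),
    SHARED1 = c(90, 90, 90, 90, o),
    FLAT1 = rep(20, 12))
  colnames(vals) <- names(tissues)
  atlas_matrix(vals, tissues)
}

test_that("abundance scores are category-mean ratios", {
  atl <- mini_atlas()
  expect_equal(unname(endocrine_abundance("FLAT1", atl)), 1)
  expect_equal(unname(endocrine_abundance("ENDO1", atl)), 9)
  expect_equal(unname(cns_abundance("CNS1", atl)), 9)
  expect_error(endocrine_abundance("NOPE", atl), "absent")
})

test_that("tropism labels follow the threshold rule", {
  atl <- mini_atlas()
  tr <- assign_tropism(c("ENDO1", "CNS1", "SHARED1", "FLAT1"), atl)
  expect_equal(tr$label, c("A", "B", "C", "MISC"))
  comp <- attr(tr, "composition")
  expect_equal(sum(comp), 1)
  expect_equal(unname(comp), rep(0.25, 4))
  expect_error(assign_tropism(character(0), atl), "empty")
})

test_that("labels are invariant under a global atlas rescaling", {
  atl <- mini_atlas()
  scaled <- atlas_matrix(atl$values * 12.5, atl$tissue_category)
  a <- assign_tropism(rownames(atl$values), atl)
  b <- assign_tropism(rownames(atl$values), scaled)
  expect_identical(a$label, b$label)
})

test_that("simulated block composition is recovered on the synthetic atlas", {
  cfg <- tiny_config(n_activated = 140L,
                     block_fracs = c(endocrine = 0.25, cns = 0.25,
                                     shared = 0.20))
  tr <- generate_experiment(cfg)$truth
  atlas <- generate_atlas(cfg, tr)
  res <- assign_tropism(tr$activated_ids, atlas)
  truth_lab <- true_block_labels(tr, res$gene_id)
  nb <- truth_lab != "MISC"
  expect_gte(mean(res$label[nb] == truth_lab[nb]), 0.95)
})

test_that("identical profiles merge first at distance zero", {
  atl <- mini_atlas()
  vals <- rbind(atl$values, ENDO1B = atl$values["ENDO1", ])
  hc <- profile_hclust(atlas_matrix(vals, atl$tissue_category))
  first <- hc$merge[1, ]
  merged <- sort(hc$labels[-first])
  expect_equal(merged, c("ENDO1", "ENDO1B"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
})

test_that("correlated tissue blocks merge before unrelated genes join", {
  atl <- mini_atlas()
  hc <- profile_hclust(atl, genes = c("ENDO1", "ENDO2", "CNS1"))
  expect_setequal(hc$labels[-hc$merge[1, ]], c("ENDO1", "ENDO2"))
})

test_that("the dendrogram is invariant under input-order permutation", {
  cfg <- tiny_config(n_activated = 20L)
  tr <- generate_experiment(cfg)$truth
  atlas <- generate_atlas(cfg, tr)
  genes <- tr$activated_ids
  h1 <- profile_hclust(atlas, genes)
  h2 <- profile_hclust(atlas, rev(genes))
  expect_identical(h1$merge, h2$merge)
  expect_identical(h1$labels, h2$labels)
  expect_equal(h1$height, h2$height)
})

test_that("constant genes are tolerated and logged", {
  tissues <- c(islet = "endocrine", cortex = "cns", liver = "other")
  vals <- rbind(A1 = c(9, 1, 1), A2 = c(8, 1, 2), K1 = c(5, 5, 5))
  colnames(vals) <- names(tissues)
  hc <- profile_hclust(atlas_matrix(vals, tissues))
  expect_identical(attr(hc, "constant_genes"), "K1")
  # the constant gene joins last, at the correlation-zero distance 1
  expect_equal(hc$height[2], 1)
})

test_that("newick export reflects the merge structure", {
  atl <- mini_atlas()
  nw <- dendrogram_newick(profile_hclust(atl,
                                         c("ENDO1", "ENDO2", "CNS1")))
  expect_match(nw, "^\\(.*\\);$")
  expect_match(nw, "ENDO1")
  expect_match(nw, "CNS1")
})
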
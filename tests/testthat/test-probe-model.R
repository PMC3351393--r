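make_probes_with_means <- function(target_means) {
  # two probes per array, PM == MM so the array mean equals the target
  pm <- rbind(target_means, target_means)
  samples <- data.frame(sample_id = sprintf("a%d", seq_along(target_means)),
                        condition = "control", timepoint = NA_character_,
                        replicate = seq_along(target_means))
  probe_matrix(pm = pm, mm = pm, probeset_id = c("PS1", "PS1"),
               probe_index = 1:2, samples = samples)
}

test_that("median-array normalization rescales to the reference mean", {
  pr <- make_probes_with_means(c(100, 180, 260))
  out <- normalize_to_median_array(pr)
  sf <- attr(out, "scale_factors")
  expect_equal(unname(sf), c(1.8, 1.0, 180 / 260))
  expect_identical(attr(out, "reference_array"), "a2")
  expect_equal(unname(colMeans(out$pm)), rep(180, 3))
  # reference column bit-identical
  expect_identical(out$pm[, 2], pr$pm[, 2])
})

test_that("normalization is the identity on identical arrays", {
  pr <- make_probes_with_means(c(150, 150, 150, 150))
  out <- normalize_to_median_array(pr)
  expect_identical(out$pm, pr$pm)
  expect_equal(unname(attr(out, "scale_factors")), rep(1, 4))
})

test_that("even array count takes the lower-mean array of the middle pair", {
  pr <- make_probes_with_means(c(100, 200))
  out <- normalize_to_median_array(pr)
  expect_identical(attr(out, "reference_array"), "a1")
  expect_equal(unname(attr(out, "scale_factors")), c(1, 0.5))
})

test_that("an all-zero array is a named normalization error", {
  pr <- make_probes_with_means(c(100, 200, 300))
  pr$pm[, 2] <- 0; pr$mm[, 2] <- 0
  expect_error(normalize_to_median_array(pr), "a2")
})

test_that("single-probe probesets collapse to the PM-MM difference", {
  theta <- matrix(c(10, 25, 90), 1, 3)
  phi <- matrix(1, 1, 1)
  ex <- fit_expression_index(manual_probes(theta, phi))
  expect_equal(unname(ex$theta[1, ]), c(10, 25, 90))
  expect_equal(unname(ex$se[1, ]), c(0, 0, 0))
})

test_that("noiseless multiplicative probesets are fitted exactly", {
  theta <- matrix(c(2, 4), 1, 2) * 10 # keep above the PM-MM floor
  phi <- matrix(1, 1, 3)
  ex <- fit_expression_index(manual_probes(theta, phi))
  expect_equal(ex$theta[1, 2] / ex$theta[1, 1], 2, tolerance = 1e-10)
  # identifiability: sum of squared sensitivities equals probe count
  expect_equal(sum(ex$phi[names(ex$phi) == "PS001"]^2), 3, tolerance = 1e-6)
  # non-trivial sensitivities, several probesets
  set.seed(5)
  theta2 <- matrix(exp(rnorm(8 * 6, 4, 1)), 8, 6)
  phi2 <- exp(matrix(rnorm(8 * 5, 0, 0.4), 8, 5))
  phi2 <- phi2 / sqrt(rowMeans(phi2^2))
  ex2 <- fit_expression_index(manual_probes(theta2, phi2))
  expect_equal(unname(ex2$theta / theta2),
               matrix(1, 8, 6), tolerance = 1e-8)
  expect_true(all(abs(tapply(ex2$phi^2, names(ex2$phi), sum) - 5) < 1e-6))
})

test_that("a grossly contaminated cell is excluded and the fit restored", {
  theta <- matrix(c(2, 4), 1, 2) * 10
  phi <- matrix(1, 1, 3)
  pr <- manual_probes(theta, phi)
  pr$pm[1, 2] <- pr$pm[1, 2] * 100 # probe 1, array 2
  ex <- fit_expression_index(pr)
  expect_true(ex$outlier_mask[1, 2])
  expect_equal(ex$theta[1, 2] / ex$theta[1, 1], 2, tolerance = 1e-6)
})

test_that("fitted theta tracks the simulated signal on noiseless data", {
  cfg <- noiseless_config(n_transcripts = 100L)
  sim <- generate_experiment(cfg)
  ex <- fit_expression_index(sim$probes) # unnormalized: compare raw signal
  y <- sim$probes$pm - sim$probes$mm
  theta_true <- rowsum(y, sim$probes$probeset_id) / cfg$probes_per_set
  varying <- apply(theta_true, 1L, stats::sd) > 0
  cors <- sapply(which(varying), function(i)
    stats::cor(ex$theta[i, ], theta_true[i, ]))
  expect_gt(sum(varying), 10)
  expect_true(all(cors >= 0.999))
})

test_that("fold-change CI matches the closed form and orders correctly", {
  ci <- fold_change_ci(100, 10, 300, 20, level = 0.90)
  z <- qnorm(0.95)
  expect_equal(ci$fc, 3)
  expect_equal(ci$lcb, (300 - z * 20) / (100 + z * 10), tolerance = 1e-12)
  expect_equal(ci$ucb, (300 + z * 20) / (100 - z * 10), tolerance = 1e-12)
  expect_equal(round(ci$lcb, 3), 2.294)
  expect_equal(round(ci$ucb, 3), 3.984)
  # degenerate: identical groups, zero SE
  ci0 <- fold_change_ci(50, 0, 50, 0)
  expect_equal(unlist(ci0[c("fc", "lcb", "ucb")]),
               c(fc = 1, lcb = 1, ucb = 1))
  # denominator floor gives +Inf upper bound
  expect_equal(fold_change_ci(10, 20, 30, 1)$ucb, Inf)
})

test_that("lcb <= fc <= ucb and lcb is monotone in SE and level", {
  set.seed(9)
  for (i in 1:200) {
    rm_ <- runif(1, 1, 500); tm <- runif(1, 1, 500)
    rs <- runif(1, 0, 100); ts <- runif(1, 0, 100)
    ci <- fold_change_ci(rm_, rs, tm, ts)
    expect_lte(ci$lcb, ci$fc + 1e-12)
    expect_lte(ci$fc, ci$ucb + 1e-12)
  }
  base <- fold_change_ci(100, 5, 300, 10)
  wider <- fold_change_ci(100, 15, 300, 10)
  expect_lt(wider$lcb, base$lcb)
  expect_gt(wider$ucb, base$ucb)
  higher_level <- fold_change_ci(100, 5, 300, 10, level = 0.99)
  expect_lt(higher_level$lcb, base$lcb)
})

test_that("fold changes are invariant under a global intensity rescaling", {
  cfg <- tiny_config(n_transcripts = 80L, target_enriched_size = 20L,
                     n_activated = 10L, n_suppressed = 0L)
  sim <- generate_experiment(cfg)
  big <- sim$probes
  big$pm <- big$pm * 7.3
  big$mm <- big$mm * 7.3
  e1 <- fit_expression_index(normalize_to_median_array(sim$probes),
                             eps_floor = 1)
  e2 <- fit_expression_index(normalize_to_median_array(big),
                             eps_floor = 7.3)
  t1 <- differential_table(e1)
  t2 <- differential_table(e2)
  expect_equal(t2$fc_d14, t1$fc_d14, tolerance = 1e-8)
  expect_equal(t2$lcb_d14, t1$lcb_d14, tolerance = 1e-8)
})
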
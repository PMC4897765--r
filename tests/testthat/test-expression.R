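make_null_dataset <- function(genes, reps = 3, seed = 1, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(genes * 3 * reps, sd = sd), nrow = genes)
  expression_dataset(x, rep(c("E30", "E34", "P1"), each = reps))
}

test_that("permutation ANOVA p-values respect their attainable range and conventions", {
  ds <- make_null_dataset(50, seed = 2)
  res <- permutation_anova(ds, n_perm = 200, seed = 3)
  expect_true(all(res$p_value >= 1 / 201))
  expect_true(all(res$p_value <= 1))

  ## a constant gene has no variance to test: p = 1 by convention
  x <- rbind(const = rep(5, 9), moving = c(rep(0, 6), rep(10, 3)))
  dsc <- expression_dataset(x, rep(c("E30", "E34", "P1"), each = 3))
  resc <- permutation_anova(dsc, n_perm = 500, seed = 4)
  expect_equal(resc$p_value[resc$gene == "const"], 1)
  ## an extreme separation is held back only by permutation granularity
  p_strong <- resc$p_value[resc$gene == "moving"]
  expect_gte(p_strong, 1 / 501)
  expect_lt(p_strong, 0.05)

  ## the observed F agrees with the classical one-way statistic
  g <- factor(rep(c("E30", "E34", "P1"), each = 3))
  set.seed(9)
  y <- rnorm(9)
  dsf <- expression_dataset(matrix(y, 1), g)
  f_pkg <- permutation_anova(dsf, n_perm = 10, seed = 1)$f_statistic
  f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(f_pkg, f_aov, tolerance = 1e-10)
})

test_that("the permutation test is calibrated on null data", {
  ds <- make_null_dataset(1000, seed = 11)
  res <- permutation_anova(ds, n_perm = 500, seed = 12)
  frac <- mean(res$p_value < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), se3)
})

test_that("Bonferroni adjustment is the clipped product rule", {
  expect_equal(adjust_bonferroni(rep(0.001, 10))[1], 0.01)
  expect_equal(adjust_bonferroni(rep(0.5, 10))[1], 1)
  expect_equal(adjust_bonferroni(rep(1, 5)), rep(1, 5))
  ## monotone: adjustment preserves the ordering of p-values
  set.seed(5)
  p <- runif(50)
  adj <- adjust_bonferroni(p)
  expect_identical(order(adj[order(p)]), seq_len(50L))
  ## clipped values stay clipped under re-adjustment
  expect_true(all(adjust_bonferroni(adj[adj >= 1]) == 1))
  ## BH is exposed behind the flag
  expect_equal(adjust_pvalues(p, "BH"), p.adjust(p, "BH"))
})

test_that("temporal profiles follow the two-contrast decision rules", {
  expect_identical(classify_temporal_profile(3, 0.01, 1 / 3, 0.01), "PEAK")
  expect_identical(classify_temporal_profile(1 / 3, 0.01, 3, 0.01), "TROUGH")
  expect_identical(classify_temporal_profile(1.1, 0.8, 2.5, 0.01), "LATE_UP")
  expect_identical(classify_temporal_profile(2.5, 0.01, 2.5, 0.01),
                   "MONOTONE_DISCARDED")
  expect_identical(classify_temporal_profile(2.5, 0.01, 1, 0.9), "EARLY_UP")
  expect_identical(classify_temporal_profile(0.3, 0.01, 1, 0.9), "EARLY_DOWN")
  expect_identical(classify_temporal_profile(1, 0.9, 0.3, 0.01), "LATE_DOWN")
  expect_identical(classify_temporal_profile(1.1, 0.9, 1.2, 0.8), "FLAT")
  ## a large fold change without significance is not called
  expect_identical(classify_temporal_profile(4, 0.2, 1, 0.9), "FLAT")
  ## a significant but sub-threshold fold change is not called
  expect_identical(classify_temporal_profile(1.5, 0.001, 1, 0.9), "FLAT")
})

test_that("the screen recovers planted profiles and degrades with noise", {
  truth <- planted_expression_truth(
    c(PEAK = 6, TROUGH = 4, EARLY_UP = 5, EARLY_DOWN = 5,
      LATE_UP = 6, LATE_DOWN = 4, MONOTONE_UP = 5, FLAT = 65))
  expected <- ifelse(truth$profile %in% c("MONOTONE_UP", "MONOTONE_DOWN"),
                     "MONOTONE_DISCARDED", truth$profile)

  ds <- generate_expression_dataset(truth, sigma = 0.05, replicates = 5,
                                    seed = 31)
  scr <- profile_screen(ds, n_perm = 4999, adjust = "BH", seed = 32)
  expect_identical(scr$profile, expected)

  ## heavier noise cannot improve recovery
  ds_noisy <- generate_expression_dataset(truth, sigma = 1.5, replicates = 5,
                                          seed = 31)
  scr_noisy <- profile_screen(ds_noisy, n_perm = 999, adjust = "BH", seed = 32)
  expect_lte(mean(scr_noisy$profile == expected), mean(scr$profile == expected))
})

test_that("expression datasets validate their stage structure", {
  x <- matrix(0, 2, 6)
  expect_error(expression_dataset(x, rep(c("a", "b"), each = 3)), "three stages")
  expect_error(expression_dataset(x, c("a", "a", "b", "b", "c", "c")[1:5]),
               "label every sample")
  expect_error(expression_dataset(matrix(0, 2, 4),
                                  c("a", "b", "c", "c")), "two replicates")
})

test_that("comparative-Ct fold changes follow 2^(-ddCt)", {
  flat <- data.frame(gene = rep(c("g", "actin"), each = 6),
                     condition = rep(rep(c("A", "B"), each = 3), 2),
                     replicate = rep(1:3, 4), ct = rep(20, 12))
  expect_equal(ddct_fold_change(flat, "g", "B", "A"), 1)
  ## self-comparison is always 1
  expect_equal(ddct_fold_change(flat, "g", "A", "A"), 1)

  drop1 <- flat
  drop1$ct[drop1$gene == "g" & drop1$condition == "B"] <- 19
  expect_equal(ddct_fold_change(drop1, "g", "B", "A"), 2)

  rise <- flat
  rise$ct[rise$gene == "g" & rise$condition == "B"] <- 20 + log2(2.5)
  expect_equal(ddct_fold_change(rise, "g", "B", "A"), 0.4)

  expect_error(ddct_fold_change(flat, "g", "B", "A", reference_gene = "gapdh"),
               "reference gene")
  bad <- flat[flat$gene != "g" | flat$condition != "B", ]
  expect_error(ddct_fold_change(bad, "g", "B", "A"), "missing Ct")

  ## generator round-trip: planted log2 fold changes are recovered exactly
  ct <- generate_ct_table(c(Cdh1 = -1.32, Trnp1 = 1), condition = "E34",
                          baseline_condition = "E30")
  expect_equal(ddct_fold_change(ct, "Cdh1", "E34", "E30"), 2^-1.32)
  expect_equal(ddct_fold_change(ct, "Trnp1", "E34", "E30"), 2)
  expect_warning(ct_table(flat[-1, ]), "triplicate")
})
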
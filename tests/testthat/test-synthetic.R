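test_that("the design library catalogues the study's labeling experiments", {
  lib <- paper_design_library()
  ## short-survival ventricular tracing at E34, analysed at E36
  d <- lib$short_E34
  expect_identical(d$injection$site, "VENTRICLE")
  expect_equal(d$injection$time, 34)
  expect_equal(d$analysis_time, 36)
  ## local OSVZ injection at P1 analysed at P3
  o <- lib$osvz_P1_P3
  expect_identical(o$injection$site, "OSVZ_LOCAL")
  expect_equal(o$injection$time, 43)
  expect_equal(o$analysis_time, 45)
  ## the BrdU cohort design pulses at E36.0-E36.5
  b <- lib$brdu_E34_E38
  expect_equal(b$brdu$start, 36)
  expect_equal(b$brdu$end, 36.5)
  expect_equal(b$analysis_time, 38)
  ## every design analyses after its injection
  expect_true(all(vapply(lib, function(x)
    x$analysis_time > x$injection$time, logical(1))))
})

test_that("labeling datasets sample the census reproducibly", {
  design <- experiment_design(injection_spec("VENTRICLE", 34, 800),
                              analysis_time = 35.5, n_sampled_cells = 600)
  cfg <- sim_config(founders = 800, t0 = 34, t_end = 35.5, seed = 41,
                    rules = mode_rule_set(mode_fractions(0, 1, 0)))
  cen <- generate_labeling_dataset(design, config = cfg, seed = 42)
  expect_equal(sum(cen$count), 600L)
  ## hypergeometric sampling of an asymmetric one-round census: about half
  ## of labeled cells are of the mother type
  k <- sum(cen$count[cen$cell_type == "ARGC"])
  expect_lt(abs(k / 600 - 0.5), 3 * sqrt(0.25 / 600))

  ## determinism and clamping
  cen2 <- generate_labeling_dataset(design, config = cfg, seed = 42)
  expect_identical(as.data.frame(cen), as.data.frame(cen2))
  big <- experiment_design(injection_spec("VENTRICLE", 34, 800),
                          analysis_time = 35.5, n_sampled_cells = 5000)
  expect_warning(full <- generate_labeling_dataset(big, config = cfg, seed = 42),
                 "full census")
  expect_equal(sum(full$count), 800L) # one integrated daughter per clone
})

test_that("angle samples realise the requested class mixture", {
  pure <- generate_angle_sample(c(1, 0, 0), 500, seed = 51)
  expect_true(all(pure$angle_deg >= 0 & pure$angle_deg < 30))
  expect_true(all(pure$class_true == "HORIZONTAL"))

  mix <- generate_angle_sample(c(0.5, 0, 0.5), 10000, seed = 52)
  s <- angle_summary(mix$angle_deg, mix$convention[1])
  se3 <- 3 * sqrt(0.25 / 10000)
  expect_lt(abs(s$class_fractions[["HORIZONTAL"]] - 0.5), se3)
  expect_lt(abs(s$class_fractions[["VERTICAL"]] - 0.5), se3)
  expect_equal(s$class_fractions[["OBLIQUE"]], 0)

  ## radial-fiber samples classify identically after conversion
  rf <- generate_angle_sample(c(0.2, 0.3, 0.5), 2000, convention = "RADIAL_FIBER",
                              seed = 53)
  expect_identical(classify_cleavage(rf$angle_deg, "RADIAL_FIBER"), rf$class_true)

  expect_error(generate_angle_sample(c(1, 0, 0), 0), ">= 1")
  expect_error(generate_angle_sample(c(0.5, 0.2, 0.2), 10), "summing to 1")
  expect_identical(generate_angle_sample(c(0.3, 0.3, 0.4), 50, seed = 5),
                   generate_angle_sample(c(0.3, 0.3, 0.4), 50, seed = 5))
})

test_that("expression generation is exact at zero noise and carries its truth", {
  truth <- planted_expression_truth(c(PEAK = 2, FLAT = 8))
  ds <- generate_expression_dataset(truth, sigma = 0, replicates = 5, seed = 61)
  expect_identical(attr(ds, "truth"), truth)
  ## stage means reproduce the planted means exactly
  m2 <- rowMeans(ds$values[, ds$stages == "E34"])
  expect_equal(unname(m2), truth$mean_stage2)

  ## the screen recovers a planted peak at the default 2-fold threshold
  scr <- profile_screen(ds, n_perm = 4999, seed = 62)
  expect_identical(scr$profile[truth$profile == "PEAK"], rep("PEAK", 2L))
  expect_identical(scr$profile[truth$profile == "FLAT"], rep("FLAT", 8L))

  expect_identical(
    generate_expression_dataset(truth, sigma = 0.3, seed = 7)$values,
    generate_expression_dataset(truth, sigma = 0.3, seed = 7)$values)
  expect_error(planted_expression_truth(c(WAVY = 3)), "unknown profile")
})
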
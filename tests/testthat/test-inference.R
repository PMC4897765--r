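test_that("the closed-form labeled-mother fraction matches brute-force enumeration", {
  ## the three homogeneous regimes of the segregation model
  expect_equal(expected_labeled_mother_fraction(mode_fractions(1, 0, 0)), 1)
  expect_equal(expected_labeled_mother_fraction(mode_fractions(0, 1, 0)), 0.5)
  expect_equal(expected_labeled_mother_fraction(mode_fractions(0, 0, 1)), 0)
  expect_equal(expected_labeled_mother_fraction(mode_fractions(0.5, 0.5, 0)), 0.75)

  ## exact agreement with enumeration over a simplex grid
  for (p in seq(0, 1, by = 0.1)) {
    for (q in seq(0, 1 - p, by = 0.1)) {
      r <- 1 - p - q
      expect_equal(expected_labeled_mother_fraction(mode_fractions(p, q, r)),
                   enumerate_labeled_mother_fraction(p, q, r))
    }
  }
  expect_error(mode_fractions(0.5, 0.6, 0.2), "sum to 1")
  expect_error(mode_fractions(-0.1, 0.6, 0.5), "\\[0, 1\\]")
})

test_that("population fate classification tests the fraction against one half", {
  cons <- classify_population_fate(24, 100)
  expect_identical(cons$classification, "CONSUMPTION")
  expect_lt(cons$p_value, 1e-6)

  ren <- classify_population_fate(50, 100)
  expect_identical(ren$classification, "RENEWAL")

  ## 52/100 is not distinguishable from one half
  near <- classify_population_fate(52, 100)
  expect_identical(near$classification, "RENEWAL")
  expect_equal(near$p_value, exact_binom_p_oracle(52, 100), tolerance = 1e-10)
  expect_true(near$conf_int[1] < 0.5 && near$conf_int[2] > 0.5)

  ## the literal point-threshold rule is available behind the flag
  expect_identical(classify_population_fate(52, 100, method = "threshold")$classification,
                   "AMPLIFICATION")
  expect_identical(classify_population_fate(50, 100, method = "threshold")$classification,
                   "RENEWAL")

  amp <- classify_population_fate(80, 100)
  expect_identical(amp$classification, "AMPLIFICATION")
  expect_error(classify_population_fate(101, 100))
})

test_that("classification is monotone in the labeled count", {
  ord <- c(CONSUMPTION = -1L, RENEWAL = 0L, AMPLIFICATION = 1L)
  for (n in c(20L, 100L, 400L)) {
    cls <- vapply(0:n, function(k)
      ord[[classify_population_fate(k, n)$classification]], integer(1))
    expect_true(all(diff(cls) >= 0L))
  }
})

test_that("mode-fraction inversion round-trips and respects the simplex", {
  expect_equal(unlist(feasible_mode_fractions(0.5, q_known = 1)[c("p", "q", "r")]),
               c(p = 0, q = 1, r = 0))
  expect_equal(unlist(feasible_mode_fractions(0.75, q_known = 0.5)[c("p", "q", "r")]),
               c(p = 0.5, q = 0.5, r = 0))

  ## boundary fractions identify the modes without q
  expect_s3_class(feasible_mode_fractions(1), "mode_fractions")
  expect_equal(feasible_mode_fractions(1)$p, 1)
  expect_equal(feasible_mode_fractions(0)$r, 1)

  ## interior fractions leave a one-parameter family
  fam <- feasible_mode_fractions(0.4)
  expect_s3_class(fam, "mode_fraction_family")
  expect_equal(fam$q_range, c(0, 0.8))

  ## round-trip identity across the feasible region
  for (l in seq(0, 1, by = 0.05)) {
    q_max <- min(2 * l, 2 * (1 - l))
    for (q in seq(0, q_max, length.out = 5)) {
      m <- feasible_mode_fractions(l, q_known = q)
      expect_equal(expected_labeled_mother_fraction(m), l, tolerance = 1e-12)
    }
  }
  expect_error(feasible_mode_fractions(0.2, q_known = 0.9), "infeasible")
  expect_error(feasible_mode_fractions(1.2), "\\[0, 1\\]")
})

test_that("delamination arithmetic assigns one delaminating daughter per non-vertical division", {
  expect_equal(predicted_delamination_fraction(0.5), 0.25)
  expect_equal(predicted_delamination_fraction(0), 0)
  expect_equal(predicted_delamination_fraction(1), 0.5)
  expect_error(predicted_delamination_fraction(1.2), "\\[0, 1\\]")
  ## consistency with the angle summary
  s <- angle_summary(c(5, 40, 70, 80))
  expect_equal(s$d_pred, s$f_nonvertical / 2)
})

test_that("condition comparison uses the Pearson chi-square on the 2xK table", {
  same <- compare_condition_counts(c(ARGC = 50, BRGC = 50),
                                   c(ARGC = 50, BRGC = 50))
  expect_equal(unname(same$statistic), 0)
  expect_equal(unname(same$p.value), 1)

  flip <- compare_condition_counts(c(ARGC = 90, BRGC = 10),
                                   c(ARGC = 10, BRGC = 90))
  expect_equal(unname(flip$statistic), 128)
  expect_equal(unname(flip$parameter), 1)

  expect_error(compare_condition_counts(c(ARGC = 10, BRGC = 0),
                                        c(ARGC = 12, BRGC = 0)),
               "merge")

  ## census tables collapse to cell-type margins before testing
  cen <- one_round_census(200, mode_fractions(0, 1, 0), seed = 3)
  res <- compare_condition_counts(cen, cen)
  expect_equal(unname(res$statistic), 0)
})

test_that("simulated censuses recover the division-mode truth", {
  truth <- mode_fractions(0.3, 0.5, 0.2)
  l_true <- expected_labeled_mother_fraction(truth)
  cen <- one_round_census(10000, truth, seed = 17)
  k <- sum(cen$count[cen$cell_type == "ARGC"])
  n <- sum(cen$count)
  fate <- classify_population_fate(k, n)
  expect_true(fate$conf_int[1] <= l_true && l_true <= fate$conf_int[2])
  rec <- feasible_mode_fractions(k / n, q_known = truth$q)
  expect_lt(abs(rec$p - truth$p), 0.02)
  expect_lt(abs(rec$r - truth$r), 0.02)
})
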
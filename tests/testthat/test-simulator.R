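test_that("division counts follow the branching process exactly", {
  ## pure self-amplification: 2^3 live aRGCs after three cycles
  amp <- sim_config(founders = 1, t0 = 34, t_end = 37.5, seed = 1,
                    rules = mode_rule_set(mode_fractions(1, 0, 0)))
  f <- run_simulation(amp)
  live <- f[is.na(f$division_time), ]
  expect_equal(nrow(live), 8L)
  expect_true(all(live$type == "ARGC"))

  ## pure self-consumption: the mother is not regenerated
  cons <- sim_config(founders = 1, t0 = 34, t_end = 35.5, seed = 1,
                     rules = mode_rule_set(mode_fractions(0, 0, 1)))
  cen <- census_at(run_simulation(cons), 35.5)
  expect_equal(sum(cen$count[cen$cell_type == "ARGC"]), 0L)
  expect_equal(sum(cen$count[cen$cell_type == "BRGC"]), 2L)

  ## conservation under pure asymmetry: counts equal the founder count
  asym <- sim_config(founders = 10000, t0 = 34, t_end = 35.5, seed = 2,
                     rules = mode_rule_set(mode_fractions(0, 1, 0)))
  cen2 <- census_at(run_simulation(asym), 35.5)
  expect_equal(sum(cen2$count[cen2$cell_type == "ARGC"]), 10000L)
  expect_equal(sum(cen2$count[cen2$cell_type == "BRGC"]), 10000L)
})

test_that("synchronized division without loss doubles the population per cycle", {
  cfg <- sim_config(founders = 7, t0 = 30, t_end = 34.5, seed = 3,
                    rules = mode_rule_set(mode_fractions(1, 0, 0)))
  f <- run_simulation(cfg)
  for (k in 0:4)
    expect_equal(sum(census_at(f, 30 + k + 0.5)$count), 7L * 2^k)
})

test_that("a missing fate rule fails loudly, naming the gap", {
  rules <- fate_rule_set(list(
    fate_rule("ARGC", outcome_table("BRGC", "BRGC", "HORIZONTAL", 2L, 1))),
    cell_cycle_hours = c(ARGC = 24, BRGC = 24))
  cfg <- sim_config(founders = 1, t0 = 34, t_end = 36.5, seed = 1,
                    rules = rules)
  expect_error(run_simulation(cfg), "no fate rule.*BRGC")
  expect_error(sim_config(founders = data.frame(type = character(0),
                                                layer = character(0)),
                          t0 = 30, t_end = 32, seed = 1),
               "empty")
})

test_that("migration follows the entry-window arithmetic", {
  rules <- migration_rules() # delays 2 + 2, window [E34, E42]
  b34 <- apply_migration(hand_cell(1, "BRGC", "VZ", 34), rules)
  expect_equal(b34$isvz_time, 36)
  expect_equal(b34$osvz_time, 38)

  ## born at P1: reaches ISVZ at P3 but the window has closed
  b43 <- apply_migration(hand_cell(1, "BRGC", "VZ", 43), rules)
  expect_equal(b43$isvz_time, 45)
  expect_true(is.na(b43$osvz_time))

  ## window that excludes the journey entirely
  shut <- migration_rules(osvz_entry_window = c(28, 29))
  expect_true(is.na(apply_migration(hand_cell(1, "BRGC", "VZ", 34), shut)$osvz_time))

  ## OSVZ-born cells never change layer
  o <- apply_migration(hand_cell(1, "BRGC", "OSVZ", 44), rules)
  expect_true(is.na(o$isvz_time) && is.na(o$osvz_time))

  ## a closed gene gate at birth vetoes OSVZ entry
  g <- apply_migration(hand_cell(1, "BRGC", "VZ", 35, gate_at_birth = "closed"),
                       rules)
  expect_equal(g$isvz_time, 37)
  expect_true(is.na(g$osvz_time))

  ## the indirect ISVZ route only exists behind its switch
  i_off <- apply_migration(hand_cell(1, "BRGC", "ISVZ", 36), rules)
  expect_true(is.na(i_off$osvz_time))
  i_on <- apply_migration(hand_cell(1, "BRGC", "ISVZ", 36),
                          migration_rules(allow_isvz_route = TRUE))
  expect_equal(i_on$osvz_time, 38)
})

test_that("injection sites determine which cells can be transduced", {
  cfg <- sim_config(founders = 60, t0 = 30, t_end = 45, seed = 11)
  f <- run_simulation(cfg)

  fv <- suppressWarnings(infect(f, injection_spec("VENTRICLE", 43, 10000), seed = 1))
  expect_true(all(fv$type[fv$reporter == "EPISOMAL"] == "ARGC"))
  expect_gt(sum(fv$reporter == "EPISOMAL"), 0L)

  fi <- suppressWarnings(
    infect(f, injection_spec("ISVZ_LOCAL", 43, 10000,
                             retrograde_labeling = FALSE), seed = 1))
  lay <- osvzlineage:::layer_at(fi, 43)
  expect_true(all(lay[fi$reporter == "EPISOMAL"] == "ISVZ"))

  fo <- suppressWarnings(
    infect(f, injection_spec("OSVZ_LOCAL", 43, 10000,
                             retrograde_labeling = TRUE), seed = 1))
  epi_type <- fo$type[fo$reporter == "EPISOMAL"]
  expect_true("ARGC" %in% epi_type) # retrogradely labeled apical cells
  expect_warning(infect(f, injection_spec("VENTRICLE", 43, 10000), seed = 1),
                 "eligible")
  expect_error(infect(f, injection_spec("VENTRICLE", 20, 5), seed = 1),
               "outside the simulated span")
})

test_that("the reporter integrates into exactly one daughter and is then heritable", {
  ## two cycles of amplification from one infected founder: the integrated
  ## sub-lineage is exactly one daughter's subtree
  cfg <- sim_config(founders = 1, t0 = 34, t_end = 36.5, seed = 5,
                    rules = mode_rule_set(mode_fractions(1, 0, 0)))
  f <- run_simulation(cfg)
  f <- infect(f, injection_spec("VENTRICLE", 34, 1), seed = 6)
  f <- segregate_reporter(f, seed = 7)
  daughters <- f[which(f$parent_id == f$id[f$reporter == "EPISOMAL"]), ]
  expect_equal(sum(daughters$reporter == "INTEGRATED"), 1L)
  expect_equal(sum(census_at(f, 36.5,
                             filters = list(reporter = "INTEGRATED"))$count), 2L)

  ## binomial oracle: across many asymmetric divisions the integrated cell
  ## is the mother type half the time
  n <- 4000
  cen <- one_round_census(n, mode_fractions(0, 1, 0), seed = 9)
  k <- sum(cen$count[cen$cell_type == "ARGC"])
  expect_equal(sum(cen$count), n)
  expect_lt(abs(k / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("each clone carries at most one integrated sub-lineage", {
  cfg <- sim_config(founders = 40, t0 = 32, t_end = 38, seed = 13)
  f <- run_simulation(cfg)
  f <- infect(f, injection_spec("VENTRICLE", 32, 25), seed = 14)
  n_infected <- sum(f$reporter == "EPISOMAL")
  f <- segregate_reporter(f, seed = 15)
  integrated <- f[f$reporter == "INTEGRATED", ]
  parent_state <- f$reporter[match(integrated$parent_id, f$id)]
  roots_per_clone <- table(integrated$clone_id[parent_state != "INTEGRATED"])
  expect_true(all(roots_per_clone <= 1L))
  expect_lte(length(roots_per_clone), n_infected)
  ## integrated mothers always pass the state to both daughters
  kids_of_integrated <- f[!is.na(f$parent_id) &
                            f$parent_id %in% integrated$id[!is.na(integrated$division_time)], ]
  expect_true(all(kids_of_integrated$reporter == "INTEGRATED"))
})

test_that("BrdU marks S-phase overlap and is heritable", {
  cfg <- sim_config(founders = 16, t0 = 34, t_end = 38, seed = 21)
  f <- run_simulation(cfg)
  fb <- pulse_brdu(f, brdu_pulse(36, 36.5))
  ## mothers dividing inside the pulse are labeled
  mid <- fb[!is.na(fb$division_time) & fb$division_time == 36, ]
  expect_true(all(mid$brdu))
  ## descendants of labeled mothers inherit the mark
  desc <- fb[!is.na(fb$parent_id) & fb$parent_id %in% mid$id, ]
  expect_true(all(desc$brdu))
  ## founders divide at E35, a full S-phase before the pulse: unlabeled
  founders <- fb[is.na(fb$parent_id), ]
  expect_true(all(!founders$brdu))

  ## a population whose divisions all precede the pulse is 0% BrdU+
  pre <- run_simulation(sim_config(founders = 8, t0 = 30, t_end = 35, seed = 2,
                                   rules = mode_rule_set(mode_fractions(1, 0, 0))))
  pre2 <- pulse_brdu(pre, brdu_pulse(36, 36.5, availability_lag_days = 0))
  expect_equal(sum(pre2$brdu), 0L)
})

test_that("censuses are filtered, bounded to the span, and deterministic", {
  cfg <- sim_config(founders = 12, t0 = 32, t_end = 36, seed = 31)
  f <- run_simulation(cfg)
  ## at t0 the census is exactly the founders
  c0 <- census_at(f, 32)
  expect_equal(sum(c0$count), 12L)
  expect_equal(unique(c0$cell_type), "ARGC")
  ## nobody infected: the integrated-reporter census is empty
  expect_equal(nrow(census_at(f, 35, filters = list(reporter = "INTEGRATED"))), 0L)
  expect_error(census_at(f, 31), "span")
  expect_error(census_at(f, 37), "span")
  expect_error(census_at(f, 35, filters = list(colour = "green")), "unknown")

  ## bit-identical reruns under the same configuration
  f2 <- run_simulation(cfg)
  expect_identical(census_at(f, 36), census_at(f2, 36))
  ## a different seed changes the realization
  f3 <- run_simulation(sim_config(founders = 12, t0 = 32, t_end = 36, seed = 32))
  expect_false(identical(census_at(f, 36), census_at(f3, 36)))
})

test_that("closing the gene gate from E34 prevents OSVZ seeding but spares the ISVZ", {
  cfg <- sim_config(founders = 20, t0 = 30, t_end = 42.5, seed = 5,
                    gene_track = gene_level_track(cdh1_low_from = 34,
                                                  trnp1_high_from = 34))
  f <- run_simulation(cfg)
  f <- infect(f, injection_spec("VENTRICLE", 30, 20), seed = 6)
  f <- segregate_reporter(f, seed = 7)
  cen <- census_at(f, 42, filters = list(reporter = "INTEGRATED"))
  expect_equal(sum(cen$count[cen$cell_type == "BRGC" & cen$layer == "OSVZ"]), 0L)
  expect_gt(sum(cen$count[cen$cell_type == "BRGC" & cen$layer == "ISVZ"]), 0L)

  ## under the default track the same design does seed the OSVZ
  cfg_wt <- sim_config(founders = 20, t0 = 30, t_end = 42.5, seed = 5)
  fw <- segregate_reporter(infect(run_simulation(cfg_wt),
                                  injection_spec("VENTRICLE", 30, 20), seed = 6),
                           seed = 7)
  cw <- census_at(fw, 42, filters = list(reporter = "INTEGRATED"))
  expect_gt(sum(cw$count[cw$cell_type == "BRGC" & cw$layer == "OSVZ"]), 0L)
})
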
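# Independent oracles used to freeze expected values, kept deliberately
# separate from the implementation paths they check.

# Brute-force enumeration of the single-daughter reporter-segregation model:
# average, over division modes and the two equiprobable integration choices,
# the indicator that the integrated daughter is of the mother type.
enumerate_labeled_mother_fraction <- function(p, q, r) {
  modes <- list(amp = c("M", "M"), asym = c("M", "O"), cons = c("O", "O"))
  probs <- c(amp = p, asym = q, cons = r)
  total <- 0
  for (m in names(modes)) {
    for (daughter in 1:2) {
      total <- total + probs[[m]] * 0.5 * (modes[[m]][daughter] == "M")
    }
  }
  total
}

# Two-sided exact binomial p-value vs 0.5 by direct summation of the pmf.
exact_binom_p_oracle <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Minimal hand-built forest rows for migration/census checks.
hand_cell <- function(id, type, birth_layer, birth_time, parent_id = NA_integer_,
                      division_time = NA_real_, gate_at_birth = NULL,
                      reporter = "NONE") {
  df <- data.frame(id = as.integer(id), parent_id = as.integer(parent_id),
                   clone_id = 1L, type = type, birth_layer = birth_layer,
                   birth_time = birth_time, division_time = division_time,
                   reporter = reporter, brdu = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(gate_at_birth)) df$gate_at_birth <- gate_at_birth
  df
}

# One-round clone experiment: founders infected at t0, one division, census.
one_round_census <- function(n_clones, m, seed) {
  cfg <- sim_config(founders = n_clones, t0 = 34, t_end = 35.5, seed = seed,
                    rules = mode_rule_set(m))
  f <- run_simulation(cfg)
  f <- infect(f, injection_spec("VENTRICLE", 34, n_clones),
              seed = seed + 1L)
  f <- segregate_reporter(f, seed = seed + 2L)
  census_at(f, 35.5, filters = list(reporter = "INTEGRATED"))
}
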
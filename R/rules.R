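## Division rules, the Cdh1/Trnp1 gene gate, migration rules and experiment
## specifications consumed by the simulator.

#' Piecewise-constant qualitative gene-level track for Cdh1 and Trnp1
#'
#' The critical window for OSVZ seeding is gated by qualitative expression
#' levels of two genes: the window opens when Cdh1 expression falls and Trnp1
#' is still low, and closes when Trnp1 rises around birth. Levels are
#' piecewise-constant (`"HIGH"`/`"LOW"`) over embryonic-day time.
#'
#' The default track encodes the qualitative model: Cdh1 HIGH before E34 and
#' LOW after; Trnp1 LOW before E42 (birth) and HIGH after.
#'
#' @param cdh1_low_from Embryonic day at which Cdh1 switches HIGH -> LOW
#'   (`Inf` keeps Cdh1 HIGH throughout).
#' @param trnp1_high_from Embryonic day at which Trnp1 switches LOW -> HIGH
#'   (`Inf` keeps Trnp1 LOW throughout).
#' @return An object of class `"gene_level_track"`.
#' @export
gene_level_track <- function(cdh1_low_from = 34, trnp1_high_from = 42) {
  stopifnot(is.numeric(cdh1_low_from), is.numeric(trnp1_high_from))
  structure(list(cdh1_low_from = cdh1_low_from,
                 trnp1_high_from = trnp1_high_from),
            class = "gene_level_track")
}

#' Query gene levels and the gate state at a time point
#'
#' The gate state summarises the fate regime implied by the two gene levels:
#' `"pre"` (Cdh1 HIGH: self-renewal/amplification enforced), `"open"`
#' (Cdh1 LOW and Trnp1 LOW: the critical window, bRGC-generating and
#' self-consuming divisions) and `"closed"` (Trnp1 HIGH: window closed,
#' self-renewal with ISVZ-destined bRGC output). Cdh1 HIGH dominates.
#'
#' @param track A [gene_level_track()].
#' @param t Numeric vector of embryonic days.
#' @return `gene_levels()`: data frame with columns `cdh1` and `trnp1`;
#'   `gate_state()`: character vector in `c("pre", "open", "closed")`.
#' @export
gate_state <- function(track, t) {
  stopifnot(inherits(track, "gene_level_track"), is.numeric(t))
  cdh1_high <- t < track$cdh1_low_from
  trnp1_high <- t >= track$trnp1_high_from
  ifelse(cdh1_high, "pre", ifelse(trnp1_high, "closed", "open"))
}

#' @rdname gate_state
#' @export
gene_levels <- function(track, t) {
  stopifnot(inherits(track, "gene_level_track"), is.numeric(t))
  data.frame(cdh1 = ifelse(t < track$cdh1_low_from, "HIGH", "LOW"),
             trnp1 = ifelse(t >= track$trnp1_high_from, "HIGH", "LOW"))
}

#' Construct a division-outcome table
#'
#' A probability distribution over division outcomes for one progenitor
#' context. Each outcome names the ordered pair of daughter types, the
#' cleavage class of the division and the number of daughters delaminating
#' from the apical surface (at most the number of non-aRGC daughters).
#'
#' @param daughter1,daughter2 Character vectors of daughter cell types.
#' @param cleavage Character vector of cleavage classes.
#' @param n_delaminating Integer vector in `{0, 1, 2}`.
#' @param prob Numeric vector of probabilities summing to 1 (tolerance 1e-9).
#' @return A data frame of class `"outcome_table"`.
#' @export
outcome_table <- function(daughter1, daughter2, cleavage, n_delaminating, prob) {
  df <- data.frame(daughter1 = daughter1, daughter2 = daughter2,
                   cleavage = cleavage, n_delaminating = as.integer(n_delaminating),
                   prob = prob, stringsAsFactors = FALSE)
  if (!all(df$daughter1 %in% CELL_TYPES) || !all(df$daughter2 %in% CELL_TYPES))
    stop("daughter types must be in CELL_TYPES")
  if (!all(df$cleavage %in% CLEAVAGE_CLASSES))
    stop("cleavage must be in CLEAVAGE_CLASSES")
  non_argc <- (df$daughter1 != "ARGC") + (df$daughter2 != "ARGC")
  if (any(df$n_delaminating < 0L | df$n_delaminating > non_argc))
    stop("n_delaminating must be between 0 and the number of non-aRGC daughters")
  if (any(df$prob < 0)) stop("outcome probabilities must be >= 0")
  if (abs(sum(df$prob) - 1) > 1e-9)
    stop("outcome probabilities must sum to 1 (tolerance 1e-9)")
  class(df) <- c("outcome_table", "data.frame")
  df
}

#' Define one fate rule
#'
#' A rule maps a progenitor context — cell type, layer, gate state and an
#' optional time interval — to an [outcome_table()]. Wildcards (`"*"`) match
#' any layer or gate state; rules are consulted in order and the first match
#' wins.
#'
#' @param type Cell type the rule applies to.
#' @param layer Layer or `"*"`.
#' @param gate Gate state (`"pre"`, `"open"`, `"closed"`) or `"*"`.
#' @param outcomes An [outcome_table()].
#' @param t_min,t_max Embryonic-day interval `[t_min, t_max)` the rule covers.
#' @return A list of class `"fate_rule"`.
#' @export
fate_rule <- function(type, outcomes, layer = "*", gate = "*",
                      t_min = -Inf, t_max = Inf) {
  stopifnot(type %in% CELL_TYPES,
            layer == "*" || layer %in% LAYERS,
            gate %in% c("*", "pre", "open", "closed"),
            inherits(outcomes, "outcome_table"),
            t_min < t_max)
  structure(list(type = type, layer = layer, gate = gate,
                 t_min = t_min, t_max = t_max, outcomes = outcomes),
            class = "fate_rule")
}

#' Assemble a fate rule set
#'
#' @param rules A list of [fate_rule()] objects.
#' @param cell_cycle_hours Named numeric vector of cell-cycle durations in
#'   hours for the cycling types; types absent from it never divide. The
#'   default 24 h applies to all cycling progenitors (only S-phase, about
#'   12 h, is constrained by observation; total cycle length is a free
#'   parameter that scales the simulated clock).
#' @return An object of class `"fate_rule_set"`.
#' @export
fate_rule_set <- function(rules,
                          cell_cycle_hours = c(ARGC = 24, BRGC = 24, IPC = 24)) {
  stopifnot(is.list(rules), length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "fate_rule")),
            is.numeric(cell_cycle_hours), all(cell_cycle_hours > 0),
            !is.null(names(cell_cycle_hours)),
            all(names(cell_cycle_hours) %in% CELL_TYPES))
  structure(list(rules = rules, cell_cycle_hours = cell_cycle_hours),
            class = "fate_rule_set")
}

## First rule matching (type, layer, gate, time); NULL if none.
find_rule <- function(rule_set, type, layer, gate, t) {
  for (r in rule_set$rules) {
    if (r$type == type &&
        (r$layer == "*" || r$layer == layer) &&
        (r$gate == "*" || r$gate == gate) &&
        t >= r$t_min && t < r$t_max)
      return(r)
  }
  NULL
}

#' Default fate rules: the gene-gated division-regime preset
#'
#' A configuration preset encoding the qualitative fate model. Apical RGC
#' outcomes depend on the gate state: before the window (`"pre"`, Cdh1 HIGH)
#' aRGCs mostly self-renew; during the window (`"open"`) they shift to
#' self-consuming, bRGC-generating divisions, with a burst before E36 and a
#' moderate regime after; after closure (`"closed"`, Trnp1 HIGH) they
#' self-renew while streaming bRGCs to the ISVZ. Basal RGCs self-amplify,
#' most strongly in the OSVZ, and produce glial (star-cell) output only once
#' the gate has closed (postnatal stages). IPCs divide once into two
#' neurons.
#'
#' The probabilities are free parameters loosely calibrated so that
#' short-survival labeled-cell fractions resemble the observed developmental
#' series; they are inputs to the simulator, never asserted as outputs.
#'
#' @return A [fate_rule_set()].
#' @export
default_fate_rules <- function() {
  argc_pre <- outcome_table(
    daughter1 = c("ARGC", "ARGC", "ARGC", "BRGC", "BRGC"),
    daughter2 = c("ARGC", "BRGC", "MIGRATING_NEURON", "BRGC", "MIGRATING_NEURON"),
    cleavage = c("VERTICAL", "OBLIQUE", "OBLIQUE", "HORIZONTAL", "HORIZONTAL"),
    n_delaminating = c(0L, 1L, 1L, 2L, 2L),
    prob = c(0.25, 0.30, 0.15, 0.20, 0.10))
  argc_burst <- outcome_table(
    daughter1 = c("BRGC", "ARGC", "ARGC", "BRGC", "BRGC"),
    daughter2 = c("BRGC", "BRGC", "ARGC", "IPC", "MIGRATING_NEURON"),
    cleavage = c("HORIZONTAL", "OBLIQUE", "VERTICAL", "HORIZONTAL", "HORIZONTAL"),
    n_delaminating = c(2L, 1L, 0L, 2L, 2L),
    prob = c(0.55, 0.25, 0.10, 0.05, 0.05))
  argc_open_late <- outcome_table(
    daughter1 = c("ARGC", "ARGC", "ARGC", "BRGC", "BRGC"),
    daughter2 = c("ARGC", "BRGC", "MIGRATING_NEURON", "BRGC", "MIGRATING_NEURON"),
    cleavage = c("VERTICAL", "OBLIQUE", "OBLIQUE", "HORIZONTAL", "HORIZONTAL"),
    n_delaminating = c(0L, 1L, 1L, 2L, 2L),
    prob = c(0.20, 0.50, 0.05, 0.20, 0.05))
  argc_closed <- outcome_table(
    daughter1 = c("ARGC", "ARGC", "ARGC", "BRGC", "BRGC"),
    daughter2 = c("ARGC", "BRGC", "MIGRATING_NEURON", "BRGC", "MIGRATING_NEURON"),
    cleavage = c("VERTICAL", "OBLIQUE", "OBLIQUE", "HORIZONTAL", "HORIZONTAL"),
    n_delaminating = c(0L, 1L, 1L, 2L, 2L),
    prob = c(0.20, 0.55, 0.10, 0.10, 0.05))
  brgc_osvz <- outcome_table(
    daughter1 = c("BRGC", "BRGC", "MIGRATING_NEURON"),
    daughter2 = c("BRGC", "MIGRATING_NEURON", "MIGRATING_NEURON"),
    cleavage = c("HORIZONTAL", "OBLIQUE", "VERTICAL"),
    n_delaminating = c(0L, 0L, 0L),
    prob = c(0.45, 0.30, 0.25))
  brgc_closed <- outcome_table(
    daughter1 = c("BRGC", "BRGC", "BRGC", "MIGRATING_NEURON"),
    daughter2 = c("BRGC", "STAR_CELL", "MIGRATING_NEURON", "MIGRATING_NEURON"),
    cleavage = c("HORIZONTAL", "OBLIQUE", "OBLIQUE", "VERTICAL"),
    n_delaminating = c(0L, 0L, 0L, 0L),
    prob = c(0.35, 0.10, 0.30, 0.25))
  brgc_any <- outcome_table(
    daughter1 = c("BRGC", "BRGC", "MIGRATING_NEURON"),
    daughter2 = c("BRGC", "MIGRATING_NEURON", "MIGRATING_NEURON"),
    cleavage = c("HORIZONTAL", "OBLIQUE", "VERTICAL"),
    n_delaminating = c(0L, 0L, 0L),
    prob = c(0.35, 0.40, 0.25))
  ipc_any <- outcome_table(
    daughter1 = "MIGRATING_NEURON", daughter2 = "MIGRATING_NEURON",
    cleavage = "VERTICAL", n_delaminating = 0L, prob = 1)
  fate_rule_set(list(
    fate_rule("ARGC", argc_pre, layer = "VZ", gate = "pre"),
    fate_rule("ARGC", argc_burst, layer = "VZ", gate = "open", t_max = 36),
    fate_rule("ARGC", argc_open_late, layer = "VZ", gate = "open", t_min = 36),
    fate_rule("ARGC", argc_closed, layer = "VZ", gate = "closed"),
    fate_rule("BRGC", brgc_osvz, layer = "OSVZ"),
    fate_rule("BRGC", brgc_closed, gate = "closed"),
    fate_rule("BRGC", brgc_any),
    fate_rule("IPC", ipc_any)
  ))
}

#' Build a homogeneous apical-RGC rule set from division-mode fractions
#'
#' Convenience constructor for analytic checks: aRGCs divide with probability
#' `p` symmetrically into two aRGCs (self-amplifying, vertical cleavage),
#' `q` asymmetrically into an aRGC plus a bRGC (oblique), and `r`
#' symmetrically into two bRGCs (self-consuming, horizontal). Daughter bRGCs
#' and any other types do not divide under this rule set, so one round of
#' division is exactly the closed-form reporter-segregation model.
#'
#' @param m A [mode_fractions()] object (or numeric `c(p, q, r)`).
#' @return A [fate_rule_set()].
#' @export
mode_rule_set <- function(m) {
  m <- as_mode_fractions(m)
  keep <- c(m$p, m$q, m$r) > 0
  tab <- outcome_table(
    daughter1 = c("ARGC", "ARGC", "BRGC")[keep],
    daughter2 = c("ARGC", "BRGC", "BRGC")[keep],
    cleavage = c("VERTICAL", "OBLIQUE", "HORIZONTAL")[keep],
    n_delaminating = c(0L, 1L, 2L)[keep],
    prob = c(m$p, m$q, m$r)[keep])
  fate_rule_set(list(fate_rule("ARGC", tab)),
                cell_cycle_hours = c(ARGC = 24))
}

#' Inter-layer migration rules
#'
#' Newborn basal progenitors (bRGCs, and IPCs en route to the OSVZ) born in
#' the VZ lineage reach the ISVZ after `delay_vz_to_isvz` days and may
#' advance to the OSVZ `delay_isvz_to_osvz` days later — but only if both
#' their birth time and their OSVZ arrival time fall inside
#' `osvz_entry_window`, and (when the forest records it) the gene gate was
#' open at their birth. Otherwise they remain in the ISVZ permanently.
#' OSVZ-born cells never change layer. ISVZ-born basal progenitors may take
#' the indirect ISVZ -> OSVZ route inside the window when
#' `allow_isvz_route = TRUE` (whether the few mid-window OSVZ bRGCs arrive
#' directly or via an ISVZ division is observationally open; both routes are
#' implemented behind this switch).
#'
#' @param delay_vz_to_isvz,delay_isvz_to_osvz Positive migration delays, days.
#' @param osvz_entry_window Numeric length-2 embryonic-day interval (default
#'   `c(34, 42)`: window opening at E34, closing at birth).
#' @param allow_isvz_route Allow ISVZ-born basal progenitors to advance to
#'   the OSVZ inside the window (default `FALSE`: the ISVZ retains its
#'   residents and the OSVZ is seeded by through-migrating VZ-born streams;
#'   with the switch on, in-window ISVZ-born cells also advance).
#' @return An object of class `"migration_rules"`.
#' @export
migration_rules <- function(delay_vz_to_isvz = 2, delay_isvz_to_osvz = 2,
                            osvz_entry_window = c(34, 42),
                            allow_isvz_route = FALSE) {
  stopifnot(delay_vz_to_isvz > 0, delay_isvz_to_osvz > 0,
            length(osvz_entry_window) == 2L,
            osvz_entry_window[1] < osvz_entry_window[2])
  structure(list(delay_vz_to_isvz = delay_vz_to_isvz,
                 delay_isvz_to_osvz = delay_isvz_to_osvz,
                 osvz_entry_window = osvz_entry_window,
                 allow_isvz_route = isTRUE(allow_isvz_route)),
            class = "migration_rules")
}

#' Retroviral injection specification
#'
#' @param site `"VENTRICLE"` (transduces only cells in contact with the
#'   ventricular surface, i.e. apically attached aRGCs), `"ISVZ_LOCAL"` or
#'   `"OSVZ_LOCAL"` (transduce somata in that layer, plus — when
#'   `retrograde_labeling = TRUE` — apical-layer cells whose radial process
#'   spans the site: aRGCs for ISVZ injections; aRGCs and ISVZ bRGCs for
#'   OSVZ injections).
#' @param time Injection time, embryonic days.
#' @param n_infected Number of cells to transduce (>= 1).
#' @param retrograde_labeling Also label cells reached via their basal
#'   process (default `TRUE` for local injections, as observed).
#' @return An object of class `"injection_spec"`.
#' @export
injection_spec <- function(site, time, n_infected,
                           retrograde_labeling = site != "VENTRICLE") {
  site <- match.arg(site, c("VENTRICLE", "ISVZ_LOCAL", "OSVZ_LOCAL"))
  stopifnot(is.numeric(time), length(time) == 1L,
            is.numeric(n_infected), n_infected >= 1)
  structure(list(site = site, time = time,
                 n_infected = as.integer(n_infected),
                 retrograde_labeling = isTRUE(retrograde_labeling)),
            class = "injection_spec")
}

#' BrdU pulse specification
#'
#' Cells whose S-phase interval — modeled as the `s_phase_hours` window
#' ending at their division time — overlaps
#' `[start, end + availability_lag_days]` incorporate BrdU; the label is
#' heritable (dilution is not modeled).
#'
#' @param start,end Pulse administration interval, embryonic days.
#' @param s_phase_hours S-phase duration (default 12 h).
#' @param availability_lag_days Residual label availability after the last
#'   administration, days (default 0).
#' @return An object of class `"brdu_pulse"`.
#' @export
brdu_pulse <- function(start, end, s_phase_hours = 12,
                       availability_lag_days = 0) {
  stopifnot(start < end, s_phase_hours > 0, availability_lag_days >= 0)
  structure(list(start = start, end = end, s_phase_hours = s_phase_hours,
                 availability_lag_days = availability_lag_days),
            class = "brdu_pulse")
}

#' Simulation configuration
#'
#' @param founders Either a count (taken as that many apical RGCs in the VZ)
#'   or a data frame with columns `type` and `layer`, one row per founder.
#' @param t0,t_end Simulation span in embryonic days (`t0 < t_end`).
#' @param seed Integer seed; required, recorded with the forest.
#' @param rules A [fate_rule_set()].
#' @param migration A [migration_rules()].
#' @param gene_track A [gene_level_track()].
#' @param neuron_maturation_days Days after which a migrating neuron is
#'   counted as a differentiating neuron in the cortical plate (default 4).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(founders, t0, t_end, seed,
                       rules = default_fate_rules(),
                       migration = migration_rules(),
                       gene_track = gene_level_track(),
                       neuron_maturation_days = 4) {
  if (is.numeric(founders) && length(founders) == 1L) {
    founders <- data.frame(type = rep("ARGC", founders),
                           layer = rep("VZ", founders))
  }
  stopifnot(is.data.frame(founders), all(c("type", "layer") %in% names(founders)),
            all(founders$type %in% CELL_TYPES), all(founders$layer %in% LAYERS))
  if (nrow(founders) < 1L) stop("founder set is empty")
  if (missing(seed) || is.null(seed)) stop("`seed` must be given explicitly")
  stopifnot(is.numeric(t0), is.numeric(t_end), t0 < t_end,
            inherits(rules, "fate_rule_set"),
            inherits(migration, "migration_rules"),
            inherits(gene_track, "gene_level_track"),
            neuron_maturation_days > 0)
  structure(list(founders = founders, t0 = t0, t_end = t_end,
                 seed = as.integer(seed), rules = rules, migration = migration,
                 gene_track = gene_track,
                 neuron_maturation_days = neuron_maturation_days),
            class = "sim_config")
}
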
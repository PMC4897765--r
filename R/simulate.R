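## The branching-process engine. A lineage forest is a data frame with one
## row per cell; division events are processed frontier-by-frontier (each
## cell divides once, after its cell-cycle duration, into exactly two
## daughters drawn from the fate rule in force at the division time).

FOREST_COLUMNS <- c("id", "parent_id", "clone_id", "type", "birth_layer",
                    "birth_time", "gate_at_birth", "isvz_time", "osvz_time",
                    "division_time", "cleavage", "n_delaminating",
                    "reporter", "brdu")

## OSVZ competence: forests record the gate state at each cell's birth; cells
## born outside the open window never seed the OSVZ. Hand-built forests
## without the column are treated as competent.
osvz_competent <- function(gate_at_birth) {
  if (is.null(gate_at_birth)) TRUE else gate_at_birth == "open"
}

## Migration is a property of the basal sub-lineage, not of individual
## cells: a bRGC stream leaving the VZ at its origin time reaches the ISVZ
## delay_vz_to_isvz days later and (when eligible) the OSVZ after a further
## delay_isvz_to_osvz days, regardless of how many divisions happen en
## route. Daughters born mid-journey inherit the stream origin.
migration_schedule <- function(type, origin_layer, origin_time, origin_gate,
                               rules) {
  n <- length(type)
  isvz <- rep(NA_real_, n)
  osvz <- rep(NA_real_, n)
  basal <- type %in% c("BRGC", "IPC") & !is.na(origin_layer)
  win <- rules$osvz_entry_window
  comp <- osvz_competent(origin_gate)
  if (length(comp) == 1L) comp <- rep(comp, n)
  comp[is.na(comp)] <- FALSE

  vz <- basal & origin_layer == "VZ"
  isvz[vz] <- origin_time[vz] + rules$delay_vz_to_isvz
  cand <- isvz + rules$delay_isvz_to_osvz
  ok <- vz & comp &
    origin_time >= win[1] & origin_time <= win[2] &
    cand >= win[1] & cand <= win[2]
  osvz[which(ok)] <- cand[which(ok)]

  if (rules$allow_isvz_route) {
    is_isvz <- basal & origin_layer == "ISVZ"
    cand2 <- origin_time + rules$delay_isvz_to_osvz
    ok2 <- is_isvz & comp &
      origin_time >= win[1] & origin_time <= win[2] &
      cand2 >= win[1] & cand2 <= win[2]
    osvz[which(ok2)] <- cand2[which(ok2)]
  }
  list(isvz_time = isvz, osvz_time = osvz)
}

#' Recompute migration trajectories for a lineage forest
#'
#' Applies [migration_rules()] to every cell: VZ-born basal progenitors
#' occupy the ISVZ from `birth + delay_vz_to_isvz` and advance to the OSVZ
#' `delay_isvz_to_osvz` days later only if birth and arrival both fall
#' inside the OSVZ entry window (and the gene gate was open at birth, when
#' recorded); otherwise they remain in the ISVZ permanently. OSVZ-born cells
#' never change layer.
#'
#' @param forest A lineage forest ([run_simulation()]).
#' @param rules A [migration_rules()].
#' @return The forest with updated `isvz_time`/`osvz_time` columns.
#' @export
apply_migration <- function(forest, rules) {
  stopifnot(is.data.frame(forest), inherits(rules, "migration_rules"))
  ## simulated forests carry the basal-stream origin; hand-built forests
  ## default to each cell's own birth record
  o_time <- forest$origin_time %||% forest$birth_time
  o_layer <- forest$origin_layer %||% forest$birth_layer
  o_gate <- forest$origin_gate %||% forest$gate_at_birth
  if (is.null(o_gate)) o_gate <- rep("open", nrow(forest))
  sched <- migration_schedule(forest$type, o_layer, o_time, o_gate, rules)
  forest$isvz_time <- sched$isvz_time
  forest$osvz_time <- sched$osvz_time
  forest
}

maturation_days <- function(forest) {
  m <- attr(forest, "neuron_maturation_days")
  if (is.null(m)) 4 else m
}

## Effective type/layer of cells at analysis time t (scalar or per-cell).
type_at <- function(forest, t) {
  ty <- forest$type
  mat <- maturation_days(forest)
  mn <- ty == "MIGRATING_NEURON" & (t - forest$birth_time >= mat)
  ty[mn] <- "DIFF_NEURON"
  ty
}

layer_at <- function(forest, t) {
  lay <- forest$birth_layer
  basal <- forest$type %in% c("BRGC", "IPC")
  in_isvz <- basal & !is.na(forest$isvz_time) & t >= forest$isvz_time
  in_osvz <- basal & !is.na(forest$osvz_time) & t >= forest$osvz_time
  lay[in_isvz] <- "ISVZ"
  lay[in_osvz] <- "OSVZ"
  mat <- maturation_days(forest)
  age <- t - forest$birth_time
  mn <- forest$type == "MIGRATING_NEURON"
  lay[mn & age >= 1 & age < mat] <- "IZ"
  lay[mn & age >= mat] <- "CP"
  lay[forest$type == "DIFF_NEURON"] <- "CP"
  lay
}

#' Simulate clonal lineages as a stochastic branching process
#'
#' Starting from the founder cells at `t0`, every cycling cell divides once,
#' after the cell-cycle duration of its type, into exactly two daughters
#' drawn from the fate rule matching the mother's type, current layer, gate
#' state and time at division. Daughters inherit the mother's layer (apical
#' RGC daughters are always born in the VZ) and their migration trajectory
#' is scheduled at birth from the configured [migration_rules()]. The run is
#' deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A data frame of class `"lineage_forest"`, one row per cell:
#'   identifiers (`id`, `parent_id`, `clone_id`), state at birth (`type`,
#'   `birth_layer`, `birth_time`, `gate_at_birth`), scheduled migration
#'   times, the division record (`division_time`, `cleavage`,
#'   `n_delaminating`; `NA` for cells that never divide in the span) and
#'   label states (`reporter`, `brdu`). The simulation span, neuron
#'   maturation lag and full configuration are carried as attributes.
#' @examples
#' cfg <- sim_config(founders = 1, t0 = 34, t_end = 37.5, seed = 1,
#'                   rules = mode_rule_set(mode_fractions(1, 0, 0)))
#' f <- run_simulation(cfg)
#' sum(is.na(f$division_time) & f$type == "ARGC") # 8 live aRGCs after 3 cycles
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rules <- config$rules
  track <- config$gene_track
  mig <- config$migration
  t0 <- config$t0
  t_end <- config$t_end
  cyc_days <- rules$cell_cycle_hours / 24

  with_seed(config$seed, {
    n0 <- nrow(config$founders)
    gate0 <- gate_state(track, rep(t0, n0))
    basal0 <- config$founders$type %in% c("BRGC", "IPC")
    o_layer0 <- ifelse(basal0, config$founders$layer, NA_character_)
    o_time0 <- ifelse(basal0, t0, NA_real_)
    o_gate0 <- ifelse(basal0, gate0, NA_character_)
    sched0 <- migration_schedule(config$founders$type, o_layer0, o_time0,
                                 o_gate0, mig)
    frontier <- data.frame(
      id = seq_len(n0), parent_id = NA_integer_, clone_id = seq_len(n0),
      type = config$founders$type, birth_layer = config$founders$layer,
      birth_time = rep(t0, n0), gate_at_birth = gate0,
      origin_time = o_time0, origin_layer = o_layer0, origin_gate = o_gate0,
      isvz_time = sched0$isvz_time, osvz_time = sched0$osvz_time,
      division_time = NA_real_, cleavage = NA_character_,
      n_delaminating = NA_integer_, reporter = "NONE", brdu = FALSE,
      stringsAsFactors = FALSE)
    next_id <- n0 + 1L
    done <- list()
    gen <- 0L

    while (nrow(frontier) > 0L) {
      gen <- gen + 1L
      idx <- match(frontier$type, names(cyc_days))
      div_t <- frontier$birth_time + unname(cyc_days)[idx] # NA for non-cycling
      dividing <- which(!is.na(div_t) & div_t <= t_end)
      frontier$division_time[dividing] <- div_t[dividing]

      if (length(dividing) == 0L) {
        done[[gen]] <- frontier
        break
      }
      md_t <- div_t[dividing]
      m_lay <- layer_at(frontier[dividing, , drop = FALSE], t = md_t)
      m_gate <- gate_state(track, md_t)
      m_type <- frontier$type[dividing]

      nd <- length(dividing)
      d1 <- character(nd); d2 <- character(nd)
      clv <- character(nd); ndel <- integer(nd)
      key <- paste(m_type, m_lay, m_gate, md_t, sep = "\r")
      for (uk in unique(key)) {
        sel <- which(key == uk)
        i1 <- sel[1L]
        r <- find_rule(rules, m_type[i1], m_lay[i1], m_gate[i1], md_t[i1])
        if (is.null(r))
          stop(sprintf(
            "no fate rule defined for type=%s, layer=%s, gate=%s at %s",
            m_type[i1], m_lay[i1], m_gate[i1], format_dev_time(md_t[i1])))
        k <- sample.int(nrow(r$outcomes), length(sel), replace = TRUE,
                        prob = r$outcomes$prob)
        d1[sel] <- r$outcomes$daughter1[k]
        d2[sel] <- r$outcomes$daughter2[k]
        clv[sel] <- r$outcomes$cleavage[k]
        ndel[sel] <- r$outcomes$n_delaminating[k]
      }
      frontier$cleavage[dividing] <- clv
      frontier$n_delaminating[dividing] <- ndel
      done[[gen]] <- frontier

      dtype <- as.vector(rbind(d1, d2))
      db <- rep(md_t, each = 2L)
      dlay <- ifelse(dtype == "ARGC", "VZ", rep(m_lay, each = 2L))
      dgate <- rep(m_gate, each = 2L)
      dbasal <- dtype %in% c("BRGC", "IPC")
      ## basal daughters of a basal mother whose migration is still pending
      ## continue the mother's stream (journeys outlast the cell cycle);
      ## daughters of settled mothers start a new stream at birth
      m_basal <- rep(frontier$type[dividing] %in% c("BRGC", "IPC"), each = 2L)
      m_isvz <- frontier$isvz_time[dividing]
      m_osvz <- frontier$osvz_time[dividing]
      pending <- (!is.na(m_isvz) & md_t < m_isvz) |
        (!is.na(m_osvz) & md_t < m_osvz)
      inherit <- dbasal & m_basal & rep(pending, each = 2L)
      d_o_time <- ifelse(dbasal, db, NA_real_)
      d_o_layer <- ifelse(dbasal, dlay, NA_character_)
      d_o_gate <- ifelse(dbasal, dgate, NA_character_)
      d_o_time[inherit] <- rep(frontier$origin_time[dividing], each = 2L)[inherit]
      d_o_layer[inherit] <- rep(frontier$origin_layer[dividing], each = 2L)[inherit]
      d_o_gate[inherit] <- rep(frontier$origin_gate[dividing], each = 2L)[inherit]
      dsched <- migration_schedule(dtype, d_o_layer, d_o_time, d_o_gate, mig)
      nk <- length(dtype)
      frontier <- data.frame(
        id = seq.int(next_id, length.out = nk),
        parent_id = rep(frontier$id[dividing], each = 2L),
        clone_id = rep(frontier$clone_id[dividing], each = 2L),
        type = dtype, birth_layer = dlay, birth_time = db,
        gate_at_birth = dgate,
        origin_time = d_o_time, origin_layer = d_o_layer,
        origin_gate = d_o_gate,
        isvz_time = dsched$isvz_time, osvz_time = dsched$osvz_time,
        division_time = NA_real_, cleavage = NA_character_,
        n_delaminating = NA_integer_, reporter = "NONE", brdu = FALSE,
        stringsAsFactors = FALSE)
      next_id <- next_id + nk
    }

    forest <- do.call(rbind, done)
    rownames(forest) <- NULL
    ## cell-level flags implied by type
    forest$apical_attachment <- forest$type == "ARGC"
    forest$basal_process <- forest$type %in% c("ARGC", "BRGC")
    attr(forest, "t0") <- t0
    attr(forest, "t_end") <- t_end
    attr(forest, "neuron_maturation_days") <- config$neuron_maturation_days
    attr(forest, "seed") <- config$seed
    attr(forest, "config") <- config
    class(forest) <- c("lineage_forest", "data.frame")
    forest
  })
}

forest_span <- function(forest) {
  c(attr(forest, "t0") %||% min(forest$birth_time),
    attr(forest, "t_end") %||% max(forest$birth_time,
                                   forest$division_time, na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Live cells at t: born, and not yet divided.
live_at <- function(forest, t) {
  forest$birth_time <= t &
    (is.na(forest$division_time) | forest$division_time > t)
}

#' Transduce cells with a retroviral reporter
#'
#' Samples `n_infected` cells among those eligible at the injection time and
#' sets their reporter state to `EPISOMAL` (the reporter integrates into one
#' random daughter only at the first division after infection; see
#' [segregate_reporter()]). Ventricular injections reach only apically
#' attached cells; local injections reach somata in the target layer, plus
#' retrogradely labeled apical-layer cells when requested.
#'
#' @param forest A lineage forest.
#' @param spec An [injection_spec()].
#' @param seed Optional integer seed.
#' @return The forest with updated reporter states.
#' @export
infect <- function(forest, spec, seed = NULL) {
  stopifnot(inherits(spec, "injection_spec"))
  span <- forest_span(forest)
  if (spec$time < span[1] || spec$time > span[2])
    stop("injection time lies outside the simulated span")
  live <- live_at(forest, spec$time)
  lay <- layer_at(forest, spec$time)
  elig <- switch(spec$site,
    VENTRICLE = live & forest$type == "ARGC",
    ISVZ_LOCAL = live & (lay == "ISVZ" |
      (spec$retrograde_labeling & forest$type == "ARGC")),
    OSVZ_LOCAL = live & (lay == "OSVZ" |
      (spec$retrograde_labeling &
         (forest$type == "ARGC" | (forest$type == "BRGC" & lay == "ISVZ")))))
  idx <- which(elig)
  with_seed(seed, {
    if (length(idx) < spec$n_infected) {
      warning(sprintf("only %d eligible cells for %d requested infections; infecting all",
                      length(idx), spec$n_infected))
      chosen <- idx
    } else {
      chosen <- idx[sample.int(length(idx), spec$n_infected)]
    }
    forest$reporter[chosen] <- "EPISOMAL"
    forest
  })
}

children_index <- function(forest) {
  has_parent <- !is.na(forest$parent_id)
  split(which(has_parent), forest$parent_id[has_parent])
}

#' Segregate the retroviral reporter at division
#'
#' For every `EPISOMAL` cell that divides, the reporter integrates into
#' exactly one uniformly chosen daughter, which becomes `INTEGRATED`; the
#' other daughter carries no reporter. `INTEGRATED` cells pass the state to
#' both daughters indefinitely. `EPISOMAL` cells that never divide keep the
#' episome and are excluded from integrated-reporter censuses.
#'
#' @param forest A lineage forest with some `EPISOMAL` cells (see [infect()]).
#' @param seed Optional integer seed.
#' @return The forest with propagated reporter states.
#' @export
segregate_reporter <- function(forest, seed = NULL) {
  kids <- children_index(forest)
  epi <- which(forest$reporter == "EPISOMAL" & !is.na(forest$division_time))
  with_seed(seed, {
    if (length(epi) > 0L) {
      km <- kids[as.character(forest$id[epi])]
      stopifnot(all(lengths(km) == 2L))
      kmat <- matrix(unlist(km, use.names = FALSE), ncol = 2L, byrow = TRUE)
      pick <- 1L + (stats::runif(length(epi)) < 0.5)
      frontier <- kmat[cbind(seq_along(epi), pick)]
      while (length(frontier) > 0L) {
        forest$reporter[frontier] <- "INTEGRATED"
        frontier <- unlist(kids[as.character(forest$id[frontier])],
                           use.names = FALSE)
      }
    }
    forest
  })
}

#' Apply a BrdU pulse
#'
#' Marks `brdu = TRUE` every cell whose S-phase interval (the
#' `s_phase_hours` window ending at its division time) overlaps the pulse
#' availability interval, and propagates the label to all descendants
#' (dilution is not modeled).
#'
#' @param forest A lineage forest.
#' @param pulse A [brdu_pulse()].
#' @return The forest with updated `brdu` flags.
#' @export
pulse_brdu <- function(forest, pulse) {
  stopifnot(inherits(pulse, "brdu_pulse"))
  s_days <- pulse$s_phase_hours / 24
  hit <- !is.na(forest$division_time) &
    forest$division_time >= pulse$start &
    (forest$division_time - s_days) <=
      (pulse$end + pulse$availability_lag_days)
  forest$brdu[hit] <- TRUE
  kids <- children_index(forest)
  frontier <- which(hit)
  while (length(frontier) > 0L) {
    forest$brdu[frontier] <- TRUE
    frontier <- unlist(kids[as.character(forest$id[frontier])],
                       use.names = FALSE)
  }
  forest
}

#' Census the forest at an analysis time
#'
#' Counts live cells grouped by effective cell type, layer, reporter and
#' BrdU state at time `t`, after applying the requested filters. Migrating
#' neurons older than the maturation lag are counted as differentiating
#' neurons in the cortical plate.
#'
#' @param forest A lineage forest.
#' @param t Analysis time (embryonic days) inside the simulated span.
#' @param filters Named list restricting rows, e.g.
#'   `list(reporter = "INTEGRATED")`; valid names are `cell_type`, `layer`,
#'   `reporter`, `brdu`.
#' @return A data frame of class `"census_table"` with columns
#'   `analysis_time`, `cell_type`, `layer`, `reporter`, `brdu`, `count`.
#' @export
census_at <- function(forest, t, filters = list()) {
  span <- forest_span(forest)
  if (!is.numeric(t) || length(t) != 1L || t < span[1] || t > span[2])
    stop(sprintf("analysis time must lie within the simulated span [%s, %s]",
                 format_dev_time(span[1]), format_dev_time(span[2])))
  bad <- setdiff(names(filters), c("cell_type", "layer", "reporter", "brdu"))
  if (length(bad))
    stop("unknown census filter(s): ", paste(bad, collapse = ", "))
  sub <- forest[live_at(forest, t), , drop = FALSE]
  df <- data.frame(cell_type = type_at(sub, t), layer = layer_at(sub, t),
                   reporter = sub$reporter, brdu = sub$brdu,
                   stringsAsFactors = FALSE)
  for (nm in names(filters)) df <- df[df[[nm]] %in% filters[[nm]], , drop = FALSE]
  if (nrow(df) == 0L) {
    out <- data.frame(analysis_time = numeric(0), cell_type = character(0),
                      layer = character(0), reporter = character(0),
                      brdu = logical(0), count = integer(0))
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            by = df, FUN = sum)
    out <- data.frame(analysis_time = t, agg[c("cell_type", "layer",
                                               "reporter", "brdu")],
                      count = as.integer(agg$count))
    out <- out[order(out$cell_type, out$layer, out$reporter, out$brdu), ]
    rownames(out) <- NULL
  }
  attr(out, "analysis_time") <- t
  class(out) <- c("census_table", "data.frame")
  out
}

#' @export
print.lineage_forest <- function(x, ...) {
  span <- forest_span(x)
  cat(sprintf("Lineage forest: %d cells in %d clones, %s to %s (seed %s)\n",
              nrow(x), length(unique(x$clone_id)),
              format_dev_time(span[1]), format_dev_time(span[2]),
              attr(x, "seed") %||% "unset"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more cells)\n", sep = "")
  invisible(x)
}

#' @export
summary.lineage_forest <- function(object, t = forest_span(object)[2], ...) {
  census_at(object, t)
}
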
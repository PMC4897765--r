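## Synthetic-data generators: every input the pipeline consumes can be
## produced in closed loop with its ground truth attached.

#' Define a clonal labeling experiment design
#'
#' @param injection An [injection_spec()].
#' @param analysis_time Census time (embryonic days), after the injection.
#' @param n_sampled_cells Number of reporter-positive cells to sample from
#'   the census (mirroring the hundreds-to-thousands of cells counted per
#'   experimental group).
#' @param label Free-text tag.
#' @param brdu Optional [brdu_pulse()] administered during the survival.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(injection, analysis_time, n_sampled_cells = 1000,
                              label = "", brdu = NULL) {
  stopifnot(inherits(injection, "injection_spec"),
            analysis_time > injection$time, n_sampled_cells >= 1)
  if (!is.null(brdu)) stopifnot(inherits(brdu, "brdu_pulse"))
  structure(list(injection = injection, analysis_time = analysis_time,
                 n_sampled_cells = as.integer(n_sampled_cells),
                 label = label, brdu = brdu),
            class = "experiment_design")
}

#' The catalogue of study labeling designs
#'
#' Returns the fixed library of clonal labeling experiments emulated by the
#' simulator: ventricular injections across development with 2-day survival
#' (the short-survival division-mode series), ventricular injections with
#' 7-8 day survival (long enough for newborn bRGCs to reach the OSVZ), local
#' ISVZ and OSVZ injections at P1 followed to P3/P6/P14 (lineage
#' independence of the postnatal OSVZ), and the E34 injection with a BrdU
#' pulse at E36.0-E36.5 analysed at E38 (direct-versus-indirect OSVZ
#' seeding). Sampled-cell counts mirror the reported group sizes.
#'
#' @param n_infected Founding infections per experiment (default 100).
#' @return A named list of [experiment_design()] objects.
#' @export
paper_design_library <- function(n_infected = 100) {
  vent <- function(t, n = n_infected) injection_spec("VENTRICLE", t, n)
  p <- to_embryonic_day
  designs <- list(
    ## short-survival ventricular series (division-mode tracing)
    short_E30 = experiment_design(vent(30), 32, 170, "VZ E30 +2d"),
    short_E32 = experiment_design(vent(32), 34, 304, "VZ E32 +2d"),
    short_E34 = experiment_design(vent(34), 36, 931, "VZ E34 +2d"),
    short_E36 = experiment_design(vent(36), 38, 104, "VZ E36 +2d"),
    short_P1 = experiment_design(vent(p(1)), p(3), 1094, "VZ P1 +2d"),
    ## long-survival ventricular series (OSVZ seeding window)
    long_E34 = experiment_design(vent(34), p(0), 513, "VZ E34 -> P0"),
    long_E36 = experiment_design(vent(36), p(1), 958, "VZ E36 -> P1"),
    long_E38 = experiment_design(vent(38), p(3), 906, "VZ E38 -> P3"),
    long_P1 = experiment_design(vent(p(1)), p(10), 1499, "VZ P1 -> P10"),
    ## local postnatal injections (OSVZ lineage independence)
    isvz_P1_P3 = experiment_design(injection_spec("ISVZ_LOCAL", p(1), n_infected),
                                   p(3), 1000, "ISVZ P1 -> P3"),
    isvz_P1_P6 = experiment_design(injection_spec("ISVZ_LOCAL", p(1), n_infected),
                                   p(6), 1000, "ISVZ P1 -> P6"),
    isvz_P1_P14 = experiment_design(injection_spec("ISVZ_LOCAL", p(1), n_infected),
                                    p(14), 1000, "ISVZ P1 -> P14"),
    osvz_P1_P3 = experiment_design(injection_spec("OSVZ_LOCAL", p(1), n_infected),
                                   p(3), 420, "OSVZ P1 -> P3"),
    osvz_P1_P6 = experiment_design(injection_spec("OSVZ_LOCAL", p(1), n_infected),
                                   p(6), 1288, "OSVZ P1 -> P6"),
    osvz_P1_P14 = experiment_design(injection_spec("OSVZ_LOCAL", p(1), n_infected),
                                    p(14), 819, "OSVZ P1 -> P14"),
    ## BrdU cohort design: label cells cycling E36-E37 (S-phase ~12 h)
    brdu_E34_E38 = experiment_design(vent(34), 38, 229, "VZ E34 + BrdU E36-E36.5 -> E38",
                                     brdu = brdu_pulse(36, 36.5))
  )
  designs
}

#' Default simulation configuration for a labeling design
#'
#' Builds a [sim_config()] whose span covers the design: the population is
#' seeded with apical RGC founders at E30 (or at the injection time, if
#' earlier) so that germinal layers are populated before local injections,
#' and simulated until the analysis time.
#'
#' @param design An [experiment_design()].
#' @param seed Integer seed.
#' @param founders Number of founding apical RGCs. Defaults to the design's
#'   infection count for ventricular injections (the founders are exactly
#'   the transducible apical pool) and to 50 for local injections, whose
#'   target layers must first be populated from an E30 VZ.
#' @return A [sim_config()].
#' @export
design_sim_config <- function(design, seed, founders = NULL) {
  ventricular <- design$injection$site == "VENTRICLE"
  t0 <- if (ventricular) design$injection$time else
    min(30, design$injection$time)
  if (is.null(founders))
    founders <- if (ventricular) design$injection$n_infected else 50
  sim_config(founders = founders, t0 = t0, t_end = design$analysis_time,
             seed = seed)
}

#' Simulate a labeling experiment and sample its census
#'
#' Runs the branching-process simulation, applies the design's injection,
#' reporter segregation and optional BrdU pulse, censuses integrated-reporter
#' cells at the analysis time and samples `n_sampled_cells` of them without
#' replacement (hypergeometric sampling; the full census is returned with a
#' warning when it is smaller than the requested sample). Deterministic
#' given `seed`.
#'
#' @param design An [experiment_design()].
#' @param config A [sim_config()]; defaults to [design_sim_config()].
#' @param seed Integer seed driving simulation, labeling and sampling.
#' @return A `census_table` of sampled reporter-positive cells; the full
#'   (unsampled) census and the design are attached as attributes `"truth"`
#'   and `"design"`.
#' @export
generate_labeling_dataset <- function(design, config = NULL, seed = 1) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(config)) config <- design_sim_config(design, derive_seed(seed, 1))
  forest <- run_simulation(config)
  forest <- infect(forest, design$injection, seed = derive_seed(seed, 2))
  forest <- segregate_reporter(forest, seed = derive_seed(seed, 3))
  if (!is.null(design$brdu)) forest <- pulse_brdu(forest, design$brdu)
  full <- census_at(forest, design$analysis_time,
                    filters = list(reporter = "INTEGRATED"))
  total <- sum(full$count)
  if (total == 0L)
    stop("no integrated-reporter cells at the analysis time; ",
         "increase founders or infections")
  n <- design$n_sampled_cells
  if (n >= total) {
    if (n > total)
      warning(sprintf("requested %d sampled cells but only %d labeled cells exist; returning the full census",
                      n, total))
    out <- full
  } else {
    idx <- rep(seq_len(nrow(full)), full$count)
    keep <- with_seed(derive_seed(seed, 4), idx[sample.int(length(idx), n)])
    cnt <- tabulate(keep, nbins = nrow(full))
    out <- full[cnt > 0L, , drop = FALSE]
    out$count <- cnt[cnt > 0L]
    rownames(out) <- NULL
    attr(out, "analysis_time") <- attr(full, "analysis_time")
    class(out) <- class(full)
  }
  attr(out, "truth") <- full
  attr(out, "design") <- design
  out
}

#' Draw a synthetic cleavage-angle sample
#'
#' Draws each mitosis' cleavage class from `class_fractions` and then an
#' angle uniformly within the class band (under the stated convention).
#'
#' @param class_fractions Numeric length-3 vector of
#'   horizontal/oblique/vertical fractions summing to 1 (named or in
#'   `CLEAVAGE_CLASSES` order).
#' @param n Sample size (>= 1).
#' @param convention Angle convention of the generated measurements.
#' @param seed Optional integer seed.
#' @return A data frame with columns `angle_deg`, `convention` and the true
#'   class per mitosis in `class_true`.
#' @export
generate_angle_sample <- function(class_fractions, n, convention = "SURFACE",
                                  seed = NULL) {
  if (length(class_fractions) != 3L || any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-9)
    stop("`class_fractions` must be three non-negative fractions summing to 1")
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  convention <- check_convention(convention)
  ## class bands under the SURFACE convention; complemented for RADIAL_FIBER
  lo_s <- c(HORIZONTAL = 0, OBLIQUE = 30, VERTICAL = 60)
  hi_s <- c(HORIZONTAL = 30, OBLIQUE = 60, VERTICAL = 90)
  with_seed(seed, {
    cls <- CLEAVAGE_CLASSES[sample.int(3L, n, replace = TRUE,
                                       prob = class_fractions)]
    a_surface <- stats::runif(n, lo_s[cls], hi_s[cls])
    ang <- if (convention == "SURFACE") a_surface else 90 - a_surface
    data.frame(angle_deg = ang, convention = convention, class_true = cls,
               stringsAsFactors = FALSE)
  })
}

#' Plant a ground-truth set of temporal expression profiles
#'
#' Builds per-gene true stage means (log2 scale) realising the requested
#' profile labels: an `effect` of `e` log2 units gives a `2^e`-fold change
#' in each affected contrast (the default `e = 2`, i.e. 4-fold, exceeds the
#' screen's 2-fold threshold).
#'
#' @param n_per_profile Named integer vector of gene counts per profile
#'   label (names among `PROFILE_LABELS` except `MONOTONE_DISCARDED`, plus
#'   optionally `MONOTONE_UP`/`MONOTONE_DOWN` for genes changing in the same
#'   direction twice).
#' @param effect Log2 effect size per affected contrast (default 2).
#' @param base_mean Baseline log2 intensity (default 8).
#' @return A data frame of class `"expression_truth"`: `gene`, `profile`,
#'   `mean_stage1..3`.
#' @export
planted_expression_truth <- function(n_per_profile = c(PEAK = 10, LATE_UP = 10,
                                                       FLAT = 80),
                                     effect = 2, base_mean = 8) {
  shapes <- list(
    FLAT = c(0, 0, 0),
    PEAK = c(0, 1, 0), TROUGH = c(0, -1, 0),
    EARLY_UP = c(0, 1, 1), EARLY_DOWN = c(0, -1, -1),
    LATE_UP = c(0, 0, 1), LATE_DOWN = c(0, 0, -1),
    MONOTONE_UP = c(0, 1, 2), MONOTONE_DOWN = c(0, -1, -2))
  bad <- setdiff(names(n_per_profile), names(shapes))
  if (length(bad)) stop("unknown profile(s): ", paste(bad, collapse = ", "))
  rows <- do.call(rbind, lapply(names(n_per_profile), function(pr) {
    k <- n_per_profile[[pr]]
    if (k == 0L) return(NULL)
    m <- base_mean + effect * matrix(shapes[[pr]], k, 3, byrow = TRUE)
    data.frame(profile = pr, mean_stage1 = m[, 1], mean_stage2 = m[, 2],
               mean_stage3 = m[, 3], stringsAsFactors = FALSE)
  }))
  rows <- cbind(gene = sprintf("gene_%04d", seq_len(nrow(rows))), rows)
  structure(rows, class = c("expression_truth", "data.frame"))
}

#' Generate a three-stage expression matrix with planted profiles
#'
#' Log2 intensities are the true stage means plus i.i.d. Gaussian noise.
#'
#' @param truth A [planted_expression_truth()] data frame.
#' @param sigma Noise standard deviation, log2 units (default 0.25).
#' @param replicates Replicates per stage (default 3, as in the arrays'
#'   two-to-three biological replicas).
#' @param stages Stage labels in temporal order.
#' @param seed Optional integer seed.
#' @return An [expression_dataset()] with the truth attached as attribute
#'   `"truth"`.
#' @export
generate_expression_dataset <- function(truth, sigma = 0.25, replicates = 3,
                                        stages = c("E30", "E34", "P1"),
                                        seed = NULL) {
  stopifnot(inherits(truth, "expression_truth") || is.data.frame(truth),
            sigma >= 0, replicates >= 2, length(stages) == 3L)
  mu <- as.matrix(truth[, c("mean_stage1", "mean_stage2", "mean_stage3")])
  with_seed(seed, {
    cols <- rep(seq_len(3L), each = replicates)
    x <- mu[, cols, drop = FALSE] +
      matrix(stats::rnorm(nrow(mu) * length(cols), sd = sigma),
             nrow(mu), length(cols))
    rownames(x) <- truth$gene
    colnames(x) <- paste0(stages[cols], "_r", rep(seq_len(replicates), 3L))
    ds <- expression_dataset(x, factor(stages[cols], levels = stages))
    attr(ds, "truth") <- truth
    ds
  })
}

#' Generate a triplicate qPCR Ct table with known fold changes
#'
#' @param log2_fc Named numeric vector of true log2 fold changes
#'   (condition vs baseline) per target gene.
#' @param condition,baseline_condition Condition names.
#' @param reference_gene Housekeeping gene held constant (default
#'   `"actin"`).
#' @param base_ct Baseline target Ct (default 24) and reference Ct
#'   (default 18).
#' @param sd Replicate noise on Ct values (default 0: exact triplicates).
#' @param seed Optional integer seed.
#' @return A [ct_table()] with attribute `"truth"` holding `log2_fc`.
#' @export
generate_ct_table <- function(log2_fc, condition = "E34",
                              baseline_condition = "E30",
                              reference_gene = "actin",
                              base_ct = c(target = 24, reference = 18),
                              sd = 0, seed = NULL) {
  stopifnot(is.numeric(log2_fc), !is.null(names(log2_fc)))
  with_seed(seed, {
    one_gene <- function(g, ct_base, ct_cond) {
      data.frame(gene = g,
                 condition = rep(c(baseline_condition, condition), each = 3L),
                 replicate = rep(1:3, 2L),
                 ct = rep(c(ct_base, ct_cond), each = 3L) +
                   stats::rnorm(6L, sd = sd),
                 stringsAsFactors = FALSE)
    }
    rows <- lapply(names(log2_fc), function(g)
      ## a gain of one Ct cycle means half the transcript: Ct = base - log2(FC)
      one_gene(g, base_ct[["target"]], base_ct[["target"]] - log2_fc[[g]]))
    rows <- c(rows, list(one_gene(reference_gene, base_ct[["reference"]],
                                  base_ct[["reference"]])))
    out <- ct_table(do.call(rbind, rows))
    attr(out, "truth") <- log2_fc
    out
  })
}
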
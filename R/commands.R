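## File-level pipeline commands: each reads declared inputs, writes its
## outputs plus a JSON run manifest sufficient to re-run bit-identically.

usage_error <- function(...) {
  stop(structure(class = c("osvz_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

data_error <- function(...) {
  stop(structure(class = c("osvz_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

write_manifest <- function(out_dir, command, params, inputs, outputs) {
  manifest <- list(
    command = command,
    package = "osvzlineage",
    version = as.character(utils::packageVersion("osvzlineage")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(outputs)))
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_from_yaml <- function(cfg) {
  if (is.null(cfg$seed)) usage_error("config must specify an explicit integer `seed`")
  for (key in c("t0", "t_end", "founders"))
    if (is.null(cfg[[key]])) usage_error("config is missing field `", key, "`")
  founders <- cfg$founders
  if (is.list(founders)) {
    ## "count" rather than "n": bare `n` is a YAML 1.1 boolean
    count <- founders$count %||% founders[["n"]] %||% 1
    founders <- data.frame(type = rep(founders$type %||% "ARGC", count),
                           layer = rep(founders$layer %||% "VZ", count))
  }
  mig <- if (is.null(cfg$migration)) migration_rules() else
    do.call(migration_rules, cfg$migration)
  trk <- if (is.null(cfg$gene_track)) gene_level_track() else
    do.call(gene_level_track, cfg$gene_track)
  sim_config(founders = founders, t0 = cfg$t0, t_end = cfg$t_end,
             seed = cfg$seed, migration = mig, gene_track = trk,
             neuron_maturation_days = cfg$neuron_maturation_days %||% 4)
}

#' Run a configured simulation from a YAML file
#'
#' Reads a YAML configuration (required fields: `seed`, `t0`, `t_end`,
#' `founders`, e.g. `founders: {count: 20, type: ARGC, layer: VZ}`;
#' optional: `injection`, `analysis_times`, `migration`, `gene_track`,
#' `neuron_maturation_days`), runs the simulation, applies
#' the injection and reporter segregation if configured, and writes the
#' forest TSV, one census TSV per analysis time, and a run manifest to
#' `out_dir`.
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of output paths.
#' @export
cmd_simulate <- function(config_path, out_dir) {
  if (!file.exists(config_path)) usage_error("config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  config <- config_from_yaml(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  forest <- run_simulation(config)
  if (!is.null(cfg$injection)) {
    spec <- do.call(injection_spec, cfg$injection)
    forest <- infect(forest, spec, seed = derive_seed(config$seed, 2))
    forest <- segregate_reporter(forest, seed = derive_seed(config$seed, 3))
  }
  paths <- c(forest = file.path(out_dir, "forest.tsv"))
  write_forest_tsv(forest, paths[["forest"]])
  times <- cfg$analysis_times %||% config$t_end
  for (t in times) {
    p <- file.path(out_dir, sprintf("census_%s.tsv", format_dev_time(t)))
    write_census_tsv(census_at(forest, t), p)
    paths[paste0("census_", format_dev_time(t))] <- p
  }
  write_manifest(out_dir, "simulate",
                 params = cfg, inputs = config_path, outputs = unname(paths))
  invisible(paths)
}

#' Infer division modes and delamination predictions from files
#'
#' Reads a reporter-positive census TSV and optionally a cleavage-angle TSV,
#' classifies the population fate regime of the mother progenitor type,
#' inverts the labeled fraction into the feasible division-mode family,
#' summarises the angle sample and writes a results TSV plus a
#' human-readable report.
#'
#' @param census_path Census TSV ([write_census_tsv()] schema).
#' @param out_dir Output directory.
#' @param angles_path Optional angle-sample TSV.
#' @param mother_type Progenitor type of the originally infected mothers
#'   (default `"ARGC"`).
#' @param alpha Significance level (default 0.05).
#' @return Invisibly, the named vector of output paths.
#' @export
cmd_infer <- function(census_path, out_dir, angles_path = NULL,
                      mother_type = "ARGC", alpha = 0.05) {
  census <- read_census_tsv(census_path)
  if (nrow(census) == 0L || sum(census$count) == 0L)
    data_error("census is empty: nothing to infer from")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- census_type_counts(census)
  k <- if (mother_type %in% names(counts)) counts[[mother_type]] else 0L
  n <- sum(counts)
  fate <- classify_population_fate(k, n, alpha = alpha)
  fam <- feasible_mode_fractions(k / n)

  res <- data.frame(
    quantity = c("labeled_mother_fraction", "classification", "p_value",
                 "ci_lower", "ci_upper", "q_max_feasible"),
    value = c(format(k / n), fate$classification, format(fate$p_value),
              format(fate$conf_int[1]), format(fate$conf_int[2]),
              format(if (inherits(fam, "mode_fraction_family"))
                fam$q_range[2] else fam$q)))
  paths <- c(results = file.path(out_dir, "inference_results.tsv"),
             report = file.path(out_dir, "inference_report.txt"))
  inputs <- census_path

  report <- c(utils::capture.output(summary(fate)),
              utils::capture.output(print(fam)),
              sprintf("alpha = %g; mother type = %s; n = %d labeled cells",
                      alpha, mother_type, n),
              paste("note: the RENEWAL (50%) category is assigned by a",
                    "two-sided exact binomial test, an extension of the",
                    "point-threshold rule"))
  if (!is.null(angles_path)) {
    ang <- read_angles_tsv(angles_path)
    if (length(unique(ang$convention)) != 1L)
      data_error("angle sample mixes conventions; split by `convention` first")
    s <- angle_summary(ang$angle_deg, ang$convention[1])
    report <- c(report, utils::capture.output(print(s)))
    res <- rbind(res, data.frame(
      quantity = c("f_nonvertical", "d_pred"),
      value = c(format(s$f_nonvertical), format(s$d_pred))))
    inputs <- c(inputs, angles_path)
  }
  write_tsv(res, paths[["results"]])
  writeLines(report, paths[["report"]])
  write_manifest(out_dir, "infer",
                 params = list(census = census_path, angles = angles_path,
                               mother_type = mother_type, alpha = alpha),
                 inputs = inputs, outputs = unname(paths))
  invisible(paths)
}

#' Run the expression profile screen from files
#'
#' Reads a genes x samples TSV and a sample sheet (`sample`, `stage`,
#' `replicate`), runs [profile_screen()] and writes the per-gene results
#' TSV.
#'
#' @param matrix_path Expression matrix TSV (first column = gene id).
#' @param samples_path Sample sheet TSV.
#' @param out_dir Output directory.
#' @param n_perm,fc_thresh,fdr_thresh,adjust,seed Passed to
#'   [profile_screen()]; `seed` is required for reproducibility.
#' @return Invisibly, the named vector of output paths.
#' @export
cmd_profile <- function(matrix_path, samples_path, out_dir, seed,
                        n_perm = 500, fc_thresh = 2, fdr_thresh = 0.05,
                        adjust = "bonferroni") {
  if (missing(seed) || is.null(seed))
    usage_error("an explicit integer `seed` is required")
  mat <- read_tsv_checked(matrix_path, character(0), "expression matrix")
  if (ncol(mat) < 2L || nrow(mat) == 0L)
    data_error("expression matrix is empty or has no sample columns")
  sheet <- read_tsv_checked(samples_path, c("sample", "stage"), "sample sheet")
  x <- as.matrix(mat[, -1L, drop = FALSE])
  rownames(x) <- mat[[1L]]
  miss <- setdiff(colnames(x), sheet$sample)
  if (length(miss))
    data_error("sample sheet is missing sample(s): ", paste(miss, collapse = ", "))
  stages <- sheet$stage[match(colnames(x), sheet$sample)]
  ds <- expression_dataset(x, factor(stages, levels = unique(sheet$stage)))
  scr <- profile_screen(ds, n_perm = n_perm, fc_thresh = fc_thresh,
                        fdr_thresh = fdr_thresh, adjust = adjust, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(out_dir, "profile_results.tsv"))
  write_tsv(as.data.frame(scr), paths[["results"]])
  write_manifest(out_dir, "profile",
                 params = list(matrix = matrix_path, samples = samples_path,
                               seed = seed, n_perm = n_perm,
                               fc_thresh = fc_thresh, fdr_thresh = fdr_thresh,
                               adjust = adjust),
                 inputs = c(matrix_path, samples_path),
                 outputs = unname(paths))
  invisible(paths)
}

#' Materialise a small synthetic test corpus
#'
#' Writes a complete, seeded set of pipeline inputs to `out_dir`: a sampled
#' labeling census with angle sample, an expression matrix with its sample
#' sheet and planted truth, and a triplicate Ct table.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the named vector of output paths.
#' @export
cmd_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- experiment_design(injection_spec("VENTRICLE", 34, 300),
                              analysis_time = 36, n_sampled_cells = 400,
                              label = "fixture: VZ E34 +2d")
  census <- generate_labeling_dataset(design, seed = seed)
  angles <- generate_angle_sample(c(0.25, 0.25, 0.5), n = 200,
                                  seed = derive_seed(seed, 10))
  truth <- planted_expression_truth(c(PEAK = 5, LATE_UP = 5, FLAT = 40))
  ds <- generate_expression_dataset(truth, sigma = 0.25,
                                    seed = derive_seed(seed, 11))
  ct <- generate_ct_table(c(Cdh1 = -1.32, Trnp1 = 1), seed = derive_seed(seed, 12))

  paths <- c(census = file.path(out_dir, "census.tsv"),
             angles = file.path(out_dir, "angles.tsv"),
             matrix = file.path(out_dir, "expression_matrix.tsv"),
             samples = file.path(out_dir, "sample_sheet.tsv"),
             truth = file.path(out_dir, "expression_truth.tsv"),
             ct = file.path(out_dir, "ct_table.tsv"))
  write_census_tsv(census, paths[["census"]])
  write_angles_tsv(angles, paths[["angles"]])
  write_tsv(data.frame(gene = rownames(ds$values), ds$values,
                       check.names = FALSE), paths[["matrix"]])
  write_tsv(data.frame(sample = colnames(ds$values),
                       stage = as.character(ds$stages),
                       replicate = sub(".*_r", "", colnames(ds$values))),
            paths[["samples"]])
  write_tsv(truth, paths[["truth"]])
  write_tsv(as.data.frame(ct), paths[["ct"]])
  write_manifest(out_dir, "fixtures", params = list(seed = seed),
                 inputs = character(0), outputs = unname(paths))
  invisible(paths)
}
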
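#' osvzlineage: progenitor lineage dynamics of OSVZ formation
#'
#' Tools to simulate and analyse clonal lineage-tracing experiments in the
#' developing gyrencephalic cortex: a stochastic branching process of
#' progenitor divisions gated by Cdh1/Trnp1 expression levels, retroviral
#' single-daughter reporter segregation, division-mode inference from labeled
#' cell censuses, cleavage-plane angle statistics, and a three-stage
#' differential-expression profile screen.
#'
#' @keywords internal
"_PACKAGE"

## Closed taxonomies shared by all modules. Ages are real-valued embryonic
## days; ferret birth is E42, so postnatal day n maps to E(42 + n).

#' Cell types, layers and related closed enumerations
#'
#' @format Character vectors naming the closed enumerations used throughout:
#' cell types (`CELL_TYPES`), germinal/cortical layers (`LAYERS`), reporter
#' states (`REPORTER_STATES`), cleavage classes (`CLEAVAGE_CLASSES`) and
#' angle-measurement conventions (`ANGLE_CONVENTIONS`).
#'
#' `ARGC` is an apical radial glia cell (soma in VZ, apically attached, long
#' basal process); `BRGC` a basal radial glia cell (soma outside VZ, basal
#' process, no apical attachment); `IPC` the cycling Tbr2+ subset of
#' multipolar cells; `STAR_CELL` aggregates astrocyte/oligodendrocyte
#' lineages.
#' @name enumerations
NULL

#' @rdname enumerations
#' @export
CELL_TYPES <- c("ARGC", "BRGC", "IPC", "MIGRATING_NEURON", "DIFF_NEURON",
                "STAR_CELL")

#' @rdname enumerations
#' @export
LAYERS <- c("VZ", "ISVZ", "OSVZ", "IZ", "CP")

#' @rdname enumerations
#' @export
REPORTER_STATES <- c("NONE", "EPISOMAL", "INTEGRATED")

#' @rdname enumerations
#' @export
CLEAVAGE_CLASSES <- c("HORIZONTAL", "OBLIQUE", "VERTICAL")

#' @rdname enumerations
#' @export
ANGLE_CONVENTIONS <- c("SURFACE", "RADIAL_FIBER")

## Embryonic age of birth: E42 = P0.
BIRTH_E_DAY <- 42

#' Map a postnatal day to its embryonic-day equivalent
#'
#' Ferret birth occurs at E42 (P0), so postnatal day `n` corresponds to
#' embryonic day `42 + n`. The mapping is strictly increasing and invertible;
#' all package clocks run on real-valued embryonic days.
#'
#' @param postnatal_day Non-negative numeric vector of postnatal days.
#' @return Numeric vector of embryonic days.
#' @examples
#' to_embryonic_day(0) # E42, birth
#' to_embryonic_day(3) # E45
#' @export
to_embryonic_day <- function(postnatal_day) {
  if (!is.numeric(postnatal_day) || any(is.na(postnatal_day)))
    stop("`postnatal_day` must be numeric and non-missing")
  if (any(postnatal_day < 0))
    stop("`postnatal_day` must be >= 0 (use embryonic days directly for prenatal ages)")
  BIRTH_E_DAY + postnatal_day
}

#' Format an embryonic-day age as an E/P stage symbol
#'
#' @param e_day Numeric vector of embryonic days (>= 28).
#' @return Character vector such as `"E34"` or `"P1"`.
#' @export
format_dev_time <- function(e_day) {
  stopifnot(is.numeric(e_day))
  fmt1 <- function(t) {
    lab <- if (t >= BIRTH_E_DAY) paste0("P", t - BIRTH_E_DAY) else paste0("E", t)
    sub("\\.0$", "", sub("(\\.\\d)0+$", "\\1", lab))
  }
  vapply(e_day, fmt1, character(1))
}

check_angle <- function(angle) {
  if (!is.numeric(angle) || any(is.na(angle)))
    stop("cleavage angles must be numeric and non-missing")
  if (any(angle < 0 | angle > 90))
    stop("cleavage angles must lie in [0, 90] degrees")
  invisible(angle)
}

check_convention <- function(convention) {
  convention <- toupper(convention)
  if (length(convention) != 1L || !convention %in% ANGLE_CONVENTIONS)
    stop("`convention` must be one of ", paste(ANGLE_CONVENTIONS, collapse = ", "))
  convention
}

#' Classify a mitotic cleavage-plane angle
#'
#' Under the ventricular-surface convention, cleavage planes at \[0, 30)
#' degrees are horizontal, \[30, 60) oblique and \[60, 90\] vertical.
#' Measurements taken against the radial-fiber scaffold are the complement
#' (90 - angle) of surface measurements, so the radial-fiber rule is defined
#' by conversion and the two conventions agree exactly, including at the 30
#' and 60 degree boundaries (assigned to the upper class under the surface
#' convention).
#'
#' @param angle Numeric vector of angles in degrees, in \[0, 90\].
#' @param convention `"SURFACE"` (angle to the ventricular surface, default)
#'   or `"RADIAL_FIBER"` (angle to the radial-fiber scaffold).
#' @return Character vector of cleavage classes
#'   (`"HORIZONTAL"`, `"OBLIQUE"`, `"VERTICAL"`).
#' @examples
#' classify_cleavage(c(25, 45, 90), "SURFACE")
#' classify_cleavage(75, "RADIAL_FIBER") # horizontal
#' @export
classify_cleavage <- function(angle, convention = "SURFACE") {
  check_angle(angle)
  convention <- check_convention(convention)
  if (convention == "RADIAL_FIBER") angle <- 90 - angle
  ifelse(angle < 30, "HORIZONTAL", ifelse(angle < 60, "OBLIQUE", "VERTICAL"))
}

#' Convert an angle measurement between the two conventions
#'
#' Returns the complementary angle (90 - angle) expressed in the other
#' convention; `classify_cleavage()` is invariant under this conversion.
#'
#' @param angle Numeric vector of angles in \[0, 90\].
#' @param convention Convention the input angles were measured in.
#' @return A data frame with columns `angle` and `convention`.
#' @export
convert_angle <- function(angle, convention = "SURFACE") {
  check_angle(angle)
  convention <- check_convention(convention)
  other <- setdiff(ANGLE_CONVENTIONS, convention)
  data.frame(angle = 90 - angle, convention = other)
}

#' Summarise a sample of cleavage-plane angles
#'
#' Computes the horizontal/oblique/vertical class fractions, a binned
#' histogram, the non-vertical fraction and the predicted delaminating
#' daughter fraction (see [predicted_delamination_fraction()]).
#'
#' @param angles Numeric vector of angles in \[0, 90\] (single convention).
#' @param convention Convention the angles were measured in.
#' @param bin_width Histogram bin width in degrees (default 5).
#' @return An object of class `"angle_summary"`: a list with elements
#'   `n`, `convention`, `class_fractions`, `histogram` (data frame of
#'   `bin_start`, `bin_end`, `count`), `f_nonvertical` and `d_pred`.
#' @examples
#' s <- angle_summary(c(10, 20, 80, 85))
#' s$class_fractions
#' s$d_pred # 0.25
#' @export
angle_summary <- function(angles, convention = "SURFACE", bin_width = 5) {
  if (length(angles) < 1L) stop("angle sample is empty")
  check_angle(angles)
  convention <- check_convention(convention)
  if (!is.numeric(bin_width) || bin_width <= 0 || bin_width > 90)
    stop("`bin_width` must be in (0, 90]")
  cls <- factor(classify_cleavage(angles, convention), levels = CLEAVAGE_CLASSES)
  frac <- as.vector(table(cls)) / length(angles)
  names(frac) <- CLEAVAGE_CLASSES
  breaks <- unique(c(seq(0, 90, by = bin_width), 90))
  cut_idx <- findInterval(angles, breaks, rightmost.closed = TRUE)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1L)
  f_nv <- unname(frac["HORIZONTAL"] + frac["OBLIQUE"])
  structure(list(
    n = length(angles),
    convention = convention,
    class_fractions = frac,
    histogram = data.frame(bin_start = breaks[-length(breaks)],
                           bin_end = breaks[-1], count = counts),
    f_nonvertical = f_nv,
    d_pred = predicted_delamination_fraction(f_nv)
  ), class = "angle_summary")
}

#' @export
print.angle_summary <- function(x, ...) {
  cat("Cleavage-angle summary (", x$n, " mitoses, ", x$convention,
      " convention)\n", sep = "")
  cat(sprintf("  horizontal %.1f%%  oblique %.1f%%  vertical %.1f%%\n",
              100 * x$class_fractions["HORIZONTAL"],
              100 * x$class_fractions["OBLIQUE"],
              100 * x$class_fractions["VERTICAL"]))
  cat(sprintf("  non-vertical fraction %.3f -> predicted delaminating daughters %.3f\n",
              x$f_nonvertical, x$d_pred))
  invisible(x)
}

## Internal RNG helpers: evaluate `code` under `seed` without disturbing the
## caller's RNG stream; seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Stable derived seeds below 2^31 for pipeline sub-stages.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset * 1000003) %% 2147483646) + 1L
}
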
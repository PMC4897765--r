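## Division-mode inference from labeled-cell censuses: the single-daughter
## reporter-segregation model and its inversion, population fate
## classification, and the delamination arithmetic.

#' Division-mode mixture fractions
#'
#' The population-level mixture of apical progenitor division modes:
#' `p` symmetric self-amplifying (two progenitors like the mother),
#' `q` asymmetric (one progenitor like the mother plus one different cell),
#' `r` symmetric self-consuming (two cells different from the mother).
#'
#' @param p,q,r Fractions in \[0, 1\] summing to 1 (tolerance 1e-9).
#' @return An object of class `"mode_fractions"`.
#' @export
mode_fractions <- function(p, q, r) {
  v <- c(p = p, q = q, r = r)
  if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12))
    stop("mode fractions must lie in [0, 1]")
  if (abs(sum(v) - 1) > 1e-9)
    stop("mode fractions must sum to 1 (tolerance 1e-9)")
  structure(list(p = unname(min(max(p, 0), 1)),
                 q = unname(min(max(q, 0), 1)),
                 r = unname(min(max(r, 0), 1))),
            class = "mode_fractions")
}

as_mode_fractions <- function(m) {
  if (inherits(m, "mode_fractions")) return(m)
  if (is.numeric(m) && length(m) == 3L) return(mode_fractions(m[1], m[2], m[3]))
  stop("expected a mode_fractions object or a numeric (p, q, r) triple")
}

#' @export
print.mode_fractions <- function(x, ...) {
  cat(sprintf(
    "Division-mode fractions: p = %.4g (amplifying), q = %.4g (asymmetric), r = %.4g (self-consuming)\n",
    x$p, x$q, x$r))
  invisible(x)
}

#' Expected labeled mother-type fraction under single-daughter integration
#'
#' In a clonal labeling experiment the retroviral reporter integrates into
#' exactly one uniformly chosen daughter at the first division of each
#' infected progenitor. After one division round, a symmetric amplifying
#' division always presents a labeled cell of the mother type, an asymmetric
#' division does so half the time, and a self-consuming division never does;
#' so the expected fraction of reporter-positive cells of the mother type is
#' `p + q/2`.
#'
#' @param m A [mode_fractions()] object or numeric `c(p, q, r)`.
#' @return The expected labeled mother-type fraction, in \[0, 1\].
#' @examples
#' expected_labeled_mother_fraction(mode_fractions(1, 0, 0)) # 1.0
#' expected_labeled_mother_fraction(mode_fractions(0, 1, 0)) # 0.5
#' expected_labeled_mother_fraction(mode_fractions(0, 0, 1)) # 0.0
#' @export
expected_labeled_mother_fraction <- function(m) {
  m <- as_mode_fractions(m)
  m$p + m$q / 2
}

## Wilson score interval for a binomial proportion; well behaved at extreme
## fractions, reported alongside the exact interval.
wilson_interval <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Classify the population-level fate regime from a labeled census
#'
#' A reporter-positive census in which more than 50% of labeled cells are of
#' the mother progenitor type indicates self-amplification, 50% indicates
#' self-renewal and less than 50% consumption. Because an observed fraction
#' is a finite sample, the default method tests the observed count against
#' 0.5 with a two-sided exact binomial test and only departs from
#' `"RENEWAL"` when significant; the literal point-threshold rule is
#' available with `method = "threshold"`.
#'
#' @param k Number of reporter-positive cells of the mother type.
#' @param n Total reporter-positive cells (`0 <= k <= n`, `n >= 1`).
#' @param alpha Significance level for the exact test (default 0.05).
#' @param method `"binomial"` (default) or `"threshold"`.
#' @return An object of class `"fate_classification"` with elements
#'   `classification` (`"AMPLIFICATION"`, `"RENEWAL"` or `"CONSUMPTION"`),
#'   `fraction`, `p_value`, `conf_int` (exact, level `1 - alpha`),
#'   `wilson` (Wilson score interval), `k`, `n`, `alpha`, `method`.
#' @examples
#' classify_population_fate(24, 100) # consumption
#' classify_population_fate(52, 100) # renewal: interval spans 0.5
#' @export
classify_population_fate <- function(k, n, alpha = 0.05,
                                     method = c("binomial", "threshold")) {
  method <- match.arg(method)
  stopifnot(is.numeric(k), is.numeric(n), length(k) == 1L, length(n) == 1L,
            n >= 1, k >= 0, k <= n, alpha > 0, alpha < 1)
  bt <- stats::binom.test(k, n, p = 0.5, conf.level = 1 - alpha)
  frac <- k / n
  cls <- if (method == "threshold") {
    if (frac > 0.5) "AMPLIFICATION" else if (frac < 0.5) "CONSUMPTION" else "RENEWAL"
  } else {
    if (bt$p.value < alpha) {
      if (frac > 0.5) "AMPLIFICATION" else "CONSUMPTION"
    } else "RENEWAL"
  }
  structure(list(classification = cls, fraction = frac,
                 p_value = unname(bt$p.value),
                 conf_int = unname(as.numeric(bt$conf.int)),
                 wilson = wilson_interval(k, n, 1 - alpha),
                 k = as.integer(k), n = as.integer(n),
                 alpha = alpha, method = method),
            class = "fate_classification")
}

#' @export
print.fate_classification <- function(x, ...) {
  cat(sprintf("Population fate: %s\n", x$classification))
  cat(sprintf("  labeled mother-type fraction %d/%d = %.3f  (exact %.0f%% CI %.3f-%.3f)\n",
              x$k, x$n, x$fraction, 100 * (1 - x$alpha),
              x$conf_int[1], x$conf_int[2]))
  if (x$method == "binomial") {
    cat(sprintf("  exact binomial test vs 0.5: p = %.4g (alpha = %g)\n",
                x$p_value, x$alpha))
  } else {
    cat("  literal point-threshold rule (>50% / 50% / <50%); note a fraction\n",
        "  of exactly 0.5 is a measure-zero event in finite samples\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.fate_classification <- function(object, ...) {
  print(object)
  cat(sprintf("  Wilson %.0f%% interval for the fraction: %.3f-%.3f\n",
              100 * (1 - object$alpha), object$wilson[1], object$wilson[2]))
  invisible(object)
}

#' Invert an observed labeled mother-type fraction into mode fractions
#'
#' The reporter-segregation model maps mode fractions to the labeled
#' mother-type fraction `L = p + q/2`, which with `p + q + r = 1` leaves a
#' one-parameter family of solutions: for each feasible asymmetric fraction
#' `q`, `p = L - q/2` and `r = 1 - L - q/2`. Without further information the
#' feasible family is returned (`q` ranges over `[0, min(2L, 2(1-L))]`);
#' supplying `q_known` selects the unique point. At the boundaries `L = 1`
#' and `L = 0` the family collapses to the unique points `(1, 0, 0)` and
#' `(0, 0, 1)`.
#'
#' @param l_obs Observed labeled mother-type fraction, in \[0, 1\].
#' @param q_known Optional known asymmetric-division fraction.
#' @param tol Numerical tolerance for simplex feasibility (default 1e-9).
#' @return A [mode_fractions()] point when determined, otherwise an object
#'   of class `"mode_fraction_family"` with elements `l_obs`, `q_range` and
#'   `at(q)` evaluating family members.
#' @examples
#' feasible_mode_fractions(0.75, q_known = 0.5) # (0.5, 0.5, 0)
#' feasible_mode_fractions(1.0)                 # unique: (1, 0, 0)
#' @export
feasible_mode_fractions <- function(l_obs, q_known = NULL, tol = 1e-9) {
  stopifnot(is.numeric(l_obs), length(l_obs) == 1L)
  if (l_obs < -tol || l_obs > 1 + tol)
    stop("`l_obs` must lie in [0, 1]")
  l_obs <- min(max(l_obs, 0), 1)
  if (!is.null(q_known)) {
    stopifnot(is.numeric(q_known), length(q_known) == 1L)
    p <- l_obs - q_known / 2
    r <- 1 - p - q_known
    if (q_known < -tol || q_known > 1 + tol || p < -tol || r < -tol)
      stop(sprintf(
        "infeasible: l_obs = %g with q = %g leaves (p, r) = (%g, %g) outside the simplex",
        l_obs, q_known, p, r))
    return(mode_fractions(min(max(p, 0), 1), min(max(q_known, 0), 1),
                          min(max(r, 0), 1)))
  }
  q_max <- min(2 * l_obs, 2 * (1 - l_obs))
  if (q_max < tol)
    return(mode_fractions(l_obs, 0, 1 - l_obs))
  structure(list(l_obs = l_obs, q_range = c(0, q_max),
                 at = function(q) feasible_mode_fractions(l_obs, q_known = q)),
            class = "mode_fraction_family")
}

#' @export
print.mode_fraction_family <- function(x, ...) {
  cat(sprintf(
    "Feasible division-mode family for labeled mother-type fraction L = %.4g:\n",
    x$l_obs))
  cat(sprintf("  p = L - q/2, r = 1 - L - q/2 for q in [%.4g, %.4g]\n",
              x$q_range[1], x$q_range[2]))
  cat("  (the census alone cannot identify which division kinds occurred)\n")
  invisible(x)
}

#' Predicted delaminating-daughter fraction from cleavage-plane statistics
#'
#' Each division with an oblique or horizontal (non-vertical) cleavage plane
#' is assumed to release exactly one of its two daughters from the apical
#' surface, and vertical divisions none; a non-vertical mitosis fraction `f`
#' therefore predicts that `f/2` of all daughter cells delaminate from the
#' VZ. A 50% non-vertical fraction explains delamination of only 25% of
#' daughters — far short of the observed output of basal cells, implying a
#' cleavage-independent delamination route.
#'
#' @param f_nonvertical Fraction of mitoses with oblique or horizontal
#'   cleavage planes, in \[0, 1\].
#' @return Predicted fraction of daughter cells delaminating.
#' @examples
#' predicted_delamination_fraction(0.5) # 0.25
#' @export
predicted_delamination_fraction <- function(f_nonvertical) {
  if (!is.numeric(f_nonvertical) || any(f_nonvertical < 0 | f_nonvertical > 1))
    stop("`f_nonvertical` must lie in [0, 1]")
  f_nonvertical / 2
}

census_type_counts <- function(x) {
  if (inherits(x, "census_table")) {
    counts <- tapply(x$count, x$cell_type, sum)
    stats::setNames(as.vector(counts), names(counts))
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else stop("expected a census_table or a named count vector")
}

#' Compare cell-type composition between two conditions
#'
#' Pearson chi-square test (no continuity correction) on the 2 x K
#' contingency table of cell-type counts from two censuses.
#'
#' @param table_a,table_b `census_table` objects or named count vectors over
#'   matching categories.
#' @return The `htest` result of [stats::chisq.test()].
#' @examples
#' compare_condition_counts(c(ARGC = 90, BRGC = 10), c(ARGC = 10, BRGC = 90))
#' @export
compare_condition_counts <- function(table_a, table_b) {
  a <- census_type_counts(table_a)
  b <- census_type_counts(table_b)
  cats <- union(names(a), names(b))
  m <- rbind(a = sapply(cats, function(k) if (k %in% names(a)) a[[k]] else 0),
             b = sapply(cats, function(k) if (k %in% names(b)) b[[k]] else 0))
  colnames(m) <- cats
  exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_counts <= 0))
    stop("zero expected count in category '",
         cats[which(colSums(exp_counts) <= 0)[1]],
         "'; merge sparse categories before testing")
  suppressWarnings(stats::chisq.test(m, correct = FALSE))
}
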
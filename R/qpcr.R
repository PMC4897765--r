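## Comparative-Ct (ddCt) qRT-PCR fold changes.

#' Validate a long-format Ct table
#'
#' @param ct Data frame with columns `gene`, `condition`, `replicate`, `ct`
#'   (cycle-threshold values, > 0). Triplicate replicates are expected; a
#'   warning is issued otherwise.
#' @return The validated data frame (invisibly classed `"ct_table"`).
#' @export
ct_table <- function(ct) {
  need <- c("gene", "condition", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(ct$ct) || any(is.na(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be positive numbers")
  reps <- table(ct$gene, ct$condition)
  if (any(reps[reps > 0] != 3L))
    warning("non-triplicate Ct replicates detected; means are used as-is")
  structure(as.data.frame(ct), class = c("ct_table", "data.frame"))
}

mean_ct <- function(ct, gene, condition) {
  v <- ct$ct[ct$gene == gene & ct$condition == condition]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Fold change by the comparative Ct method
#'
#' Computes `FC = 2^(-ddCt)` with
#' `ddCt = (Ct_target - Ct_reference)_condition -
#' (Ct_target - Ct_reference)_baseline`, using replicate-mean Ct values and
#' a reference housekeeping gene (actin by default).
#'
#' @param ct A [ct_table()] (or a data frame with its columns).
#' @param target_gene Gene of interest.
#' @param condition,baseline_condition Conditions compared (e.g. stages).
#' @param reference_gene Housekeeping reference (default `"actin"`).
#' @return The linear fold change of the target in `condition` relative to
#'   `baseline_condition`.
#' @examples
#' ct <- data.frame(gene = rep(c("Cdh1", "actin"), each = 6),
#'                  condition = rep(rep(c("E30", "E34"), each = 3), 2),
#'                  replicate = rep(1:3, 4),
#'                  ct = c(22, 22, 22, 23, 23, 23, 18, 18, 18, 18, 18, 18))
#' ddct_fold_change(ct, "Cdh1", "E34", "E30") # 0.5: one extra cycle, halved
#' @export
ddct_fold_change <- function(ct, target_gene, condition, baseline_condition,
                             reference_gene = "actin") {
  if (!inherits(ct, "ct_table")) ct <- ct_table(ct)
  if (!reference_gene %in% ct$gene)
    stop("reference gene '", reference_gene, "' not present in the Ct table")
  vals <- c(tc = mean_ct(ct, target_gene, condition),
            rc = mean_ct(ct, reference_gene, condition),
            tb = mean_ct(ct, target_gene, baseline_condition),
            rb = mean_ct(ct, reference_gene, baseline_condition))
  if (any(is.na(vals)))
    stop("missing Ct values for ",
         paste(names(vals)[is.na(vals)], collapse = ", "),
         " (target/reference x condition/baseline)")
  ddct <- (vals[["tc"]] - vals[["rc"]]) - (vals[["tb"]] - vals[["rb"]])
  2^(-ddct)
}
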
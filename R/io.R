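## Flat-file interfaces: TSV schemas for censuses, forests and angle
## samples, and Newick export of clone topologies.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read and write census tables as TSV
#'
#' Fixed header: `analysis_time`, `cell_type`, `layer`, `reporter`, `brdu`,
#' `count`.
#'
#' @param census A `census_table` ([census_at()]).
#' @param path File path.
#' @return `read_census_tsv()` returns a `census_table`.
#' @export
write_census_tsv <- function(census, path) {
  stopifnot(inherits(census, "census_table"))
  write_tsv(as.data.frame(census), path)
}

#' @rdname write_census_tsv
#' @export
read_census_tsv <- function(path) {
  df <- read_tsv_checked(path, c("analysis_time", "cell_type", "layer",
                                 "reporter", "brdu", "count"), "census")
  df$brdu <- as.logical(df$brdu)
  attr(df, "analysis_time") <- if (nrow(df)) df$analysis_time[1] else NA_real_
  class(df) <- c("census_table", "data.frame")
  df
}

#' Read and write lineage forests as flat TSV
#'
#' One row per cell; the minimal schema (`id`, `parent_id`, `type`, `layer`,
#' `birth_time`, `reporter`, `brdu`) is always present, and the full
#' division/migration record is round-tripped when available.
#'
#' @param forest A `lineage_forest`.
#' @param path File path.
#' @return `read_forest_tsv()` returns a `lineage_forest` data frame.
#' @export
write_forest_tsv <- function(forest, path) {
  df <- as.data.frame(forest)
  df$layer <- df$birth_layer
  front <- c("id", "parent_id", "type", "layer", "birth_time", "reporter", "brdu")
  df <- df[c(front, setdiff(names(df), front))]
  write_tsv(df, path)
}

#' @rdname write_forest_tsv
#' @export
read_forest_tsv <- function(path) {
  df <- read_tsv_checked(path, c("id", "parent_id", "type", "layer",
                                 "birth_time", "reporter", "brdu"), "forest")
  if (is.null(df$birth_layer)) df$birth_layer <- df$layer
  df$brdu <- as.logical(df$brdu)
  class(df) <- c("lineage_forest", "data.frame")
  df
}

#' Read and write cleavage-angle samples as TSV
#'
#' Columns: `angle_deg`, `convention`.
#'
#' @param angles Data frame with columns `angle_deg` and `convention`.
#' @param path File path.
#' @return `read_angles_tsv()` returns the validated data frame.
#' @export
write_angles_tsv <- function(angles, path) {
  stopifnot(all(c("angle_deg", "convention") %in% names(angles)))
  write_tsv(angles[intersect(c("angle_deg", "convention", "class_true"),
                             names(angles))], path)
}

#' @rdname write_angles_tsv
#' @export
read_angles_tsv <- function(path) {
  df <- read_tsv_checked(path, c("angle_deg", "convention"), "angle sample")
  check_angle(df$angle_deg)
  df
}

#' Export clone topologies as Newick trees
#'
#' Each clone's binary lineage tree is written in Newick format with branch
#' lengths equal to the cell's lifetime in days (birth to its own division,
#' or to the end of the simulated span for terminal cells) and cell ids as
#' tip/node labels. Single-cell clones are emitted as trivial one-leaf
#' trees.
#'
#' @param forest A `lineage_forest`.
#' @param clone_ids Clones to export (default: all).
#' @return A named character vector of Newick strings, one per clone.
#' @export
forest_newick <- function(forest, clone_ids = NULL) {
  t_end <- forest_span(forest)[2]
  if (is.null(clone_ids)) clone_ids <- sort(unique(forest$clone_id))
  out <- vapply(clone_ids, function(cl) {
    sub <- forest[forest$clone_id == cl, , drop = FALSE]
    len <- ifelse(is.na(sub$division_time), t_end, sub$division_time) -
      sub$birth_time
    if (nrow(sub) == 1L)
      return(sprintf("%d:%g;", sub$id, len))
    is_tip <- is.na(sub$division_time)
    ntip <- sum(is_tip)
    num <- integer(nrow(sub))
    num[is_tip] <- seq_len(ntip)
    root_row <- which(is.na(sub$parent_id) | !(sub$parent_id %in% sub$id))
    internal <- which(!is_tip)
    ## ape convention: root = ntip + 1, then remaining internal nodes
    ord <- c(root_row, setdiff(internal, root_row))
    num[ord] <- ntip + seq_along(ord)
    child <- which(sub$parent_id %in% sub$id)
    edge <- cbind(num[match(sub$parent_id[child], sub$id)], num[child])
    tr <- structure(list(edge = edge, edge.length = len[child],
                         tip.label = as.character(sub$id[is_tip]),
                         node.label = as.character(sub$id[ord]),
                         Nnode = length(internal)),
                    class = "phylo")
    ape::write.tree(tr)
  }, character(1))
  names(out) <- paste0("clone_", clone_ids)
  out
}
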
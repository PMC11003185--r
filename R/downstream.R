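# Downstream-analysis plumbing: majority-vote supercell annotation,
# pseudobulk matrices for differential expression, and cluster filtering
# and proportion tables for differential abundance. The statistics
# themselves (moderated t-tests, proportion models) are left to dedicated
# tools; these functions emit their input matrices.

#' Majority-vote annotation of supercells
#'
#' Each supercell is labelled with the cell type most abundantly
#' represented among its labelled members. Unlabelled members are ignored;
#' a supercell with no labelled member is labelled `"unassigned"`. Ties
#' are broken alphabetically.
#'
#' @param part partition `data.table` (`cell_id`, `supercell_id`)
#' @param labels cell annotation: named vector or `cell_id` + `cell_type`
#'   table; may be partial
#' @return named character vector, supercell id -> type
#' @export
annotate_majority <- function(part, labels) {
  labels <- .as_cell_map(labels, "cell_type")
  dt <- data.table::data.table(
    supercell_id = part$supercell_id,
    type = unname(labels[part$cell_id])
  )[!is.na(type)]
  maj <- dt[, {
    tab <- table(type)
    # max count, alphabetical tie-break (table() names are sorted)
    list(type = names(tab)[which.max(tab)])
  }, by = supercell_id]
  out <- setNames(maj$type, maj$supercell_id)
  all_sc <- unique(part$supercell_id)
  out <- c(out, setNames(
    rep("unassigned", length(setdiff(all_sc, names(out)))),
    setdiff(all_sc, names(out))
  ))
  out[all_sc]
}

#' Pseudobulk expression matrix per sample and cell type
#'
#' For each combination of sample and (annotated) cell type, the mean of
#' the selected markers over the contributing supercells. Intended as
#' input to differential expression tools run per cell type across
#' samples; the selected markers would typically be the cell state
#' markers. The mean is unweighted over supercells by default; set
#' `weight_by_size = TRUE` to weight each supercell by its member count.
#'
#' @param expr supercell expression table (from [aggregate_expression()])
#' @param annotation named vector, supercell id -> cell type
#' @param markers markers to include (non-empty)
#' @param weight_by_size weight supercells by `n_cells`
#' @return `data.table` with columns `sample_id`, `cell_type`,
#'   `n_supercells`, then one column per marker
#' @export
pseudobulk <- function(expr, annotation, markers, weight_by_size = FALSE) {
  if (length(markers) == 0) {
    stop("parameter error: empty marker set", call. = FALSE)
  }
  unknown <- setdiff(markers, names(expr))
  if (length(unknown) > 0) {
    stop("parameter error: marker(s) not in expression: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  unannotated <- setdiff(expr$supercell_id, names(annotation))
  if (length(unannotated) > 0) {
    stop("consistency error: unannotated supercell(s): ",
      paste(head(unannotated, 5), collapse = ", "),
      call. = FALSE
    )
  }
  dt <- data.table::copy(expr)
  dt[, cell_type := unname(annotation[supercell_id])]
  agg <- if (weight_by_size) {
    dt[, c(
      list(n_supercells = .N),
      lapply(.SD, function(v) sum(v * n_cells) / sum(n_cells))
    ), by = .(sample_id, cell_type), .SDcols = markers]
  } else {
    dt[, c(list(n_supercells = .N), lapply(.SD, mean)),
      by = .(sample_id, cell_type), .SDcols = markers
    ]
  }
  data.table::setorder(agg, sample_id, cell_type)
  agg[]
}

#' Filter clusters by per-sample representation
#'
#' A cluster is retained only if it holds strictly more than
#' `min_per_sample` cells in every sample; a sample where the cluster is
#' absent counts as zero and fails the rule. Applied at the single-cell
#' level (after expanding supercell cluster labels to cells) ahead of
#' differential abundance testing.
#'
#' @param cell_table table with `sample_id` and `cluster_id` columns
#' @param min_per_sample strict lower bound on per-sample cells (default 3)
#' @return character vector of retained cluster ids (sorted)
#' @export
filter_clusters <- function(cell_table, min_per_sample = 3L) {
  dt <- data.table::as.data.table(cell_table)
  stopifnot(all(c("sample_id", "cluster_id") %in% names(dt)))
  counts <- data.table::CJ(
    cluster_id = unique(as.character(dt$cluster_id)),
    sample_id = unique(dt$sample_id)
  )
  obs <- dt[, .(n = .N), by = .(cluster_id = as.character(cluster_id), sample_id)]
  counts <- merge(counts, obs, by = c("cluster_id", "sample_id"), all.x = TRUE)
  counts[is.na(n), n := 0L]
  keep <- counts[, .(ok = all(n > min_per_sample)), by = cluster_id][ok == TRUE]
  sort(keep$cluster_id)
}

#' Per-sample cluster proportion table
#'
#' Fraction of each sample's cells falling in each cluster, computed at
#' the single-cell level (i.e. after expanding supercell labels back to
#' cells). Because supercells hold different numbers of cells, these
#' single-cell proportions are the recommended input to differential
#' abundance tests, not proportions of supercell counts.
#'
#' @param cell_table table with `sample_id` and `cluster_id` columns
#' @return `data.table`, rows = samples, columns = `sample_id` then one
#'   column per cluster; each row sums to 1
#' @export
cluster_proportions <- function(cell_table) {
  dt <- data.table::as.data.table(cell_table)
  stopifnot(all(c("sample_id", "cluster_id") %in% names(dt)))
  long <- dt[, .(n = .N), by = .(sample_id, cluster_id = as.character(cluster_id))]
  long[, prop := n / sum(n), by = sample_id]
  wide <- data.table::dcast(long, sample_id ~ cluster_id,
    value.var = "prop", fill = 0
  )
  data.table::setorder(wide, sample_id)
  wide[]
}
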
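#' Target number of supercells for a sample
#'
#' gamma is the ratio of cells to supercells, so a sample of `n` cells is
#' cut into `round(n / gamma)` supercells (half rounded up), clamped to the
#' feasible range: no fewer groups than graph components and no more than
#' cells.
#'
#' @param n number of cells in the sample
#' @param gamma granularity parameter (cells per supercell), >= 1
#' @param n_components connected components of the sample's kNN graph
#' @return integer target supercell count
#' @export
supercell_target_k <- function(n, gamma, n_components = 1L) {
  if (gamma < 1) stop("parameter error: gamma must be >= 1", call. = FALSE)
  k <- round_half_up(n / gamma)
  as.integer(min(max(k, n_components), n))
}

#' Build supercells for a single sample
#'
#' The full per-sample pipeline: PCA on the marker matrix (components
#' capped at the marker count), exact kNN graph on the PC scores, walktrap
#' merge dendrogram, and a cut at `round(n / gamma)` groups. The
#' dendrogram is returned alongside the partition so the sample can later
#' be re-cut at a different gamma without recomputing anything (see
#' [recut()]).
#'
#' For samples smaller than `knn_k + 1` cells the neighbour count is
#' reduced to `n - 1` so tiny samples still run.
#'
#' @param table_s expression table restricted to one sample
#' @param params a [core_params()] object
#' @param markers marker columns to use (default: the table's markers)
#' @return list with `partition` (cell to supercell `data.table`),
#'   `dendrogram` (a `supercell_dendrogram`) and `k` (supercell count)
#' @export
supercells_for_sample <- function(table_s, params = core_params(),
                                  markers = NULL) {
  stopifnot(inherits(params, "core_params"))
  markers <- markers %||% marker_names(table_s)
  sid <- unique(table_s$sample_id)
  if (length(sid) != 1) {
    stop("parameter error: supercells_for_sample expects exactly one sample, got ",
      length(sid),
      call. = FALSE
    )
  }
  n <- nrow(table_s)
  mm <- marker_matrix(table_s, markers)
  checksum <- table_checksum(table_s, markers)
  set.seed(params$seed)
  if (n == 1L) {
    dendro <- structure(
      list(
        version = 1L, sample_id = sid, n = 1L,
        cell_ids = table_s$cell_id, steps = params$walk_steps,
        params = params, checksum = checksum,
        components = list(list(
          vertices = 1L,
          merges = matrix(integer(0), 0, 2)
        ))
      ),
      class = "supercell_dendrogram"
    )
    return(list(partition = cut_to_k(dendro, 1L), dendrogram = dendro, k = 1L))
  }
  scores <- compute_pca(mm, n_pcs = params$n_pcs, scale. = params$scale_pca)
  k_nn <- min(params$knn_k, n - 1L)
  graph <- build_knn_graph(scores, k = k_nn)
  dendro <- walktrap_dendrogram(graph,
    steps = params$walk_steps,
    cell_ids = table_s$cell_id, sample_id = sid,
    params = params, checksum = checksum
  )
  k <- supercell_target_k(n, params$gamma, length(dendro$components))
  list(partition = cut_to_k(dendro, k), dendrogram = dendro, k = k)
}

#' Re-cut a stored dendrogram at a new gamma
#'
#' Produces the partition a fresh [supercells_for_sample()] run at
#' `new_gamma` would give on the same input and seed, but without
#' recomputing the PCA, the kNN graph or the walktrap merges.
#'
#' @param dendro a `supercell_dendrogram` (in memory or from
#'   [load_dendrogram()])
#' @param new_gamma the new granularity
#' @param table optional: the original expression table; when supplied, its
#'   checksum must match the one recorded in the dendrogram store
#' @return a partition `data.table` (`cell_id`, `sample_id`, `supercell_id`)
#' @export
recut <- function(dendro, new_gamma, table = NULL) {
  stopifnot(inherits(dendro, "supercell_dendrogram"))
  if (!is.null(table) && !is.null(dendro$checksum)) {
    chk <- table_checksum(table)
    if (!identical(chk, dendro$checksum)) {
      stop("integrity error: dendrogram store checksum (", dendro$checksum,
        ") does not match the supplied table (", chk,
        "); the store was built from different data",
        call. = FALSE
      )
    }
  }
  k <- supercell_target_k(dendro$n, new_gamma, length(dendro$components))
  cut_to_k(dendro, k)
}

#' Aggregate marker expression per supercell
#'
#' One output row per supercell: the mean (or median) of each marker over
#' the member cells, the member count `n_cells`, and the sample id. Rows
#' are ordered by sample, then by supercell index.
#'
#' @param table_s expression table (one sample or several)
#' @param part partition `data.table` covering every cell of `table_s`
#' @param aggregation `"mean"` or `"median"`
#' @param markers markers to aggregate (default: the table's markers)
#' @return a `data.table` with columns `supercell_id`, `sample_id`,
#'   `n_cells`, then one column per marker
#' @export
aggregate_expression <- function(table_s, part,
                                 aggregation = c("mean", "median"),
                                 markers = NULL) {
  aggregation <- match.arg(aggregation)
  markers <- markers %||% marker_names(table_s)
  missing_cells <- setdiff(table_s$cell_id, part$cell_id)
  if (length(missing_cells) > 0) {
    stop("consistency error: cell(s) missing from partition: ",
      paste(head(missing_cells, 5), collapse = ", "),
      call. = FALSE
    )
  }
  dt <- merge(
    table_s[, c("cell_id", markers), with = FALSE],
    part[, c("cell_id", "sample_id", "supercell_id"), with = FALSE],
    by = "cell_id", sort = FALSE
  )
  agg_fun <- if (aggregation == "mean") mean else stats::median
  out <- dt[, c(list(n_cells = .N), lapply(.SD, agg_fun)),
    by = .(supercell_id, sample_id), .SDcols = markers
  ]
  idx <- as.integer(sub(".*_SC_", "", out$supercell_id))
  out <- out[order(sample_id, idx)]
  data.table::setcolorder(out, c("supercell_id", "sample_id", "n_cells", markers))
  out[]
}
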
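# Multi-sample orchestration. Supercells are always created within a
# sample, never across samples, so per-sample computations are independent
# and can run concurrently. Results are a pure function of (table, params,
# seed): worker count and scheduling never change the output.

#' Plan the processing order of samples across workers
#'
#' Samples are ordered by descending cell count (ties by sample id) and
#' assigned greedily to the currently least-loaded worker — the classic
#' longest-processing-time heuristic. Workers handling large samples are
#' left alone while those with small samples pick up more.
#'
#' @param cell_counts named numeric vector or list, sample id -> cell count
#' @param n_workers number of parallel workers (>= 1)
#' @return object of class `run_plan`: list with `order` (sample ids,
#'   descending by count), `assignment` (list of sample-id vectors, one per
#'   worker) and `loads` (per-worker total cells)
#' @export
schedule_samples <- function(cell_counts, n_workers = 1L) {
  counts <- unlist(cell_counts)
  if (length(counts) == 0) {
    stop("parameter error: empty sample set", call. = FALSE)
  }
  if (any(counts <= 0)) {
    stop("parameter error: cell counts must be positive", call. = FALSE)
  }
  if (n_workers < 1) {
    stop("parameter error: n_workers must be >= 1", call. = FALSE)
  }
  ord <- names(counts)[order(-counts, names(counts))]
  assignment <- rep(list(character(0)), n_workers)
  loads <- numeric(n_workers)
  for (s in ord) {
    w <- which.min(loads) # first least-loaded worker
    assignment[[w]] <- c(assignment[[w]], s)
    loads[w] <- loads[w] + counts[[s]]
  }
  structure(
    list(order = ord, assignment = assignment, loads = loads,
      n_workers = as.integer(n_workers)
    ),
    class = "run_plan"
  )
}

#' Create supercells for every sample of a dataset
#'
#' Splits the table by sample, processes samples in descending cell-count
#' order (concurrently when `n_workers > 1`, via BiocParallel), and
#' combines the per-sample partitions and aggregated expression. Each
#' sample gets its own seed derived from the run seed and the sample id,
#' so results do not depend on which other samples are present, on the
#' worker count, or on scheduling.
#'
#' @param table an expression table with one or more samples
#' @param params a [core_params()] object (the run seed lives here)
#' @param n_workers number of concurrent workers
#' @param markers marker columns to use
#' @param out_dir optional output directory: the combined map and
#'   expression are written via [write_outputs()] and per-sample
#'   dendrogram stores under `<out_dir>/dendrograms/`
#' @return object of class `supercell_run`: list with `partition`,
#'   `expression`, `k_per_sample`, `plan`, and `store_paths` (when written)
#' @export
run_all_samples <- function(table, params = core_params(), n_workers = 1L,
                            markers = NULL, out_dir = NULL) {
  markers <- markers %||% marker_names(table)
  counts <- table[, .N, by = sample_id]
  if (any(counts$N < 1)) {
    stop("parameter error: every sample needs at least one cell", call. = FALSE)
  }
  plan <- schedule_samples(setNames(counts$N, counts$sample_id), n_workers)
  split_tables <- lapply(plan$order, function(s) {
    ts <- table[sample_id == s]
    data.table::setattr(ts, "markers", markers)
    ts
  })
  names(split_tables) <- plan$order
  bp <- if (n_workers > 1L) {
    BiocParallel::MulticoreParam(workers = n_workers)
  } else {
    BiocParallel::SerialParam()
  }
  results <- BiocParallel::bptry(BiocParallel::bplapply(
    plan$order,
    function(s, split_tables, params, markers) {
      ps <- params
      ps$seed <- derive_sample_seed(params$seed, s)
      cytosupercell::supercells_for_sample(split_tables[[s]], ps,
        markers = markers
      )
    },
    split_tables = split_tables, params = params, markers = markers,
    BPPARAM = bp
  ))
  failed <- vapply(results, inherits, logical(1), "error") |
    vapply(results, inherits, logical(1), "bperror")
  if (any(failed)) {
    stop("run aborted: sample(s) failed: ",
      paste(plan$order[failed], collapse = ", "), " — first error: ",
      conditionMessage(results[[which(failed)[1]]]),
      call. = FALSE
    )
  }
  names(results) <- plan$order
  partition <- data.table::rbindlist(lapply(results, `[[`, "partition"))
  expression <- data.table::rbindlist(lapply(plan$order, function(s) {
    aggregate_expression(split_tables[[s]], results[[s]]$partition,
      aggregation = params$aggregation, markers = markers
    )
  }))
  k_per_sample <- vapply(results, `[[`, integer(1), "k")
  store_paths <- NULL
  if (!is.null(out_dir)) {
    write_outputs(expression, partition, out_dir)
    store_paths <- vapply(plan$order, function(s) {
      save_dendrogram(results[[s]]$dendrogram, file.path(out_dir, "dendrograms"))
    }, character(1))
  }
  structure(
    list(
      partition = partition, expression = expression,
      k_per_sample = k_per_sample, plan = plan,
      dendrograms = lapply(results, `[[`, "dendrogram"),
      store_paths = store_paths, params = params
    ),
    class = "supercell_run"
  )
}

#' @export
print.supercell_run <- function(x, ...) {
  cat(sprintf(
    "supercell run: %d cells -> %d supercells across %d sample(s) (gamma = %g)\n",
    nrow(x$partition), nrow(x$expression), length(x$k_per_sample),
    x$params$gamma
  ))
  invisible(x)
}

#' Expand per-supercell values back to single cells
#'
#' Every member cell inherits its supercell's value (a cluster label, a
#' cell type, a score, ...). Expansion costs nothing beyond a lookup in
#' the cell-to-supercell map, which is why per-cell analyses such as
#' differential abundance are best run after expansion.
#'
#' @param part partition `data.table` (`cell_id`, `supercell_id`)
#' @param per_supercell_values named vector, supercell id -> value
#' @return named vector, cell id -> value, covering the cells of the
#'   supercells present in `per_supercell_values`
#' @export
expand_partition <- function(part, per_supercell_values) {
  unknown <- setdiff(names(per_supercell_values), part$supercell_id)
  if (length(unknown) > 0) {
    stop("consistency error: unknown supercell id(s): ",
      paste(head(unknown, 5), collapse = ", "),
      call. = FALSE
    )
  }
  keep <- part$supercell_id %in% names(per_supercell_values)
  setNames(
    unname(per_supercell_values[part$supercell_id[keep]]),
    part$cell_id[keep]
  )
}
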
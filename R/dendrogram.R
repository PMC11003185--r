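# Walktrap merge dendrograms and their cuts.
#
# Walktrap is run once per connected component of the kNN graph; each
# component contributes an ordered merge list (igraph convention: entries
# <= m are leaves of the component, entries > m refer to earlier merge
# rows). A cut at k groups allocates k across components by largest
# remainder, proportional to component size with a minimum of one group
# per component, then replays each component's merge list from the top.

#' Walktrap merge dendrogram of a kNN graph
#'
#' Runs walktrap community detection (short random walks of length
#' `steps`) on every connected component of `graph` and records the full
#' agglomeration as an ordered merge list per component. The dendrogram is
#' the reusable product of the expensive pipeline stages: it can be cut at
#' any number of groups, and re-cut later, without touching the graph or
#' the walktrap merges again.
#'
#' @param graph an undirected `igraph` graph (from [build_knn_graph()]);
#'   vertices are cells in row order
#' @param steps random-walk length (default 4)
#' @param cell_ids optional character vector of cell ids, one per vertex
#' @param sample_id optional sample identifier recorded in the dendrogram
#' @param params optional `core_params` recorded for provenance
#' @param checksum optional input checksum recorded for recut validation
#' @return object of class `supercell_dendrogram`
#' @export
walktrap_dendrogram <- function(graph, steps = 4L, cell_ids = NULL,
                                sample_id = NULL, params = NULL,
                                checksum = NULL) {
  n <- igraph::vcount(graph)
  if (n < 1) stop("parameter error: empty graph", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(n))
  stopifnot(length(cell_ids) == n)
  comp <- igraph::components(graph)
  components <- vector("list", comp$no)
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    m <- length(vids)
    if (m == 1L) {
      merges <- matrix(integer(0), nrow = 0, ncol = 2)
    } else {
      sub <- igraph::induced_subgraph(graph, vids)
      wt <- igraph::cluster_walktrap(sub,
        steps = steps,
        merges = TRUE, modularity = FALSE, membership = FALSE
      )
      merges <- wt$merges
      storage.mode(merges) <- "integer"
    }
    components[[ci]] <- list(vertices = as.integer(vids), merges = merges)
  }
  structure(
    list(
      version = 1L, sample_id = sample_id, n = as.integer(n),
      cell_ids = cell_ids, steps = as.integer(steps),
      params = params, checksum = checksum, components = components
    ),
    class = "supercell_dendrogram"
  )
}

#' @export
print.supercell_dendrogram <- function(x, ...) {
  cat(sprintf(
    "supercell dendrogram: %d cells, %d component(s), walk length %d%s\n",
    x$n, length(x$components), x$steps,
    if (is.null(x$sample_id)) "" else paste0(", sample ", x$sample_id)
  ))
  invisible(x)
}

# Membership of a component's m leaves after cutting its merge list at k
# groups (i.e. performing the first m - k merges). Group labels are 1..k
# ordered by smallest leaf index.
cut_merges <- function(merges, m, k) {
  if (m == 1L || k == m) {
    memb <- seq_len(m)
  } else {
    nused <- m - k
    labels <- integer(m + nused)
    used <- merges[seq_len(nused), , drop = FALSE]
    roots <- setdiff(seq_len(m + nused), as.vector(used))
    labels[roots] <- seq_along(roots)
    if (nused > 0) {
      for (j in nused:1) {
        labels[used[j, 1]] <- labels[m + j]
        labels[used[j, 2]] <- labels[m + j]
      }
    }
    memb <- labels[seq_len(m)]
  }
  # relabel stably by smallest member index
  first <- match(unique(memb), memb)
  rank <- match(memb, memb[sort(first)])
  rank
}

# Allocate k groups over components of the given sizes: largest-remainder
# apportionment proportional to size, bounded to [1, size] per component.
allocate_groups <- function(sizes, k) {
  c_n <- length(sizes)
  n <- sum(sizes)
  if (k < c_n) {
    warning(sprintf(
      "graph has %d components but %d groups requested; returning one group per component (%d groups)",
      c_n, k, c_n
    ), call. = FALSE)
    return(rep(1L, c_n))
  }
  if (k > n) stop("parameter error: k exceeds number of cells", call. = FALSE)
  quota <- k * sizes / n
  alloc <- pmin(sizes, pmax(1L, floor(quota)))
  frac <- quota - floor(quota)
  # hand out (or claw back) one group at a time; ties by component index
  while (sum(alloc) < k) {
    cand <- which(alloc < sizes)
    i <- cand[order(-frac[cand], cand)][1]
    alloc[i] <- alloc[i] + 1L
    frac[i] <- frac[i] - 1
  }
  while (sum(alloc) > k) {
    cand <- which(alloc > 1L)
    i <- cand[order(frac[cand], cand)][1]
    alloc[i] <- alloc[i] - 1L
    frac[i] <- frac[i] + 1
  }
  as.integer(alloc)
}

#' Cut a merge dendrogram into exactly k supercells
#'
#' Replays the stored merge lists from the top until exactly `k` groups
#' remain. With several connected components the `k` groups are divided
#' across components by largest remainder, proportional to component size,
#' at least one group each. Supercell ids are `<sample_id>_SC_<j>` with `j`
#' assigned in order of each group's smallest member cell index.
#'
#' @param dendro a `supercell_dendrogram`
#' @param k number of supercells; must lie in `[components, n]`
#' @return a partition `data.table` with columns `cell_id`, `sample_id`,
#'   `supercell_id`, one row per cell in input order
#' @export
cut_to_k <- function(dendro, k) {
  stopifnot(inherits(dendro, "supercell_dendrogram"))
  n <- dendro$n
  c_n <- length(dendro$components)
  k <- as.integer(k)
  if (k < c_n || k > n) {
    stop(sprintf(
      "parameter error: k = %d outside [%d, %d] (graph has %d component(s), %d cells)",
      k, c_n, n, c_n, n
    ), call. = FALSE)
  }
  sizes <- vapply(dendro$components, function(co) length(co$vertices), integer(1))
  alloc <- allocate_groups(sizes, k)
  group <- integer(n)
  offset <- 0L
  for (ci in seq_along(dendro$components)) {
    co <- dendro$components[[ci]]
    memb <- cut_merges(co$merges, sizes[ci], alloc[ci])
    group[co$vertices] <- memb + offset
    offset <- offset + max(memb)
  }
  # stable ids ordered by smallest member cell index across the sample
  ng <- offset
  first_idx <- integer(ng)
  first_idx[group[n:1]] <- n:1 # reverse pass leaves the minimum index
  new_of_old <- integer(ng)
  new_of_old[order(first_idx)] <- seq_len(ng)
  prefix <- if (is.null(dendro$sample_id)) "SC" else paste0(dendro$sample_id, "_SC")
  data.table::data.table(
    cell_id = dendro$cell_ids,
    sample_id = if (is.null(dendro$sample_id)) NA_character_ else dendro$sample_id,
    supercell_id = paste0(prefix, "_", new_of_old[group])
  )
}

#' Save a dendrogram store
#'
#' One self-describing JSON file per sample: format version, sample id,
#' cell count, walk length, parameters, input checksum, cell ids, and the
#' per-component merge lists as integer pairs.
#'
#' @param dendro a `supercell_dendrogram`
#' @param dir directory of the run's dendrogram store (created if needed)
#' @return the file path, invisibly
#' @export
save_dendrogram <- function(dendro, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sid <- if (is.null(dendro$sample_id)) "sample" else dendro$sample_id
  path <- file.path(dir, paste0("dendrogram_", gsub("[^A-Za-z0-9._-]", "_", sid), ".json"))
  obj <- list(
    format = "supercell_dendrogram", version = dendro$version,
    sample_id = dendro$sample_id, n = dendro$n, steps = dendro$steps,
    params = unclass(dendro$params), checksum = dendro$checksum,
    cell_ids = dendro$cell_ids,
    components = lapply(dendro$components, function(co) {
      list(vertices = co$vertices, merges = co$merges)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dendrogram store file
#'
#' @param path JSON file written by [save_dendrogram()]
#' @return a `supercell_dendrogram`
#' @export
load_dendrogram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "supercell_dendrogram")) {
    stop("parse error: not a dendrogram store file: ", path, call. = FALSE)
  }
  comps <- obj$components
  if (is.data.frame(comps)) {
    comps <- lapply(seq_len(nrow(comps)), function(i) {
      list(vertices = comps$vertices[[i]], merges = comps$merges[[i]])
    })
  }
  components <- lapply(comps, function(co) {
    mg <- co$merges
    if (is.null(mg) || length(mg) == 0) {
      mg <- matrix(integer(0), 0, 2)
    } else {
      mg <- matrix(as.integer(mg), ncol = 2)
    }
    list(vertices = as.integer(co$vertices), merges = mg)
  })
  params <- obj$params
  if (!is.null(params)) class(params) <- "core_params"
  structure(
    list(
      version = as.integer(obj$version), sample_id = obj$sample_id,
      n = as.integer(obj$n), cell_ids = as.character(obj$cell_ids),
      steps = as.integer(obj$steps), params = params,
      checksum = obj$checksum, components = components
    ),
    class = "supercell_dendrogram"
  )
}
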
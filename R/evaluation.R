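# Quality metrics for supercell partitions: purity, adjusted Rand index,
# normalised mutual information, weighted label-transfer accuracy, and
# binned earth mover's distance between marker distributions.

# Coerce a named vector or two-column table (cell_id + value) to a named
# character vector, dropping NAs.
.as_cell_map <- function(x, value_col = NULL) {
  if (is.data.frame(x)) {
    dt <- data.table::as.data.table(x)
    vc <- value_col %||% setdiff(names(dt), "cell_id")[1]
    x <- setNames(as.character(dt[[vc]]), dt$cell_id)
  }
  x[!is.na(x)]
}

#' Supercell purity
#'
#' Purity of a supercell is the proportion of its annotated members that
#' belong to its most dominant cell type; a perfectly homogeneous (or
#' singleton) supercell scores 1. Cells without labels are excluded;
#' supercells with no labelled member are excluded from the scores and
#' counted separately.
#'
#' @param part partition `data.table` (`cell_id`, `supercell_id`)
#' @param labels cell type annotation: named vector (cell id -> type) or a
#'   table with columns `cell_id` and `cell_type`; may cover only part of
#'   the cells
#' @return object of class `purity_report`: list with `per_supercell`
#'   (`data.table`: `supercell_id`, `n_labelled`, `dominant_type`,
#'   `purity`), `mean_purity`, `frac_pure` (share of scored supercells at
#'   purity 1), `n_labelled_cells`, `n_unscored_supercells`
#' @export
supercell_purity <- function(part, labels) {
  labels <- .as_cell_map(labels, "cell_type")
  dt <- data.table::data.table(
    supercell_id = part$supercell_id,
    type = unname(labels[part$cell_id])
  )[!is.na(type)]
  if (nrow(dt) == 0) {
    stop("parameter error: no labelled cells overlap the partition",
      call. = FALSE
    )
  }
  per <- dt[, {
    tab <- sort(table(type), decreasing = TRUE)
    list(
      n_labelled = .N,
      dominant_type = names(tab)[1],
      purity = as.numeric(tab[1]) / .N
    )
  }, by = supercell_id]
  structure(
    list(
      per_supercell = per,
      mean_purity = mean(per$purity),
      frac_pure = mean(per$purity == 1),
      n_labelled_cells = nrow(dt),
      n_unscored_supercells = length(setdiff(unique(part$supercell_id), per$supercell_id))
    ),
    class = "purity_report"
  )
}

#' @export
print.purity_report <- function(x, ...) {
  cat(sprintf(
    "purity over %d supercells (%d labelled cells): mean %.4f, %.1f%% fully pure\n",
    nrow(x$per_supercell), x$n_labelled_cells, x$mean_purity,
    100 * x$frac_pure
  ))
  invisible(x)
}

# Shared validation for partition-agreement metrics: returns a
# contingency table over the common cell universe.
.pair_contingency <- function(p1, p2) {
  p1 <- .as_cell_map(p1)
  p2 <- .as_cell_map(p2)
  common <- intersect(names(p1), names(p2))
  if (length(common) == 0) {
    stop("parameter error: the two partitions share no cells", call. = FALSE)
  }
  table(unname(p1[common]), unname(p2[common]))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance: 1 for identical
#' partitions (up to relabeling), around 0 for independent ones. Both
#' arguments are named vectors (cell id -> group) or `cell_id` + label
#' tables; the index is computed over the common cell universe, so a
#' partial annotation restricts the comparison to the annotated cells.
#'
#' @param p1,p2 partitions of the same cells
#' @return ARI in `[-1, 1]`
#' @export
adjusted_rand_index <- function(p1, p2) {
  ct <- .pair_contingency(p1, p2)
  n <- sum(ct)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(ct))
  sum_a <- sum(ch2(rowSums(ct)))
  sum_b <- sum(ch2(colSums(ct)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1) # both partitions trivial (all singletons or one block)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Normalised mutual information between two partitions
#'
#' Mutual information normalised by the arithmetic mean of the two label
#' entropies, in `[0, 1]`. When either partition is a single cluster its
#' entropy is 0 and the score is defined as 0 by convention (no structure
#' to agree on).
#'
#' @param p1,p2 partitions of the same cells
#' @return NMI in `[0, 1]`
#' @export
normalized_mutual_information <- function(p1, p2) {
  ct <- .pair_contingency(p1, p2)
  n <- sum(ct)
  p <- ct / n
  pr <- rowSums(p)
  pc <- colSums(p)
  h <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  hr <- h(pr)
  hc <- h(pc)
  if (hr == 0 || hc == 0) {
    return(0)
  }
  mi <- 0
  for (i in seq_along(pr)) {
    for (j in seq_along(pc)) {
      if (p[i, j] > 0) {
        mi <- mi + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
      }
    }
  }
  max(0, min(1, mi / ((hr + hc) / 2)))
}

#' Consolidate fine labels into broader categories
#'
#' Builds a total mapping over the supplied label set: labels named in
#' `groups` map to their broad category, unmapped labels pass through
#' unchanged.
#'
#' @param groups named character vector, fine label -> broad label
#' @return function mapping character vectors of fine labels to broad ones
#' @export
label_mapping <- function(groups) {
  force(groups)
  function(x) {
    out <- unname(groups[x])
    out[is.na(out)] <- x[is.na(out)]
    out
  }
}

#' Per-type and proportion-weighted label-transfer accuracy
#'
#' For each (consolidated) true cell type, the accuracy is the proportion
#' of its cells whose predicted label matches. The weighted accuracy
#' multiplies each type's accuracy by the type's relative proportion among
#' the truth-labelled cells and sums — so abundant types dominate the
#' summary, as they do in the data. Cells without a truth label are
#' excluded.
#'
#' @param pred predicted labels: named vector (cell id -> label) or
#'   `cell_id` + label table
#' @param truth reference labels, same forms
#' @param mapping optional named character vector consolidating fine labels
#'   into broader categories (applied to both sides); see [label_mapping()]
#' @return list with `per_type` (`data.table`: `cell_type`, `n`,
#'   `proportion`, `accuracy`) and `weighted_accuracy`
#' @export
label_accuracy <- function(pred, truth, mapping = NULL) {
  pred <- .as_cell_map(pred)
  truth <- .as_cell_map(truth)
  common <- intersect(names(truth), names(pred))
  if (length(common) == 0) {
    stop("parameter error: no cells carry both a prediction and a truth label",
      call. = FALSE
    )
  }
  map_fun <- if (is.null(mapping)) identity else label_mapping(mapping)
  dt <- data.table::data.table(
    cell_type = map_fun(unname(truth[common])),
    correct = map_fun(unname(truth[common])) == map_fun(unname(pred[common]))
  )
  per_type <- dt[, .(n = .N, accuracy = mean(correct)), by = cell_type]
  per_type[, prop := n / sum(n)]
  data.table::setnames(per_type, "prop", "proportion")
  data.table::setorder(per_type, cell_type)
  list(
    per_type = per_type[],
    weighted_accuracy = per_type[, sum(accuracy * proportion)]
  )
}

#' Earth mover's distance between two marker distributions
#'
#' The two samples are binned on a shared grid of width `bin_width`
#' anchored at `floor(min / bin_width) * bin_width` of the pooled values;
#' the EMD is the first Wasserstein distance between the two normalised
#' histograms, `sum(|cumulative difference|) * bin_width`. A bin width of
#' 0.1 is the convention for arcsinh-scale cytometry markers.
#'
#' @param x1,x2 numeric vectors of marker values (non-empty, finite)
#' @param bin_width histogram bin width
#' @return EMD `>= 0`; 0 exactly when the binned histograms coincide
#' @export
earth_movers_distance <- function(x1, x2, bin_width = 0.1) {
  if (length(x1) == 0 || length(x2) == 0) {
    stop("parameter error: both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(x1)) || any(!is.finite(x2))) {
    stop("parameter error: marker values must be finite", call. = FALSE)
  }
  lo <- floor(min(x1, x2) / bin_width) * bin_width
  hi <- max(x1, x2)
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  b1 <- tabulate(findInterval(x1, breaks, rightmost.closed = FALSE),
    nbins = length(breaks) - 1
  )
  b2 <- tabulate(findInterval(x2, breaks, rightmost.closed = FALSE),
    nbins = length(breaks) - 1
  )
  p1 <- b1 / sum(b1)
  p2 <- b2 / sum(b2)
  sum(abs(cumsum(p1 - p2))) * bin_width
}

#' Per-marker EMD between two groups of cells
#'
#' Convenience wrapper for batch-effect assessment: for every marker,
#' the EMD between the marker's distribution in group `g1` and in `g2`
#' (groups taken from `group_col`, e.g. `batch_id` or `sample_id`).
#'
#' @param table an expression table
#' @param g1,g2 the two group values to compare
#' @param group_col grouping column (default `"batch_id"`)
#' @param markers markers to score (default: all)
#' @param bin_width histogram bin width
#' @return `data.table` with columns `marker`, `emd`
#' @export
marker_emd <- function(table, g1, g2, group_col = "batch_id",
                       markers = NULL, bin_width = 0.1) {
  markers <- markers %||% marker_names(table)
  grp <- table[[group_col]]
  if (!all(c(g1, g2) %in% grp)) {
    stop("parameter error: group value(s) absent from column ", group_col,
      call. = FALSE
    )
  }
  data.table::data.table(
    marker = markers,
    emd = vapply(markers, function(m) {
      earth_movers_distance(
        table[[m]][grp == g1], table[[m]][grp == g2], bin_width
      )
    }, numeric(1))
  )
}
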
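#' Expression tables
#'
#' An expression table is a `data.table` with one row per cell: a unique
#' `cell_id`, a non-empty `sample_id`, one numeric column per marker, and
#' optional annotation columns `batch_id`, `cell_type` and `cluster_id`.
#' The marker set is carried in the `"markers"` attribute; any column that
#' is neither reserved nor a declared marker (e.g. Time, Event_length) is
#' kept but ignored by the pipeline.
#'
#' @param x a data.frame or data.table
#' @param markers character vector of marker column names; if `NULL`, every
#'   non-reserved column is taken as a marker
#' @return a validated `data.table` with attribute `"markers"`
#' @export
as_expression_table <- function(x, markers = NULL) {
  dt <- data.table::as.data.table(x)
  required <- c("cell_id", "sample_id")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(markers)) {
    markers <- setdiff(names(dt), .reserved_cols)
  } else {
    unknown <- setdiff(markers, names(dt))
    if (length(unknown) > 0) {
      stop("schema error: marker column(s) not present: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (length(markers) < 1) {
    stop("schema error: expression table needs at least one marker column",
      call. = FALSE
    )
  }
  dt[, cell_id := as.character(cell_id)]
  dt[, sample_id := as.character(sample_id)]
  dup <- dt$cell_id[duplicated(dt$cell_id)]
  if (length(dup) > 0) {
    stop("integrity error: duplicated cell_id value(s): ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(dt$sample_id)) || any(!nzchar(dt$sample_id))) {
    stop("integrity error: every row must have a non-empty sample_id",
      call. = FALSE
    )
  }
  for (m in markers) {
    v <- dt[[m]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop(sprintf(
        "parse error: marker column '%s' is not numeric (e.g. row %s)",
        m, paste(head(bad, 5), collapse = ", ")
      ), call. = FALSE)
    }
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))
      stop(sprintf(
        "integrity error: marker column '%s' has missing/non-finite values in row(s) %s",
        m, paste(head(bad, 10), collapse = ", ")
      ), call. = FALSE)
    }
  }
  data.table::setattr(dt, "markers", markers)
  dt
}

#' Marker columns of an expression table
#'
#' @param x an expression table (or any object with a `"markers"` attribute)
#' @return character vector of marker names
#' @export
marker_names <- function(x) {
  m <- attr(x, "markers", exact = TRUE)
  if (is.null(m)) setdiff(names(x), .reserved_cols) else m
}

# Numeric cell x marker matrix for one (subset of a) table.
marker_matrix <- function(table, markers = marker_names(table)) {
  as.matrix(table[, ..markers])
}

# Canonical checksum of the data a dendrogram was built from: cell ids,
# marker names and per-marker sums. Cheap, deterministic, and sensitive to
# reordering or edits of the input.
table_checksum <- function(table, markers = marker_names(table)) {
  mm <- marker_matrix(table, markers)
  s <- paste(
    nrow(table), paste(markers, collapse = ","),
    paste(sprintf("%.10g", colSums(mm)), collapse = ","),
    fnv1a32(paste(table$cell_id, collapse = "\x1f")),
    sep = "|"
  )
  sprintf("fnv1a32:%08x", fnv1a32(s))
}
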
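#' Read a cell-by-marker expression table
#'
#' Reads either a delimited text file (comma-separated, UTF-8, header row
#' required) or an FCS 3.0/3.1 file into an expression table. Delimited
#' input must carry `cell_id` and `sample_id` columns (possibly under other
#' names, via `column_map`). FCS files carry no cell ids or sample ids, so
#' `sample_id` must be supplied and cell ids are synthesised as
#' `<sample_id>:<0-based event index>`, preserving event order.
#'
#' @param path file path
#' @param format `"delimited"` or `"fcs"`
#' @param markers marker columns/channels to use; `NULL` means every
#'   non-reserved column (delimited) or every channel (FCS)
#' @param column_map optional named character vector renaming input columns,
#'   e.g. `c(cell_id = "CellID", sample_id = "Sample")`
#' @param sample_id sample identifier for FCS input (one file is one sample)
#' @return an expression table (see [as_expression_table()])
#' @export
read_expression <- function(path, format = c("delimited", "fcs"),
                            markers = NULL, column_map = NULL,
                            sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("I/O error: file does not exist: ", path, call. = FALSE)
  }
  if (format == "delimited") {
    dt <- data.table::fread(path, header = TRUE, encoding = "UTF-8")
    if (!is.null(column_map)) {
      data.table::setnames(dt, old = unname(column_map), new = names(column_map),
        skip_absent = FALSE
      )
    }
    if (!"cell_id" %in% names(dt) && !is.null(sample_id)) {
      dt[, cell_id := paste0(sample_id, ":", seq_len(.N) - 1L)]
    }
    if (!"sample_id" %in% names(dt) && !is.null(sample_id)) {
      dt[, sample_id := sample_id]
    }
    as_expression_table(dt, markers = markers)
  } else {
    fcs <- read_fcs(path)
    if (is.null(sample_id)) {
      sample_id <- sub("\\.fcs$", "", basename(path), ignore.case = TRUE)
    }
    dt <- data.table::as.data.table(fcs$data)
    dt[, cell_id := paste0(sample_id, ":", seq_len(.N) - 1L)]
    dt[, sample_id := sample_id]
    as_expression_table(dt, markers = markers %||% fcs$channels)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transform specification
#'
#' @param method `"arcsinh"` or `"none"`
#' @param cofactor positive real divisor applied before `asinh`; 5 is
#'   conventional for mass cytometry, 150 for flow cytometry
#' @param markers markers to transform (`NULL` = all markers of the table)
#' @return object of class `transform_spec`
#' @export
transform_spec <- function(method = c("arcsinh", "none"), cofactor = 5,
                           markers = NULL) {
  method <- match.arg(method)
  if (!is.numeric(cofactor) || length(cofactor) != 1 || !is.finite(cofactor) ||
    cofactor <= 0) {
    stop("parameter error: cofactor must be a positive real", call. = FALSE)
  }
  structure(list(method = method, cofactor = cofactor, markers = markers),
    class = "transform_spec"
  )
}

#' Arcsinh-transform marker values
#'
#' Replaces each selected marker value x by `asinh(x / cofactor)`, the
#' variance-stabilising transform conventional in cytometry. Columns not
#' selected are left untouched. With `method = "none"` the table is
#' returned unchanged (for data transformed upstream).
#'
#' @param table an expression table
#' @param spec a [transform_spec()]
#' @return the transformed expression table (a copy)
#' @export
arcsinh_transform <- function(table, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  out <- data.table::copy(data.table::as.data.table(table))
  all_markers <- marker_names(table)
  sel <- spec$markers %||% all_markers
  unknown <- setdiff(sel, all_markers)
  if (length(unknown) > 0) {
    stop("parameter error: unknown marker name(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (spec$method == "arcsinh") {
    for (m in sel) {
      data.table::set(out, j = m, value = asinh(out[[m]] / spec$cofactor))
    }
  }
  data.table::setattr(out, "markers", all_markers)
  out
}

#' Write supercell outputs
#'
#' Writes the aggregated supercell expression and the cell-to-supercell map
#' as two CSV files, `supercell_expression.csv`
#' (`supercell_id,sample_id,n_cells,<markers...>`) and
#' `cell_supercell_map.csv` (`cell_id,sample_id,supercell_id`). Re-reading
#' with [read_supercell_outputs()] reproduces the inputs.
#'
#' @param expr supercell expression table (from [aggregate_expression()])
#' @param map cell-to-supercell partition table
#' @param out_dir output directory, created if absent
#' @return named character vector of the two file paths, invisibly
#' @export
write_outputs <- function(expr, map, out_dir) {
  missing_sc <- setdiff(unique(map$supercell_id), expr$supercell_id)
  if (length(missing_sc) > 0) {
    stop("consistency error: map references supercell id(s) absent from ",
      "expression: ", paste(head(missing_sc, 5), collapse = ", "),
      call. = FALSE
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("I/O error: cannot create output directory: ", out_dir, call. = FALSE)
  }
  markers <- setdiff(names(expr), c("supercell_id", "sample_id", "n_cells"))
  expr_path <- file.path(out_dir, "supercell_expression.csv")
  map_path <- file.path(out_dir, "cell_supercell_map.csv")
  data.table::fwrite(
    expr[, c("supercell_id", "sample_id", "n_cells", markers), with = FALSE],
    expr_path
  )
  data.table::fwrite(map[, c("cell_id", "sample_id", "supercell_id"),
    with = FALSE
  ], map_path)
  invisible(c(expression = expr_path, map = map_path))
}

#' Read supercell outputs back
#'
#' @param out_dir directory written by [write_outputs()]
#' @return list with elements `expression` and `map`
#' @export
read_supercell_outputs <- function(out_dir) {
  expr <- data.table::fread(file.path(out_dir, "supercell_expression.csv"))
  map <- data.table::fread(
    file.path(out_dir, "cell_supercell_map.csv"),
    colClasses = list(character = c("cell_id", "sample_id", "supercell_id"))
  )
  list(expression = expr, map = map)
}

#' Write an expression table to CSV
#'
#' Reserved columns first, then markers, then any extra columns.
#' @param table an expression table
#' @param path output file
#' @return `path`, invisibly
#' @export
write_expression <- function(table, path) {
  markers <- marker_names(table)
  lead <- intersect(.reserved_cols, names(table))
  rest <- setdiff(names(table), c(lead, markers))
  data.table::fwrite(table[, c(lead, markers, rest), with = FALSE], path)
  invisible(path)
}
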
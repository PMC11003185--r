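# Gaussian-mixture generator for cytometry-like tables with known truth.
#
# Values are drawn on the arcsinh scale (roughly 0-8), the scale on which
# the pipeline operates: each cell type has a mean vector, cells scatter
# around it with a common within-type standard deviation, and optional
# per-batch additive shifts emulate batch effects. Every other module is
# testable against the recorded truth columns without any downloads.

#' Simulation configuration
#'
#' Cell type mean vectors are either supplied explicitly (`type_means`, a
#' types x markers matrix) or constructed deterministically from
#' `separation`: each type elevates its own block of markers by
#' `separation * sd` above a baseline of 1, giving pairwise mean distances
#' of at least `separation` within-type standard deviations.
#'
#' @param n_samples number of samples
#' @param cells_per_sample cells in each sample (scalar or per-sample vector)
#' @param n_markers number of markers (named `m1`, `m2`, ...)
#' @param type_props cell type proportions (must sum to 1); types are named
#'   `type1`, `type2`, ... unless the vector is named
#' @param type_means optional types x markers matrix of mean vectors
#' @param sd within-type standard deviation per marker (> 0)
#' @param separation elevation of each type's signature markers, in units
#'   of `sd` (default 3: well-separated populations)
#' @param batch_of optional named vector, sample id -> batch id
#' @param batch_shift optional named list, batch id -> named per-marker
#'   additive shift
#' @param exact_proportions assign type counts by largest remainder instead
#'   of multinomial sampling (exact cell counts per type)
#' @param seed integer seed (mandatory: generation is fully reproducible)
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_samples = 3L, cells_per_sample = 2000L,
                       n_markers = 10L, type_props = c(0.3, 0.25, 0.2, 0.15, 0.1),
                       type_means = NULL, sd = 0.35, separation = 3,
                       batch_of = NULL, batch_shift = NULL,
                       exact_proportions = FALSE, seed) {
  if (missing(seed)) stop("parameter error: seed is mandatory", call. = FALSE)
  if (abs(sum(type_props) - 1) > 1e-12) {
    stop("parameter error: type proportions must sum to 1", call. = FALSE)
  }
  if (any(type_props <= 0)) {
    stop("parameter error: type proportions must be positive", call. = FALSE)
  }
  if (sd <= 0) stop("parameter error: sd must be positive", call. = FALSE)
  n_types <- length(type_props)
  if (is.null(names(type_props))) {
    names(type_props) <- paste0("type", seq_len(n_types))
  }
  markers <- paste0("m", seq_len(n_markers))
  if (is.null(type_means)) {
    # block design: type t elevates markers with (index mod n_types) == t-1
    type_means <- matrix(1, n_types, n_markers,
      dimnames = list(names(type_props), markers)
    )
    for (t in seq_len(n_types)) {
      sig <- which((seq_len(n_markers) - 1L) %% n_types == (t - 1L))
      type_means[t, sig] <- 1 + separation * sd
    }
  } else {
    type_means <- as.matrix(type_means)
    stopifnot(nrow(type_means) == n_types, ncol(type_means) == n_markers)
    dimnames(type_means) <- list(names(type_props), markers)
  }
  cells_per_sample <- rep(as.integer(cells_per_sample),
    length.out = n_samples
  )
  structure(
    list(
      n_samples = as.integer(n_samples), cells_per_sample = cells_per_sample,
      n_markers = as.integer(n_markers), markers = markers,
      type_props = type_props, type_means = type_means, sd = sd,
      separation = separation, batch_of = batch_of,
      batch_shift = batch_shift,
      exact_proportions = isTRUE(exact_proportions), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Largest-remainder integer apportionment of n among proportions p.
largest_remainder_counts <- function(n, p) {
  quota <- n * p
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    add <- order(-frac, seq_along(p))[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  as.integer(counts)
}

#' Generate a Gaussian-mixture cytometry-like table
#'
#' Per cell: a type drawn from the configured proportions (or assigned
#' exactly by largest remainder), then marker values drawn from
#' `Normal(type mean + batch shift, sd)`. Truth columns `cell_type` and
#' (when batches are configured) `batch_id` are recorded. Fully
#' reproducible: each sample is generated under a seed derived from the
#' config seed and the sample id.
#'
#' @param config a [sim_config()]
#' @return an expression table with truth columns
#' @export
generate_mixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_types <- length(config$type_props)
  tables <- vector("list", config$n_samples)
  for (si in seq_len(config$n_samples)) {
    sid <- paste0("sample", si)
    n <- config$cells_per_sample[si]
    set.seed(derive_sample_seed(config$seed, sid))
    if (config$exact_proportions) {
      counts <- largest_remainder_counts(n, config$type_props)
      types <- rep(seq_len(n_types), counts)
      types <- types[sample.int(n)] # shuffle so order carries no signal
    } else {
      types <- sample.int(n_types, n, replace = TRUE, prob = config$type_props)
    }
    shift <- numeric(config$n_markers)
    batch <- NA_character_
    if (!is.null(config$batch_of) && sid %in% names(config$batch_of)) {
      batch <- config$batch_of[[sid]]
      bs <- config$batch_shift[[batch]]
      if (!is.null(bs)) shift[match(names(bs), config$markers)] <- unname(bs)
    }
    vals <- config$type_means[types, , drop = FALSE] +
      matrix(rnorm(n * config$n_markers, sd = config$sd), n, config$n_markers) +
      matrix(shift, n, config$n_markers, byrow = TRUE)
    dt <- data.table::data.table(
      cell_id = sprintf("%s:%d", sid, seq_len(n) - 1L),
      sample_id = sid,
      cell_type = names(config$type_props)[types]
    )
    if (!is.na(batch)) dt[, batch_id := batch]
    for (j in seq_len(config$n_markers)) {
      data.table::set(dt, j = config$markers[j], value = vals[, j])
    }
    tables[[si]] <- dt
  }
  out <- data.table::rbindlist(tables, fill = TRUE)
  as_expression_table(out, markers = config$markers)
}

#' Add a batch shift to an expression table
#'
#' Adds `shift` to the named markers of the cells belonging to `batch`
#' only; all other cells and columns are untouched. Useful to impose (or,
#' with a negative shift, remove) a known technical effect on a fixture.
#'
#' @param table an expression table with a `batch_id` column
#' @param shift named numeric vector, marker -> additive shift
#' @param batch the batch to shift
#' @return the shifted expression table (a copy)
#' @export
apply_batch_shift <- function(table, shift, batch) {
  if (!"batch_id" %in% names(table)) {
    stop("parameter error: table has no batch_id column", call. = FALSE)
  }
  if (!batch %in% table$batch_id) {
    stop("parameter error: unknown batch: ", batch, call. = FALSE)
  }
  unknown <- setdiff(names(shift), marker_names(table))
  if (length(unknown) > 0) {
    stop("parameter error: unknown marker(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  out <- data.table::copy(data.table::as.data.table(table))
  rows <- which(out$batch_id == batch)
  for (m in names(shift)) {
    data.table::set(out, i = rows, j = m, value = out[[m]][rows] + shift[[m]])
  }
  data.table::setattr(out, "markers", marker_names(table))
  out
}
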
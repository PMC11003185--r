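#' Core supercell parameters
#'
#' @param n_pcs number of principal components (default 10; capped at the
#'   number of markers)
#' @param knn_k number of nearest neighbours for the graph (default 5)
#' @param walk_steps random-walk length for walktrap (default 4)
#' @param gamma target ratio of cells to supercells (default 20)
#' @param aggregation `"mean"` or `"median"` marker aggregation
#' @param seed integer seed controlling any randomised step
#' @param scale_pca logical; scale markers to unit variance before PCA
#'   (default `FALSE`: arcsinh-transformed markers already share a scale)
#' @return object of class `core_params`
#' @export
core_params <- function(n_pcs = 10L, knn_k = 5L, walk_steps = 4L,
                        gamma = 20, aggregation = c("mean", "median"),
                        seed = 42L, scale_pca = FALSE) {
  aggregation <- match.arg(aggregation)
  if (n_pcs < 1) stop("parameter error: n_pcs must be >= 1", call. = FALSE)
  if (knn_k < 1) stop("parameter error: knn_k must be >= 1", call. = FALSE)
  if (walk_steps < 1) {
    stop("parameter error: walk_steps must be >= 1", call. = FALSE)
  }
  if (!is.numeric(gamma) || gamma < 1) {
    stop("parameter error: gamma must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_pcs = as.integer(n_pcs), knn_k = as.integer(knn_k),
      walk_steps = as.integer(walk_steps), gamma = as.numeric(gamma),
      aggregation = aggregation, seed = as.integer(seed),
      scale_pca = isTRUE(scale_pca)
    ),
    class = "core_params"
  )
}

#' Principal component scores of a cell-by-marker matrix
#'
#' Centres each marker (optionally scales to unit variance) and returns the
#' scores on `min(n_pcs, n_markers)` components, so a panel with fewer
#' markers than the requested components simply uses them all. Deterministic:
#' an exact SVD is used, with component signs fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param matrix numeric cell x marker matrix (finite values)
#' @param n_pcs requested number of components
#' @param scale. scale markers to unit variance first
#' @return object of class `pca_scores`: list with `scores` (cell x
#'   component matrix), `variance` (non-increasing per-component variance),
#'   `rotation`, `center`
#' @export
compute_pca <- function(matrix, n_pcs = 10L, scale. = FALSE) {
  if (n_pcs < 1) stop("parameter error: n_pcs must be >= 1", call. = FALSE)
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1 || ncol(matrix) < 1 || any(!is.finite(matrix))) {
    stop("parameter error: PCA input must be a non-empty finite matrix",
      call. = FALSE
    )
  }
  d <- min(as.integer(n_pcs), ncol(matrix))
  if (nrow(matrix) == 1L) {
    # degenerate: a single cell sits at the origin of every component
    scores <- base::matrix(0, 1, d)
    return(structure(list(
      scores = scores, variance = rep(0, d),
      rotation = diag(ncol(matrix))[, seq_len(d), drop = FALSE],
      center = drop(matrix[1, ])
    ), class = "pca_scores"))
  }
  sds <- NULL
  if (scale.) {
    sds <- apply(matrix, 2, stats::sd)
    sds[sds == 0] <- 1 # constant markers carry no information; leave centred
  }
  p <- stats::prcomp(matrix,
    center = TRUE, scale. = if (scale.) sds else FALSE,
    rank. = d
  )
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(
    scores = p$x[, seq_len(d), drop = FALSE],
    variance = (p$sdev^2)[seq_len(d)],
    rotation = p$rotation[, seq_len(d), drop = FALSE],
    center = p$center
  ), class = "pca_scores")
}

# Exact brute-force kNN with ties broken by lowest row index. Quadratic in
# n; used below the exact-search threshold where tie behaviour must be
# reproducible bit for bit.
brute_knn <- function(x, k) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(d2[i, -i], seq_len(n)[-i])[seq_len(k)]
    idx[i, ] <- seq_len(n)[-i][o]
  }
  idx
}

#' Build a k-nearest-neighbour graph from PCA scores
#'
#' Computes the exact Euclidean k nearest neighbours of every cell and
#' symmetrises by union: an undirected edge is present whenever either cell
#' lists the other. For up to `exact_threshold` cells a quadratic search
#' with documented tie-breaking (lowest cell index) is used; above it, the
#' KMKNN algorithm (still exact) from BiocNeighbors.
#'
#' @param scores a `pca_scores` object or a numeric matrix of coordinates
#' @param k neighbours per cell; must satisfy `1 <= k <= n - 1`
#' @param exact_threshold size below which the quadratic search is used
#' @return an `igraph` undirected simple graph with `n` vertices in cell
#'   order and graph attribute `k`
#' @export
build_knn_graph <- function(scores, k = 5L, exact_threshold = 2000L) {
  x <- if (inherits(scores, "pca_scores")) scores$scores else as.matrix(scores)
  n <- nrow(x)
  if (n < 2) {
    stop("parameter error: need at least 2 cells to build a kNN graph",
      call. = FALSE
    )
  }
  if (k < 1 || k >= n) {
    stop(sprintf(
      "parameter error: k (%d) must be in [1, n-1] with n = %d cells; lower k or merge samples",
      k, n
    ), call. = FALSE)
  }
  idx <- if (n <= exact_threshold) {
    brute_knn(x, k)
  } else {
    BiocNeighbors::findKNN(x, k = k, get.distance = FALSE)$index
  }
  el <- cbind(rep(seq_len(n), times = k), as.vector(idx))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "k", as.integer(k))
  g
}
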
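# Shared fixtures, all built in code at test time.

library(data.table)

# A tiny valid expression table with annotations.
make_small_table <- function(n = 12, n_markers = 3, seed = 1,
                             sample_ids = c("s1", "s2")) {
  set.seed(seed)
  dt <- data.table(
    cell_id = sprintf("c%02d", seq_len(n)),
    sample_id = rep(sample_ids, length.out = n),
    cell_type = sample(c("A", "B"), n, replace = TRUE)
  )
  for (j in seq_len(n_markers)) {
    set(dt, j = paste0("m", j), value = round(rnorm(n), 3))
  }
  as_expression_table(dt)
}

# Independent minimal FCS 3.1 writer (float32 list mode), used only to
# create read_fcs round-trip fixtures. Deliberately separate code from the
# package reader.
write_fcs_fixture <- function(path, data, endian = "little") {
  n <- nrow(data)
  p <- ncol(data)
  delim <- "/"
  kw <- c(
    "$MODE", "L", "$DATATYPE", "F",
    "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
    "$PAR", p, "$TOT", n
  )
  for (i in seq_len(p)) {
    kw <- c(
      kw, sprintf("$P%dN", i), colnames(data)[i],
      sprintf("$P%dB", i), 32,
      sprintf("$P%dR", i), 262144,
      sprintf("$P%dE", i), "0,0"
    )
  }
  text <- paste0(delim, paste(kw, collapse = delim), delim)
  text_start <- 58
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n * p - 1
  header <- sprintf(
    "FCS3.1    %8d%8d%8d%8d%8d%8d",
    text_start, text_end, data_start, data_end, 0, 0
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(data)), con, size = 4, endian = endian)
  invisible(path)
}

# Two 5-cliques joined by a single bridge edge: the canonical two-community
# graph for walktrap checks.
make_two_clique_graph <- function() {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::add_edges(g, c(1, 6))
}

# Brute-force maximum-modularity 2-partition of a small graph (exhaustive
# over all 2-colourings; independent of any community detection code).
best_two_partition <- function(g) {
  n <- igraph::vcount(g)
  best <- NULL
  best_q <- -Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)] + 1L)
    q <- igraph::modularity(g, memb)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  best
}

# Pair-counting ARI computed by explicit enumeration of all cell pairs.
brute_force_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      if (!same_a && !same_b) s00 <- s00 + 1
      if (same_a && !same_b) s10 <- s10 + 1
      if (!same_a && same_b) s01 <- s01 + 1
    }
  }
  idx <- s11
  total <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / total
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (idx - exp_idx) / (max_idx - exp_idx)
}

# 1-D transport cost between two histograms solved as an LP
# (independent of the cumulative-difference implementation).
lp_transport_emd <- function(p, q, centers) {
  stopifnot(requireNamespace("pracma", quietly = TRUE))
  nb <- length(p)
  cost <- as.vector(outer(centers, centers, function(a, b) abs(a - b)))
  # constraints: row sums = p, col sums = q (drop one redundant row)
  a_rows <- t(vapply(seq_len(nb), function(i) {
    m <- matrix(0, nb, nb)
    m[i, ] <- 1
    as.vector(m)
  }, numeric(nb * nb)))
  a_cols <- t(vapply(seq_len(nb), function(j) {
    m <- matrix(0, nb, nb)
    m[, j] <- 1
    as.vector(m)
  }, numeric(nb * nb)))
  aeq <- rbind(a_rows, a_cols[-nb, , drop = FALSE])
  beq <- c(p, q[-nb])
  sol <- pracma::linprog(cost, Aeq = aeq, beq = beq, maxiter = 200)
  sum(cost * sol$x)
}

run_cli <- function(...) {
  cli_main(c(...))
}
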
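test_that("purity follows the dominant-type definition and handles partial labels", {
  part <- data.table(
    cell_id = sprintf("c%d", 1:6),
    supercell_id = rep(c("SC_1", "SC_2"), each = 3)
  )
  labels <- c(c1 = "A", c2 = "A", c3 = "B", c4 = "B", c5 = "B", c6 = "B")
  rep <- supercell_purity(part, labels)
  expect_equal(sort(rep$per_supercell$purity), c(2 / 3, 1))
  expect_equal(rep$mean_purity, mean(c(2 / 3, 1)))
  expect_equal(rep$frac_pure, 0.5)

  # unlabelled cells are excluded; fully unlabelled supercells counted apart
  partial <- c(c1 = "A", c2 = "A") # SC_2 entirely unlabelled
  rep2 <- supercell_purity(part, partial)
  expect_equal(nrow(rep2$per_supercell), 1)
  expect_equal(rep2$per_supercell$purity, 1)
  expect_equal(rep2$n_unscored_supercells, 1)
  expect_error(supercell_purity(part, c(zz = "A")), "no labelled cells")

  # invariant to supercell relabeling
  part2 <- copy(part)[, supercell_id := paste0("renamed_", supercell_id)]
  expect_equal(supercell_purity(part2, labels)$mean_purity, rep$mean_purity)
})

test_that("random grouping purity matches a multinomial Monte-Carlo oracle", {
  # balanced 3-type data in random groups of 20: mean purity should equal
  # E[max count] / 20 of a Multinomial(20, 1/3) draw
  set.seed(77)
  n <- 6000
  part <- data.table(
    cell_id = sprintf("c%d", 1:n),
    supercell_id = paste0("SC_", sample(rep(1:300, each = 20)))
  )
  labels <- setNames(sample(c("A", "B", "C"), n, replace = TRUE), part$cell_id)
  obs <- supercell_purity(part, labels)$mean_purity
  oracle <- mean(apply(stats::rmultinom(20000, 20, rep(1 / 3, 3)), 2, max)) / 20
  expect_equal(obs, oracle, tolerance = 0.02)
})

test_that("ARI matches brute-force pair counting and an external implementation", {
  cells <- letters[1:4]
  p1 <- setNames(c("g1", "g1", "g2", "g2"), cells) # {a,b | c,d}
  p2 <- setNames(c("h1", "h2", "h2", "h2"), cells) # {a | b,c,d}
  expect_equal(
    adjusted_rand_index(p1, p2),
    brute_force_ari(unname(p1), unname(p2)),
    tolerance = 1e-12
  )

  expect_equal(adjusted_rand_index(p1, p1), 1)
  relab <- setNames(c("x", "x", "y", "y"), cells)
  expect_equal(adjusted_rand_index(p1, relab), 1)

  set.seed(15)
  for (i in 1:5) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    nm <- sprintf("c%d", 1:20)
    expect_equal(
      adjusted_rand_index(setNames(a, nm), setNames(b, nm)),
      brute_force_ari(a, b),
      tolerance = 1e-12
    )
    skip_if_not_installed("mclust")
    expect_equal(
      adjusted_rand_index(setNames(a, nm), setNames(b, nm)),
      mclust::adjustedRandIndex(a, b),
      tolerance = 1e-12
    )
  }

  expect_error(adjusted_rand_index(p1, setNames("g", "zz")), "share no cells")
  # symmetry
  expect_equal(adjusted_rand_index(p1, p2), adjusted_rand_index(p2, p1))
})

test_that("NMI uses arithmetic-mean normalisation with degenerate convention", {
  nm <- sprintf("c%d", 1:12)
  p1 <- setNames(rep(c("a", "b", "c"), each = 4), nm)
  expect_equal(normalized_mutual_information(p1, p1), 1)

  single <- setNames(rep("only", 12), nm)
  expect_equal(normalized_mutual_information(p1, single), 0)

  # cross-check against igraph's Danon NMI on non-degenerate cases
  set.seed(19)
  a <- sample(1:3, 50, replace = TRUE)
  b <- sample(1:4, 50, replace = TRUE)
  expect_equal(
    normalized_mutual_information(setNames(a, 1:50), setNames(b, 1:50)),
    igraph::compare(a, b, method = "nmi"),
    tolerance = 1e-10
  )
  # symmetry
  expect_equal(
    normalized_mutual_information(setNames(a, 1:50), setNames(b, 1:50)),
    normalized_mutual_information(setNames(b, 1:50), setNames(a, 1:50))
  )

  # independent random labelings of many cells share almost no information
  set.seed(99)
  big1 <- setNames(sample(1:3, 10000, replace = TRUE), 1:10000)
  big2 <- setNames(sample(1:3, 10000, replace = TRUE), 1:10000)
  expect_lt(normalized_mutual_information(big1, big2), 0.01)
})

test_that("label accuracy weights per-type scores by truth proportions", {
  nm <- sprintf("c%d", 1:10)
  truth <- setNames(rep(c("A", "B"), c(9, 1)), nm)
  pred <- setNames(c(rep("A", 9), "A"), nm) # B always wrong
  acc <- label_accuracy(pred, truth)
  expect_equal(acc$per_type[cell_type == "A"]$accuracy, 1)
  expect_equal(acc$per_type[cell_type == "B"]$accuracy, 0)
  expect_equal(acc$weighted_accuracy, 0.9)

  # all correct
  expect_equal(label_accuracy(truth, truth)$weighted_accuracy, 1)

  # fine-to-coarse consolidation against a hand-computed confusion summary
  truth3 <- setNames(c("Tcm", "Tem", "B1", "B2", "NK", "NK"), sprintf("x%d", 1:6))
  pred3 <- setNames(c("Tem", "B1", "B2", "Tcm", "NK", "B1"), sprintf("x%d", 1:6))
  mapping <- c(Tcm = "T", Tem = "T", B1 = "B", B2 = "B")
  acc3 <- label_accuracy(pred3, truth3, mapping = mapping)
  # by hand: T cells (2): pred T, B -> 1/2; B cells (2): pred B, T -> 1/2;
  # NK (2): NK, B -> 1/2; weighted = 1/2
  expect_equal(acc3$per_type$accuracy, c(0.5, 0.5, 0.5))
  expect_equal(acc3$weighted_accuracy, 0.5)

  # truth-less cells excluded; disjoint sets error
  expect_error(
    label_accuracy(setNames("A", "p1"), setNames("A", "q1")),
    "no cells"
  )
})

test_that("binned EMD matches an LP transport oracle and its axioms", {
  expect_equal(earth_movers_distance(c(0.05, 0.15), c(0.05, 0.15)), 0)
  # point mass at 0 vs at 1: unit transport distance
  expect_equal(earth_movers_distance(rep(0, 10), rep(1, 10)), 1, tolerance = 1e-9)

  skip_if_not_installed("pracma")
  set.seed(7)
  x1 <- c(0.01, 0.12, 0.13, 0.31, 0.33, 0.52)
  x2 <- c(0.11, 0.12, 0.35, 0.51, 0.55, 0.58)
  bw <- 0.1
  lo <- floor(min(x1, x2) / bw) * bw
  breaks <- seq(lo, max(x1, x2) + bw, by = bw)
  h1 <- tabulate(findInterval(x1, breaks), nbins = length(breaks) - 1)
  h2 <- tabulate(findInterval(x2, breaks), nbins = length(breaks) - 1)
  centers <- breaks[-length(breaks)] + bw / 2
  oracle <- lp_transport_emd(h1 / sum(h1), h2 / sum(h2), centers)
  expect_equal(earth_movers_distance(x1, x2, bw), oracle, tolerance = 1e-8)

  # symmetry and triangle inequality on three samples
  set.seed(8)
  a <- rnorm(200)
  b <- rnorm(200, 0.5)
  c_ <- rnorm(200, 1.2)
  expect_equal(earth_movers_distance(a, b), earth_movers_distance(b, a))
  expect_lte(
    earth_movers_distance(a, c_),
    earth_movers_distance(a, b) + earth_movers_distance(b, c_) + 1e-12
  )
  expect_error(earth_movers_distance(numeric(0), a), "non-empty")
})
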
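test_that("majority-vote annotation uses modal types with alphabetical ties", {
  part <- data.table(
    cell_id = sprintf("c%d", 1:7),
    supercell_id = c(rep("SC_1", 3), rep("SC_2", 2), rep("SC_3", 2))
  )
  labels <- c(
    c1 = "A", c2 = "A", c3 = "B", # SC_1: A majority
    c4 = "B", c5 = "A" # SC_2: tie -> A
    # SC_3 unlabelled
  )
  ann <- annotate_majority(part, labels)
  expect_equal(unname(ann["SC_1"]), "A")
  expect_equal(unname(ann["SC_2"]), "A")
  expect_equal(unname(ann["SC_3"]), "unassigned")
})

test_that("expanded majority labels agree with direct counting on a fixture", {
  cfg <- sim_config(n_samples = 1, cells_per_sample = 1000, seed = 41)
  tab <- generate_mixture(cfg)
  res <- supercells_for_sample(tab, core_params(gamma = 20, seed = 41))
  truth <- setNames(tab$cell_type, tab$cell_id)
  ann <- annotate_majority(res$partition, truth)
  expanded <- expand_partition(res$partition, ann)
  agreement <- mean(expanded[names(truth)] == truth)
  # counting oracle: agreement equals the labelled-member-weighted purity
  per <- supercell_purity(res$partition, truth)$per_supercell
  oracle <- sum(per$purity * per$n_labelled) / sum(per$n_labelled)
  expect_equal(agreement, oracle, tolerance = 1e-12)
})

test_that("pseudobulk means supercells per sample and type", {
  expr <- data.table(
    supercell_id = c("s1_SC_1", "s1_SC_2", "s1_SC_3", "s2_SC_1"),
    sample_id = c("s1", "s1", "s1", "s2"),
    n_cells = c(10, 30, 5, 8),
    mA = c(2, 4, 7, 1), mB = c(0, 1, 2, 3)
  )
  ann <- c(s1_SC_1 = "T", s1_SC_2 = "T", s1_SC_3 = "B", s2_SC_1 = "T")
  pb <- pseudobulk(expr, ann, markers = c("mA", "mB"))
  expect_equal(pb[sample_id == "s1" & cell_type == "T"]$mA, 3) # (2+4)/2
  expect_equal(pb[sample_id == "s1" & cell_type == "B"]$mA, 7) # singleton
  expect_equal(pb[sample_id == "s2" & cell_type == "T"]$mB, 3)
  expect_equal(pb[sample_id == "s1" & cell_type == "T"]$n_supercells, 2)

  # weighted option weights by member counts
  pbw <- pseudobulk(expr, ann, markers = "mA", weight_by_size = TRUE)
  expect_equal(
    pbw[sample_id == "s1" & cell_type == "T"]$mA,
    (2 * 10 + 4 * 30) / 40
  )

  expect_error(pseudobulk(expr, ann, markers = character(0)), "empty marker")
  expect_error(pseudobulk(expr, ann["s1_SC_1"], markers = "mA"), "unannotated")

  # 3-sample synthetic fixture vs a direct group-by oracle
  cfg <- sim_config(n_samples = 3, cells_per_sample = 300, seed = 43)
  tab <- generate_mixture(cfg)
  run <- run_all_samples(tab, core_params(gamma = 10, seed = 43))
  ann2 <- annotate_majority(run$partition, setNames(tab$cell_type, tab$cell_id))
  mk <- marker_names(tab)[1:3]
  pb2 <- pseudobulk(run$expression, ann2, markers = mk)
  oracle <- copy(run$expression)[, cell_type := unname(ann2[supercell_id])][
    , lapply(.SD, mean),
    by = .(sample_id, cell_type), .SDcols = mk
  ]
  merged <- merge(pb2, oracle, by = c("sample_id", "cell_type"))
  for (m in mk) {
    expect_equal(merged[[paste0(m, ".x")]], merged[[paste0(m, ".y")]],
      tolerance = 1e-12
    )
  }
})

test_that("cluster filtering keeps clusters with > threshold cells in every sample", {
  toy <- data.table(
    sample_id = rep(c("s1", "s2", "s3"), times = c(8, 8, 12)),
    cluster_id = c(
      rep("keep", 4), rep("drop", 4), # s1: keep 4, drop 4
      rep("keep", 5), rep("drop", 3), # s2: keep 5, drop 3 (3 not > 3)
      rep("keep", 6), rep("drop", 6) # s3: keep 6, drop 6
    )
  )
  expect_equal(filter_clusters(toy, 3), "keep")

  # a cluster absent from one sample fails the rule
  toy2 <- rbind(toy, data.table(sample_id = "s1", cluster_id = "partial"))
  expect_false("partial" %in% filter_clusters(toy2, 0))

  # monotone in the threshold: raising it never adds clusters
  set.seed(51)
  rand <- data.table(
    sample_id = sample(c("s1", "s2"), 200, replace = TRUE),
    cluster_id = sample(paste0("cl", 1:6), 200, replace = TRUE)
  )
  kept <- lapply(0:8, function(th) filter_clusters(rand, th))
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("proportion tables are per-sample fractions at the single-cell level", {
  toy <- data.table(
    sample_id = rep(c("s1", "s2"), c(10, 20)),
    cluster_id = c(rep("X", 2), rep("Y", 8), rep("X", 15), rep("Y", 5))
  )
  pr <- cluster_proportions(toy)
  expect_equal(pr[sample_id == "s1"]$X, 0.2)
  expect_equal(pr[sample_id == "s1"]$Y, 0.8)
  expect_equal(pr[sample_id == "s2"]$X, 0.75)
  expect_equal(rowSums(as.matrix(pr[, -1])), c(1, 1), tolerance = 1e-9,
    ignore_attr = TRUE
  )
})

test_that("single-cell proportions differ from supercell-count proportions on skewed sizes", {
  # one huge and several small supercells in cluster X: counting supercells
  # misstates the cell-level abundance
  part <- data.table(
    cell_id = sprintf("c%d", 1:100),
    sample_id = "s1",
    supercell_id = c(rep("s1_SC_1", 91), paste0("s1_SC_", 1 + 1:9))
  )
  cl <- c(s1_SC_1 = "X", setNames(rep("Y", 9), paste0("s1_SC_", 1 + 1:9)))
  cells <- data.table(
    cell_id = part$cell_id, sample_id = "s1",
    cluster_id = unname(expand_partition(part, cl)[part$cell_id])
  )
  sc_prop <- mean(cl == "X") # 0.1 of supercells
  cell_prop <- cluster_proportions(cells)[1]$X # 0.91 of cells
  expect_equal(cell_prop, 0.91)
  expect_gt(abs(cell_prop - sc_prop), 0.5)
})
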
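test_that("gene and panel signals follow the probe-weighted mean definition", {
  rr <- random_reference(n_genes = 10, n_cells = 24, n_types = 3, seed = 2)
  v <- normalize_views(rr)
  labels <- rr$cell_labels

  # brute-force oracle on random fixtures
  for (g in c("g01", "g05")) {
    for (cl in c("t1", "t2")) {
      manual <- 24 * mean(v$cell_scaled[g, labels == cl])
      expect_equal(gene_signal(v, g, cl, labels, k = 24), manual)
    }
  }
  # k = 1 is the plain cluster mean
  expect_equal(gene_signal(v, "g02", "t1", labels),
               mean(v$cell_scaled["g02", labels == "t1"]))
  # panel signal is the sum; permutation-invariant
  genes <- c("g01", "g03", "g07")
  ps <- panel_signal(v, genes, "t2", labels, k = c(2, 3, 4))
  manual <- sum(vapply(seq_along(genes), function(i)
    c(2, 3, 4)[i] * mean(v$cell_scaled[genes[i], labels == "t2"]),
    numeric(1)))
  expect_equal(ps, manual)
  expect_equal(panel_signal(v, rev(genes), "t2", labels, k = c(4, 3, 2)), ps)
  expect_equal(panel_signal(v, "g01", "t1", labels, k = 7),
               gene_signal(v, "g01", "t1", labels, k = 7))

  expect_error(gene_signal(v, "g01", "no_such_cluster", labels),
               class = "modulefish_empty_error")
})

test_that("signal gain matches hand-evaluated general and conservative ratios", {
  # two genes engineered to cluster signals 48 and 24 in the target
  counts <- matrix(c(48, 48, 2, 2,
                     24, 24, 2, 2,
                     28, 28, 96, 96), 3, 4, byrow = TRUE,
                   dimnames = list(c("hi", "lo", "rest"),
                                   c("a1", "a2", "b1", "b2")))
  labels <- c("A", "A", "B", "B")
  v <- normalize_views(gene_expression_reference(counts,
                                                 cell_labels = labels))
  s_hi <- gene_signal(v, "hi", "A", labels)
  s_lo <- gene_signal(v, "lo", "A", labels)
  expect_equal(s_lo / s_hi, 0.5)
  genes <- c("hi", "lo")
  expect_equal(signal_gain(v, genes, "A", labels,
                           reference_gene = "hi", mode = "general"), 1.5)
  expect_equal(signal_gain(v, genes, "A", labels, mode = "conservative"), 1.5)
  expect_equal(signal_gain(v, genes, "A", labels,
                           reference_gene = "lo", mode = "general"), 3)
  # single-gene module: self-ratio 1
  expect_equal(signal_gain(v, "hi", "A", labels, reference_gene = "hi",
                           mode = "general"), 1)
  # conservative <= general when the reference is the max-signal gene
  expect_lte(signal_gain(v, genes, "A", labels, mode = "conservative"),
             signal_gain(v, genes, "A", labels, reference_gene = "hi",
                         mode = "general"))
})

test_that("signal specificity ratio identifies the strongest off-target", {
  counts <- matrix(c(80, 20, 10,
                     80, 20, 10), 2, 3, byrow = TRUE,
                   dimnames = list(c("gx", "gy"), c("t", "o1", "o2")))
  labels <- c("target", "off1", "off2")
  v <- normalize_views(gene_expression_reference(counts,
                                                 cell_labels = labels))
  # cell scaling makes every column identical; rebuild so panel signals are
  # 80 / 20 / 10 per cluster on the cell-scaled matrix
  counts2 <- matrix(c(80, 20, 10,
                      20, 80, 90), 2, 3, byrow = TRUE,
                    dimnames = dimnames(counts))
  v2 <- normalize_views(gene_expression_reference(counts2,
                                                  cell_labels = labels),
                        scale_factor = 100)
  s <- vapply(labels, function(cl) panel_signal(v2, "gx", cl, labels),
              numeric(1))
  expect_equal(unname(s), c(80, 20, 10))
  r <- signal_specificity_ratio(v2, "gx", "target", labels,
                                mode = "conservative")
  expect_equal(r$ssr, 4)
  expect_equal(r$most_likely_off_target, "off1")
  g <- signal_specificity_ratio(v2, "gx", "target", labels, mode = "general")
  expect_equal(g$ssr, 80 / 30)
  expect_lte(g$ssr, r$ssr)

  # module expressed only in the target: infinite SSR
  counts3 <- matrix(c(50, 0, 0,
                      50, 100, 100), 2, 3, byrow = TRUE,
                    dimnames = dimnames(counts))
  v3 <- normalize_views(gene_expression_reference(counts3,
                                                  cell_labels = labels))
  expect_equal(signal_specificity_ratio(v3, "gx", "target", labels)$ssr, Inf)

  # SSR = 1 at the indistinguishability point
  counts4 <- matrix(c(40, 40, 10,
                      60, 60, 90), 2, 3, byrow = TRUE,
                    dimnames = dimnames(counts))
  v4 <- normalize_views(gene_expression_reference(counts4,
                                                  cell_labels = labels))
  expect_equal(signal_specificity_ratio(v4, "gx", "target", labels)$ssr, 1)

  expect_error(
    signal_specificity_ratio(v2, "gx", "target", rep("target", 3)),
    class = "modulefish_empty_error")
})

test_that("module_cell_matrix is the per-cell sum of module genes", {
  rr <- random_reference(n_genes = 8, n_cells = 20, seed = 3)
  v <- normalize_views(rr)
  panel <- gene_panel(rownames(rr$counts),
                      rep(c("M1", "M2"), each = 4))
  mcm <- module_cell_matrix(v, panel)
  # brute force per cell
  for (cell in c(1, 7, 20)) {
    expect_equal(mcm["M1", cell],
                 sum(v$cell_scaled[panel$gene[panel$module == "M1"], cell]))
  }
  # single-gene module equals that gene's row
  p1 <- gene_panel("g01", "solo")
  expect_equal(module_cell_matrix(v, p1)["solo", ],
               v$cell_scaled["g01", ])
  # disjoint modules covering all genes conserve the scale factor
  expect_true(all(abs(colSums(mcm) - v$scale_factor) < 1e-9))
  # missing genes are reported
  expect_error(module_cell_matrix(v, gene_panel("nope", "M9")),
               "nope", class = "modulefish_missing_gene_error")
})

test_that("panel signals scale with probe counts while SG and SSR stay invariant", {
  sim <- small_sim(n_cells = 300, seed = 4)
  v <- normalize_views(sim$reference)
  labels <- sim$reference$cell_labels
  genes <- names(sim$truth$module_membership)[
    which(sim$truth$module_membership == "M1")]
  k <- seq_along(genes)
  base_sig <- panel_signal(v, genes, "type1", labels, k)
  expect_equal(panel_signal(v, genes, "type1", labels, 3 * k), 3 * base_sig)
  expect_equal(
    signal_gain(v, genes, "type1", labels, k = 3 * k, mode = "conservative"),
    signal_gain(v, genes, "type1", labels, k = k, mode = "conservative"))
  r1 <- signal_specificity_ratio(v, genes, "type1", labels, k = k)
  r3 <- signal_specificity_ratio(v, genes, "type1", labels, k = 3 * k)
  expect_equal(r1$ssr, r3$ssr)
})

test_that("score_panel agrees with brute-force recomputation from scaled counts", {
  sim <- small_sim(n_cells = 300, seed = 9)
  v <- normalize_views(sim$reference)
  labels <- sim$reference$cell_labels
  mem <- sim$truth$module_membership
  panel <- gene_panel(names(mem)[!is.na(mem)], mem[!is.na(mem)],
                      target_label = sub("M", "type", mem[!is.na(mem)]))
  sc <- score_panel(v, panel, labels)
  for (i in seq_len(nrow(sc))) {
    genes <- panel$gene[panel$module == sc$module[i]]
    per_cluster <- vapply(unique(labels), function(cl)
      sum(rowMeans(v$cell_scaled[genes, labels == cl, drop = FALSE])),
      numeric(1))
    tgt <- sc$target[i]
    expect_equal(sc$signal_target[i], unname(per_cluster[tgt]),
                 tolerance = 1e-9)
    expect_equal(sc$sg_conservative[i],
                 unname(per_cluster[tgt]) /
                   max(rowMeans(v$cell_scaled[genes, labels == tgt,
                                              drop = FALSE])),
                 tolerance = 1e-9)
    expect_equal(sc$ssr_conservative[i],
                 unname(per_cluster[tgt] /
                          max(per_cluster[names(per_cluster) != tgt])),
                 tolerance = 1e-9)
  }
  gl <- glance(sc)
  expect_equal(gl$min_ssr_conservative, min(sc$ssr_conservative))
})

test_that("adjusted_rand_index matches the pair-counting oracle and known values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # exhaustive agreement over all labelings of <= 6 items (3 symbols)
  set.seed(1)
  for (n in c(4, 5, 6)) {
    for (rep in 1:40) {
      a <- sample(1:3, n, replace = TRUE)
      b <- sample(1:3, n, replace = TRUE)
      if (length(unique(a)) == 1 && length(unique(b)) == 1) next
      expect_equal(adjusted_rand_index(a, b), pair_count_ari(a, b))
    }
  }
  expect_error(adjusted_rand_index(1:3, 1:4))
})

test_that("adjusted_rand_index agrees with the reference implementation", {
  set.seed(2)
  for (rep in 1:25) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
})

test_that("simulate_clustering recovers planted separation on the meta-gene matrix", {
  sim <- small_sim(n_cells = 400, seed = 6)
  v <- normalize_views(sim$reference)
  mem <- sim$truth$module_membership
  panel <- gene_panel(names(mem)[!is.na(mem)], mem[!is.na(mem)])
  mcm <- module_cell_matrix(v, panel)
  cl <- simulate_clustering(mcm, n_pcs = 4, n_neighbors = 15,
                            resolution = 0.1, seed = 1)
  expect_equal(adjusted_rand_index(cl, sim$truth$cell_type_labels), 1)
  # deterministic under a fixed seed
  cl2 <- simulate_clustering(mcm, n_pcs = 4, n_neighbors = 15,
                             resolution = 0.1, seed = 1)
  expect_identical(as.integer(cl), as.integer(cl2))
  # n_pcs above the module count is clipped with a warning
  expect_warning(simulate_clustering(mcm, n_pcs = 10, n_neighbors = 15,
                                     resolution = 0.1, seed = 1),
                 "clipped")
})

test_that("vanishing resolution collapses a connected dataset to one community", {
  set.seed(3)
  x <- matrix(rnorm(60 * 3), 60, 3)  # one homogeneous blob
  cl <- cluster_cells(x, resolution = 1e-6, n_pcs = 3, n_neighbors = 10,
                      seed = 1)
  expect_equal(length(unique(cl$cluster)), 1)
})

test_that("hvg_baseline ranks planted high-variance genes ahead of constants", {
  # background genes share the module genes' marginal mean, so ranking must
  # come from excess variance at fixed mean (what the vst statistic measures)
  cfg <- sim_config(400, 80, 4, modules = sim_modules(4, 12, 8),
                    baseline_mean = 2, background_mean = 2 * (1 + 0.25 * 7),
                    dispersion = 10, seed = 8)
  sim <- simulate_reference(cfg)
  v <- normalize_views(sim$reference)
  planted <- names(sim$truth$module_membership)[
    !is.na(sim$truth$module_membership)]
  top <- hvg_baseline(v, n_hvg = 48)
  expect_gte(mean(planted %in% top), 0.9)
  # full-set request returns every gene
  expect_setequal(hvg_baseline(v, n_hvg = nrow(v$cell_scaled)), v$gene_ids)

  # constant gene (constant after cell scaling: equal column totals) is last
  set.seed(4)
  n_cells <- 25
  counts <- matrix(rpois(30 * n_cells, 50), 30, n_cells)
  flat <- rep(10, n_cells)
  filler <- max(colSums(counts) + flat) - colSums(counts) - flat
  m <- rbind(counts, flat, filler)
  rownames(m) <- c(paste0("g", 1:30), "flat", "filler")
  v2 <- normalize_views(gene_expression_reference(m, rownames(m),
                                                  paste0("c", seq_len(n_cells))))
  expect_true(all(abs(v2$cell_scaled["flat", ] -
                        v2$cell_scaled["flat", 1]) < 1e-9))
  ranked <- hvg_baseline(v2, n_hvg = 32)
  expect_equal(ranked[32], "flat")
})
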
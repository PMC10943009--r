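# Shared fixture builders; everything is generated in code at test time.

# Tiny reference with known counts.
tiny_reference <- function() {
  counts <- matrix(c(1, 3,
                     3, 1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), c("c1", "c2")))
  gene_expression_reference(counts)
}

# Random reference: n_genes x n_cells Poisson counts with labelled cells.
random_reference <- function(n_genes = 12, n_cells = 30, n_types = 3,
                             seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, lambda = 5) + 1L,
                   n_genes, n_cells,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("c%02d", seq_len(n_cells))))
  gene_expression_reference(
    counts, cell_labels = rep_len(paste0("t", seq_len(n_types)), n_cells))
}

# Latent-factor expression views: genes in `blocks` share a per-cell factor
# so their pairwise correlation is controlled and high. A constant ballast
# gene dominates the per-cell totals, keeping cell scaling from inducing
# compositional correlations between unrelated genes.
factor_views <- function(blocks, n_cells = 200, noise = 0.3, seed = 1,
                         base = 50) {
  set.seed(seed)
  genes <- unlist(blocks)
  vals <- matrix(0, length(genes), n_cells,
                 dimnames = list(genes, sprintf("c%03d", seq_len(n_cells))))
  for (b in seq_along(blocks)) {
    f <- rnorm(n_cells)
    for (g in blocks[[b]]) {
      vals[g, ] <- f + rnorm(n_cells, sd = noise)
    }
  }
  counts <- rbind(round(base * exp(vals / 2)),
                  ballast = rep(200L * length(genes), n_cells))
  ref <- gene_expression_reference(counts, rownames(counts), colnames(vals))
  normalize_views(ref)
}

# Standard small simulated study used by several tests: 4 planted types,
# 4 modules of 12 genes at fold change 8 on a housekeeping background.
small_sim <- function(n_cells = 600, seed = 3) {
  cfg <- sim_config(n_cells, 80, 4, modules = sim_modules(4, 12, 8),
                    baseline_mean = 2, background_mean = 8,
                    dispersion = 10, seed = seed)
  simulate_reference(cfg)
}

# Exhaustive two-sided rank-sum p-value by permutation of group assignment.
exact_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  idx <- utils::combn(n, length(x))
  obs <- sum(rank(all_v)[seq_along(x)])
  stats <- apply(idx, 2, function(i) sum(rank(all_v)[i]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Direct pair-counting Rand index adjustment (independent ARI oracle).
pair_count_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  np <- n11 + n10; nq <- n11 + n01; tot <- choose(n, 2)
  exp_idx <- np * nq / tot
  max_idx <- (np + nq) / 2
  if (max_idx == exp_idx) return(1)
  (n11 - exp_idx) / (max_idx - exp_idx)
}
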
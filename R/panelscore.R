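#' Predicted signal of one gene in one cell cluster
#'
#' The probe-weighted signal: `k * mean(cell-scaled expression of the gene
#' over the cluster's cells)`.
#'
#' @param views A [normalize_views()] result.
#' @param gene Gene id.
#' @param cluster Cluster label.
#' @param labels Per-cell labels (default: stored in `views`).
#' @param k Probes per gene.
#' @return Scaled-count signal (numeric scalar).
#' @export
gene_signal <- function(views, gene, cluster, labels = views$cell_labels,
                        k = 1) {
  abort_if(!gene %in% views$gene_ids, sprintf("gene %s not in reference", gene),
           class = "modulefish_missing_gene_error")
  in_cl <- labels == cluster
  abort_if(!any(in_cl), sprintf("cluster %s is empty", cluster),
           class = "modulefish_empty_error")
  k * mean(views$cell_scaled[gene, in_cl])
}

#' Predicted signal of a panel module in one cell cluster
#'
#' Sum of [gene_signal()] over the module's genes.
#'
#' @param views A [normalize_views()] result.
#' @param genes Character vector of gene ids.
#' @param cluster Cluster label.
#' @param labels Per-cell labels.
#' @param k Probes per gene (scalar or per-gene vector aligned with `genes`).
#' @return Scaled-count signal (numeric scalar).
#' @export
panel_signal <- function(views, genes, cluster, labels = views$cell_labels,
                         k = 1) {
  k <- rep_len(k, length(genes))
  sum(vapply(seq_along(genes), function(i) {
    gene_signal(views, genes[i], cluster, labels, k[i])
  }, numeric(1)))
}

#' Signal Gain of a module in its target cluster
#'
#' General mode: ratio of the panel signal to the signal of the reference
#' gene. Conservative mode: ratio of the panel signal to the highest single-
#' gene signal in the module (so the gain can never be inflated by a weak
#' reference choice). General SG fits marker-anchored (cell-centric) panels;
#' conservative SG is the safer default for module panels.
#'
#' @param views A [normalize_views()] result.
#' @param genes Module gene ids.
#' @param cluster Target cluster label.
#' @param labels Per-cell labels.
#' @param k Probes per gene (scalar or per-gene).
#' @param reference_gene Required in general mode; must be in `genes`.
#' @param mode `"general"` or `"conservative"`.
#' @return Dimensionless SG.
#' @export
signal_gain <- function(views, genes, cluster, labels = views$cell_labels,
                        k = 1, reference_gene = NULL,
                        mode = c("conservative", "general")) {
  mode <- match.arg(mode)
  k <- rep_len(k, length(genes))
  sig <- vapply(seq_along(genes), function(i) {
    gene_signal(views, genes[i], cluster, labels, k[i])
  }, numeric(1))
  denom <- if (mode == "general") {
    abort_if(is.null(reference_gene) || !reference_gene %in% genes,
             "general SG needs a reference_gene inside the module")
    sig[match(reference_gene, genes)]
  } else {
    max(sig)
  }
  abort_if(denom == 0, "SG undefined: zero denominator signal",
           class = "modulefish_undefined_error")
  sum(sig) / denom
}

#' Signal Specificity Ratio of a module
#'
#' Ratio of the module's panel signal in the target cluster to its signal
#' off-target: conservative mode uses the single strongest off-target cluster
#' (the most likely crosstalk partner, which is reported), general mode the
#' sum over all off-target clusters. An SSR near 1 means the target is
#' indistinguishable from its best off-target; all-zero off-target signal
#' gives `Inf`.
#'
#' @param views A [normalize_views()] result.
#' @param genes Module gene ids.
#' @param target Target cluster label.
#' @param labels Per-cell labels.
#' @param k Probes per gene.
#' @param mode `"conservative"` (default) or `"general"`.
#' @param exclude_clusters Cluster labels left out of the off-target set
#'   (e.g. unannotated cells).
#' @return List with `ssr` and `most_likely_off_target`.
#' @export
signal_specificity_ratio <- function(views, genes, target,
                                     labels = views$cell_labels, k = 1,
                                     mode = c("conservative", "general"),
                                     exclude_clusters = NULL) {
  mode <- match.arg(mode)
  clusters <- setdiff(unique(labels), exclude_clusters)
  abort_if(length(clusters) < 2, "at least two clusters are required",
           class = "modulefish_empty_error")
  sig <- vapply(clusters, function(cl) {
    panel_signal(views, genes, cl, labels, k)
  }, numeric(1))
  names(sig) <- clusters
  off <- sig[setdiff(clusters, target)]
  off_max <- names(off)[which.max(off)]
  denom <- if (mode == "conservative") max(off) else sum(off)
  ssr <- if (denom == 0) Inf else sig[[target]] / denom
  list(ssr = ssr, most_likely_off_target = off_max)
}

#' Score every module of a panel against every cluster
#'
#' Computes the full per-module score table: panel signal in the target,
#' general and conservative Signal Gain, general and conservative Signal
#' Specificity Ratio and the most likely off-target cluster. The target of a
#' module is its `target_label`; modules without one are scored against every
#' cluster and the best (max signal) cluster is used as target.
#'
#' @param views A [normalize_views()] result.
#' @param panel A [gene_panel()].
#' @param labels Per-cell labels.
#' @param exclude_clusters Passed to [signal_specificity_ratio()].
#' @return A `panel_score` tibble: one row per module with columns `module`,
#'   `target`, `n_genes`, `signal_target`, `sg_general`, `sg_conservative`,
#'   `ssr_general`, `ssr_conservative`, `off_target`.
#' @export
score_panel <- function(views, panel, labels = views$cell_labels,
                        exclude_clusters = NULL) {
  abort_if(is.null(labels), "cluster labels are required")
  clusters <- setdiff(unique(labels), exclude_clusters)
  mods <- unique(panel$module)
  rows <- lapply(mods, function(m) {
    sub <- panel[panel$module == m, ]
    target <- sub$target_label[1]
    sig_by_cluster <- vapply(clusters, function(cl) {
      panel_signal(views, sub$gene, cl, labels, sub$probes)
    }, numeric(1))
    names(sig_by_cluster) <- clusters
    if (is.na(target) || !target %in% clusters) {
      target <- names(sig_by_cluster)[which.max(sig_by_cluster)]
    }
    ref_gene <- if (any(sub$is_reference)) sub$gene[sub$is_reference][1]
    sg_gen <- if (!is.null(ref_gene)) {
      signal_gain(views, sub$gene, target, labels, sub$probes,
                  reference_gene = ref_gene, mode = "general")
    } else {
      NA_real_
    }
    sg_con <- signal_gain(views, sub$gene, target, labels, sub$probes,
                          mode = "conservative")
    ssr_con <- signal_specificity_ratio(views, sub$gene, target, labels,
                                        sub$probes, mode = "conservative",
                                        exclude_clusters = exclude_clusters)
    ssr_gen <- signal_specificity_ratio(views, sub$gene, target, labels,
                                        sub$probes, mode = "general",
                                        exclude_clusters = exclude_clusters)
    tibble::tibble(module = m, target = target, n_genes = nrow(sub),
                   signal_target = unname(sig_by_cluster[target]),
                   sg_general = sg_gen, sg_conservative = sg_con,
                   ssr_general = ssr_gen$ssr, ssr_conservative = ssr_con$ssr,
                   off_target = ssr_con$most_likely_off_target)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("panel_score", class(out))
  out
}

#' Module-cell (meta-gene) matrix
#'
#' Entry `(m, c)` is the sum of cell-scaled counts of module `m`'s genes in
#' cell `c` — what an idealized module-FISH measurement of the reference
#' would look like. Probe counts are deliberately not applied here; this is
#' the expression meta-gene used for simulated re-clustering.
#'
#' @param views A [normalize_views()] result.
#' @param panel A [gene_panel()]; every panel gene must be in the reference.
#' @return Modules x cells matrix.
#' @export
module_cell_matrix <- function(views, panel) {
  missing <- setdiff(panel$gene, views$gene_ids)
  if (length(missing) > 0) {
    rlang::abort(sprintf("panel gene(s) absent from reference: %s",
                         paste(missing, collapse = ", ")),
                 class = "modulefish_missing_gene_error")
  }
  mods <- panel_module_genes(panel)
  out <- t(vapply(mods, function(genes) {
    if (length(genes) == 1L) views$cell_scaled[genes, ]
    else colSums(views$cell_scaled[genes, , drop = FALSE])
  }, numeric(ncol(views$cell_scaled))))
  rownames(out) <- names(mods)
  colnames(out) <- views$cell_ids
  out
}

#' Simulate module-level re-clustering of the reference
#'
#' Treats the module-cell matrix as a meta-gene expression matrix and applies
#' the conventional single-cell clustering chain: z-scale the modules,
#' principal components, k-nearest-neighbour graph, modularity-based
#' community detection. Comparing the resulting labels with the reference
#' annotation (via [adjusted_rand_index()]) predicts how well a module-FISH
#' experiment could recover the known cell types.
#'
#' @param mcm Modules x cells matrix from [module_cell_matrix()].
#' @param n_pcs Principal components kept (clipped to the module count with a
#'   warning).
#' @param n_neighbors k of the kNN graph.
#' @param resolution Community-detection resolution.
#' @param seed Integer seed.
#' @param algorithm `"louvain"` (default) or `"leiden"`.
#' @return Integer cluster label per cell (named by cell id).
#' @export
simulate_clustering <- function(mcm, n_pcs = 10, n_neighbors = 20,
                                resolution = 0.8, seed = 1L,
                                algorithm = c("louvain", "leiden")) {
  algorithm <- match.arg(algorithm)
  cluster_feature_matrix(t(mcm), n_pcs = n_pcs, n_neighbors = n_neighbors,
                         resolution = resolution, seed = seed,
                         algorithm = algorithm)
}

#' Adjusted Rand Index between two labelings
#'
#' Permutation-model-adjusted Rand index computed from the contingency table:
#' 1 for identical partitions (up to label renaming), ~0 for independent
#' ones, negative for less-than-chance agreement.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  abort_if(length(labels_a) != length(labels_b),
           "labelings must have equal length")
  abort_if(length(labels_a) < 2, "need at least two items")
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Highly variable genes baseline
#'
#' Ranks genes by variance-stabilized standardized variance: a loess trend of
#' log10(variance) against log10(mean) predicts each gene's expected standard
#' deviation; values are standardized against it, clipped at `sqrt(n_cells)`,
#' and the variance of the clipped standardized values ranks the genes. The
#' top `n_hvg` simulate a conventional gene-by-gene multiplexed FISH assay.
#'
#' @param views A [normalize_views()] result (counts taken from
#'   `cell_scaled`).
#' @param n_hvg Number of genes returned.
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of the top `n_hvg` gene ids.
#' @export
hvg_baseline <- function(views, n_hvg = 1000, loess_span = 0.3) {
  x <- views$cell_scaled
  abort_if(n_hvg > nrow(x), "n_hvg exceeds the gene count")
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  std_var <- rep(0, nrow(x))
  usable <- v > 0 & mu > 0
  if (sum(usable) > 1) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                        span = loess_span, degree = 2)
    exp_sd <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(ncol(x))
    xs <- x[usable, , drop = FALSE]
    z <- (xs - mu[usable]) / exp_sd
    z[z > clip] <- clip
    std_var[usable] <- apply(z, 1, stats::var)
  }
  views$gene_ids[order(-std_var, views$gene_ids)][seq_len(n_hvg)]
}
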
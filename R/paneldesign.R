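#' Gene panel container
#'
#' A gene panel is a tibble with one row per (gene, module): columns `gene`,
#' `module`, `probes` (probes per gene, `k >= 1`), `is_reference`,
#' `target_label` and `strategy`. Within a module genes are unique;
#' cell-centric panels additionally keep genes unique across the whole panel.
#'
#' @param gene,module Character vectors (recycled as usual).
#' @param probes Integer probes per gene (>= 1).
#' @param is_reference Logical; reference marker rows.
#' @param target_label Optional cell-type label the module targets.
#' @param strategy Design strategy tag.
#' @return A `gene_panel` tibble.
#' @export
gene_panel <- function(gene, module, probes = 1L, is_reference = FALSE,
                       target_label = NA_character_, strategy = "manual") {
  out <- tibble::tibble(gene = as.character(gene),
                        module = as.character(module),
                        probes = as.integer(probes),
                        is_reference = is_reference,
                        target_label = as.character(target_label),
                        strategy = strategy)
  abort_if(any(out$probes < 1), "probes per gene must be >= 1")
  dup <- duplicated(out[, c("gene", "module")])
  abort_if(any(dup), "duplicate gene within a module")
  class(out) <- c("gene_panel", class(out))
  out
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes in %d modules (%s)\n",
              dplyr::n_distinct(x$gene), dplyr::n_distinct(x$module),
              paste(unique(x$strategy), collapse = ", ")))
  NextMethod()
}

panel_module_genes <- function(panel) {
  split(panel$gene, panel$module)
}

#' Read / write gene panels as CSV
#'
#' @param path CSV path.
#' @return `read_gene_panel()` a `gene_panel`; `write_gene_panel()` `path`,
#'   invisibly.
#' @export
read_gene_panel <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  gene_panel(tab$gene, tab$module,
             probes = tab$probes %||% 1L,
             is_reference = tab$is_reference %||% FALSE,
             target_label = tab$target_label %||% NA_character_,
             strategy = tab$strategy %||% "manual")
}

#' @rdname read_gene_panel
#' @param panel A `gene_panel`.
#' @export
write_gene_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Gene-gene Pearson correlation matrix
#'
#' Correlation of gene expression vectors across cells. Zero-variance genes
#' get correlation 0 to everything (with a warning) rather than `NA`, so the
#' matrix stays usable as a graph weight matrix.
#'
#' @param mat Genes x cells matrix (typically the log view or the binarized
#'   matrix, depending on the design strategy).
#' @param gene_subset Optional gene ids/indices to restrict to.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(mat, gene_subset = NULL) {
  if (!is.null(gene_subset)) mat <- mat[gene_subset, , drop = FALSE]
  abort_if(ncol(mat) < 2, "at least two cells are required")
  sdv <- apply(mat, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(mat)))
  if (any(sdv == 0)) {
    rlang::warn(sprintf("%d zero-variance gene(s); their correlations set to 0",
                        sum(sdv == 0)))
    cc[sdv == 0, ] <- 0
    cc[, sdv == 0] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Cell-centric panel from reference markers
#'
#' For every target cell type, selects genes whose Pearson correlation (on the
#' log view) to any of the type's reference markers exceeds `corr_threshold`.
#' If fewer than `fallback_top` genes qualify, the top `fallback_top` genes by
#' correlation are taken instead. Genes selected by more than one target are
#' then removed from the final panel entirely; reference markers always remain
#' in their own module.
#'
#' @param views A [normalize_views()] result.
#' @param labels Per-cell labels (unused for selection itself, recorded as
#'   the targets; kept for interface symmetry and validation).
#' @param reference_markers Named list: target type -> character vector of
#'   marker gene ids.
#' @param corr_threshold Correlation cut-off for inclusion.
#' @param fallback_top Genes taken by rank when too few pass the cut-off.
#' @return A [gene_panel()] with one module per target.
#' @export
cell_centric_panel <- function(views, labels = views$cell_labels,
                               reference_markers,
                               corr_threshold = 0.5, fallback_top = 15) {
  markers <- unlist(reference_markers)
  missing <- setdiff(markers, views$gene_ids)
  if (length(missing) > 0) {
    rlang::abort(sprintf("reference marker(s) not in reference: %s",
                         paste(missing, collapse = ", ")),
                 class = "modulefish_missing_gene_error")
  }
  lv <- views$log_view
  # correlation of every gene to each marker, computed in one pass
  marker_cor <- suppressWarnings(stats::cor(t(lv), t(lv[markers, , drop = FALSE])))
  marker_cor[is.na(marker_cor)] <- 0
  colnames(marker_cor) <- markers

  selections <- lapply(names(reference_markers), function(target) {
    mk <- reference_markers[[target]]
    best <- apply(marker_cor[, mk, drop = FALSE], 1, max)
    hits <- names(best)[best > corr_threshold]
    hits <- setdiff(hits, mk)
    if (length(hits) < fallback_top) {
      ranked <- names(sort(best[setdiff(names(best), mk)], decreasing = TRUE))
      hits <- ranked[seq_len(min(fallback_top, length(ranked)))]
    }
    tibble::tibble(gene = c(mk, hits), module = target,
                   is_reference = c(rep(TRUE, length(mk)),
                                    rep(FALSE, length(hits))))
  })
  sel <- dplyr::bind_rows(selections)
  dup_genes <- sel$gene[duplicated(sel$gene)]
  sel <- sel[!(sel$gene %in% dup_genes & !sel$is_reference), ]
  gene_panel(sel$gene, sel$module, is_reference = sel$is_reference,
             target_label = sel$module, strategy = "cell_centric")
}

#' Candidate feature genes from a correlation matrix
#'
#' Keeps genes correlated above `min_corr` with at least `min_partners` other
#' genes.
#'
#' @param corr_matrix Output of [pearson_matrix()].
#' @param min_corr Partner correlation cut-off (strict `>`).
#' @param min_partners Minimum number of qualifying partners.
#' @return Character vector of candidate gene ids.
#' @export
feature_gene_candidates <- function(corr_matrix, min_corr = 0.7,
                                    min_partners = 5) {
  cc <- corr_matrix
  diag(cc) <- -Inf
  partners <- rowSums(cc > min_corr)
  rownames(corr_matrix)[partners >= min_partners]
}

#' Gene modules by Leiden partitioning of the correlation graph
#'
#' Builds a graph whose nodes are the genes of `corr_matrix` and whose edges
#' are correlations at or above `edge_threshold`, then partitions it with the
#' Leiden algorithm (modularity objective, correlation edge weights).
#' Isolated genes become singleton communities.
#'
#' @param corr_matrix Output of [pearson_matrix()] (usually restricted to
#'   [feature_gene_candidates()]).
#' @param edge_threshold Edges below this correlation are removed.
#' @param resolution Leiden resolution parameter.
#' @param seed Integer seed (partition is deterministic given it).
#' @param objective `"modularity"` (default) or `"CPM"`.
#' @return Tibble with columns `gene`, `module` (`"M1"`, `"M2"`, ... by
#'   decreasing size).
#' @export
leiden_modules <- function(corr_matrix, edge_threshold = 0.6,
                           resolution = 1, seed = 1L,
                           objective = "modularity") {
  abort_if(nrow(corr_matrix) == 0, "empty correlation graph",
           class = "modulefish_empty_error")
  adj <- corr_matrix
  adj[adj < edge_threshold] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  part <- igraph::cluster_leiden(g, objective_function = objective,
                                 weights = igraph::E(g)$weight,
                                 resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(part)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(paste0("M", seq_along(sizes)), names(sizes))
  tibble::tibble(gene = rownames(corr_matrix),
                 module = unname(relabel[as.character(memb)]))
}

# Size-dependent dendrogram cut count: >30 genes -> 6; 11-30 -> 4; 6-10 -> 2;
# <6 -> 1 (returned intact).
subcluster_k <- function(n_genes) {
  if (n_genes > 30) 6L else if (n_genes > 10) 4L else if (n_genes > 5) 2L else 1L
}

#' Hierarchically sub-cluster a gene module
#'
#' Average-linkage hierarchical clustering of the genes' log-expression
#' vectors on correlation distance (1 - r), with the dendrogram cut into `k`
#' parts following a size rule (above 30 genes: k = 6; 11-30: k = 4; 6-10:
#' k = 2; below 6: returned intact); single-gene subclusters are removed
#' afterwards.
#'
#' @param module_genes Character vector of gene ids.
#' @param log_view Genes x cells log-expression matrix containing them.
#' @return List of character vectors (the subclusters, singletons dropped).
#' @export
hierarchical_subcluster <- function(module_genes, log_view) {
  abort_if(!all(module_genes %in% rownames(log_view)),
           "module genes missing from log_view")
  k <- subcluster_k(length(module_genes))
  if (k == 1L) return(list(module_genes))
  cc <- suppressWarnings(stats::cor(t(log_view[module_genes, , drop = FALSE])))
  cc[is.na(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cut <- stats::cutree(hc, k = k)
  subs <- split(module_genes, cut)
  unname(subs[lengths(subs) > 1])
}

#' Panel from factor-loading (gene expression program) matrices
#'
#' For every program (column of the non-negative loading matrix) the `top_n`
#' highest positive-loading genes are taken (a gene topping several programs
#' is assigned to its highest-loading one); nomenclature-filtered names are
#' dropped. Genes correlated across programs — shared major-cell-type
#' markers — are then pruned iteratively: while any cross-program pair
#' exceeds `corr_high` (signed Pearson on the log view), the gene least tied
#' to its own program among the worst-offending pair is removed, so one leaky
#' gene cannot eliminate a whole program. Genes whose maximum within-program
#' correlation falls below `corr_low` (unconnected genes) are removed, and
#' survivors are split into one or more modules per program by hierarchical
#' clustering ([hierarchical_subcluster()]).
#'
#' @param loadings Genes x programs non-negative matrix with dimnames.
#' @param views A [normalize_views()] result sharing gene ids.
#' @param top_n Genes taken per program by loading.
#' @param corr_low,corr_high Within-program floor and cross-program ceiling on
#'   signed Pearson correlation (log view).
#' @param name_filter Apply [gene_name_filter()] with its defaults.
#' @return A [gene_panel()] with modules named `<program>.<part>`.
#' @export
nmf_program_modules <- function(loadings, views, top_n = 50,
                                corr_low = 0.02, corr_high = 0.3,
                                name_filter = TRUE) {
  abort_if(any(loadings < 0), "factor loadings must be non-negative")
  shared <- intersect(rownames(loadings), views$gene_ids)
  abort_if(length(shared) == 0, "loadings and views share no gene ids")
  loadings <- loadings[shared, , drop = FALSE]
  programs <- colnames(loadings) %||% paste0("P", seq_len(ncol(loadings)))
  colnames(loadings) <- programs

  top_genes <- lapply(programs, function(p) {
    contributing <- rownames(loadings)[loadings[, p] > 0]
    ranked <- contributing[order(-loadings[contributing, p])]
    ranked[seq_len(min(top_n, length(ranked)))]
  })
  names(top_genes) <- programs
  if (name_filter) top_genes <- lapply(top_genes, gene_name_filter)

  # a gene topping several programs belongs to its highest-loading program
  assign <- unlist(lapply(programs, function(p) {
    stats::setNames(rep(p, length(top_genes[[p]])), top_genes[[p]])
  }))
  dup <- unique(names(assign)[duplicated(names(assign))])
  if (length(dup) > 0) {
    resolved <- vapply(dup, function(g) programs[which.max(loadings[g, ])],
                       character(1))
    assign <- c(assign[!(names(assign) %in% dup)], resolved)
  }
  genes <- names(assign)
  cc <- pearson_matrix(views$log_view, genes)

  within_max <- function(g, cur) {
    own <- setdiff(cur[assign[cur] == assign[[g]]], g)
    if (length(own) == 0) 1 else max(cc[g, own])
  }
  # iterative cross-program pruning
  repeat {
    cross <- vapply(genes, function(g) {
      others <- genes[assign[genes] != assign[[g]]]
      if (length(others) == 0) -Inf else max(cc[g, others])
    }, numeric(1))
    if (all(cross <= corr_high)) break
    worst <- genes[cross == max(cross)]
    w_within <- vapply(worst, within_max, numeric(1), cur = genes)
    drop <- worst[order(w_within, worst)][1]
    genes <- setdiff(genes, drop)
  }
  # within-program floor
  genes <- genes[vapply(genes, within_max, numeric(1), cur = genes) >=
                   corr_low]

  rows <- list()
  for (p in programs) {
    pg <- genes[assign[genes] == p]
    if (length(pg) == 0) {
      rlang::warn(sprintf("program %s has no surviving genes; dropped", p))
      next
    }
    subs <- hierarchical_subcluster(pg, views$log_view)
    if (length(subs) == 0) subs <- list(pg)
    for (s in seq_along(subs)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = subs[[s]],
        module = if (length(subs) == 1) p else sprintf("%s.%d", p, s),
        target_label = p)
    }
  }
  out <- dplyr::bind_rows(rows)
  abort_if(nrow(out) == 0, "no program genes survive",
           class = "modulefish_empty_error")
  gene_panel(out$gene, out$module, target_label = out$target_label,
             strategy = "nmf_program")
}

#' Hybrid panel: DE-seeded correlation modules
#'
#' Per cluster, DE genes are found with [find_de_genes()], mitochondrial-named
#' genes are excluded, and the gene set is greedily pruned: while the minimum
#' entry of the remaining genes' pairwise correlation matrix is at or below
#' `min_pairwise_corr`, the gene whose maximum correlation to the others is
#' lowest is removed. Modules that end up smaller than `min_module_size` are
#' dropped.
#'
#' @param views A [normalize_views()] result.
#' @param labels Per-cell cluster labels.
#' @param max_de,min_log_fc Passed to [find_de_genes()].
#' @param min_pairwise_corr Pruning floor on the minimum pairwise correlation.
#' @param min_module_size Modules smaller than this are excluded.
#' @param name_filter Apply [gene_name_filter()] with its defaults in addition
#'   to the always-on `mt`-prefix exclusion.
#' @return A [gene_panel()] with one module per surviving cluster.
#' @export
hybrid_de_modules <- function(views, labels = views$cell_labels,
                              max_de = 50, min_log_fc = 0.25,
                              min_pairwise_corr = 0.1, min_module_size = 5,
                              name_filter = FALSE) {
  de <- find_de_genes(views, labels, max_genes = max_de,
                      min_log_fc = min_log_fc)
  rows <- list()
  for (cl in unique(de$cluster)) {
    genes <- de$gene[de$cluster == cl]
    genes <- genes[!grepl("^mt", genes, ignore.case = TRUE)]
    if (name_filter) genes <- gene_name_filter(genes)
    if (length(genes) < 2) {
      if (length(genes) == 0) {
        rlang::warn(sprintf("cluster %s: DE list empty; module omitted", cl))
        next
      }
    } else {
      cc <- suppressWarnings(
        stats::cor(t(views$log_view[genes, , drop = FALSE])))
      cc[is.na(cc)] <- 0
      genes <- prune_min_correlation(genes, cc, min_pairwise_corr)
    }
    if (length(genes) < min_module_size) next
    rows[[length(rows) + 1L]] <- tibble::tibble(gene = genes, module = cl)
  }
  out <- dplyr::bind_rows(rows)
  abort_if(nrow(out) == 0, "no modules survive pruning",
           class = "modulefish_empty_error")
  gene_panel(out$gene, out$module, target_label = out$module,
             strategy = "hybrid_de")
}

# Greedy pruning: each iteration removes exactly one gene (the one whose best
# correlation to the rest is weakest), so termination is guaranteed.
prune_min_correlation <- function(genes, cc, floor) {
  while (length(genes) > 2) {
    sub <- cc[genes, genes, drop = FALSE]
    off <- sub[upper.tri(sub)]
    if (min(off) > floor) break
    diag(sub) <- -Inf
    best <- apply(sub, 1, max)
    genes <- genes[-which.min(best)]
  }
  if (length(genes) == 2 && cc[genes[1], genes[2]] <= floor) {
    genes <- character(0)
  }
  genes
}

#' Attach probes-per-gene to a panel
#'
#' @param panel A [gene_panel()].
#' @param probes_per_gene Named integer vector or `data.frame(gene, probes)`
#'   lookup; genes absent from it get `default_k`.
#' @param default_k Fallback probe count (>= 1).
#' @return The panel with its `probes` column replaced.
#' @export
assign_probe_counts <- function(panel, probes_per_gene = NULL, default_k = 1L) {
  abort_if(default_k < 1, "default_k must be >= 1")
  lookup <- if (is.data.frame(probes_per_gene)) {
    stats::setNames(probes_per_gene$probes, probes_per_gene$gene)
  } else {
    probes_per_gene
  }
  k <- rep(as.integer(default_k), nrow(panel))
  if (!is.null(lookup)) {
    abort_if(any(lookup < 1), "probes per gene must be >= 1")
    hit <- panel$gene %in% names(lookup)
    k[hit] <- as.integer(lookup[panel$gene[hit]])
  }
  panel$probes <- k
  panel
}
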
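#' Quality-control filter for cells and genes
#'
#' Removes, in this fixed order: (1) cells whose number of unique expressed
#' genes falls outside `(min_genes_per_cell, max_genes_per_cell)` or whose
#' mitochondrial count fraction exceeds `max_mito_fraction`; then (2) genes
#' expressed in fewer than `min_cells_per_gene` of the remaining cells. Cell
#' filters run before gene filters because gene prevalence changes once cells
#' are dropped. Defaults are the conventional kidney-style thresholds
#' (200/3000 unique genes, 50% mitochondrial, 10 cells).
#'
#' @param ref A [gene_expression_reference()].
#' @param min_genes_per_cell,max_genes_per_cell Unique-gene band; cells with
#'   `< min` or `> max` unique expressed genes are removed.
#' @param max_mito_fraction Cells with mitochondrial fraction above this are
#'   removed.
#' @param min_cells_per_gene Genes expressed in fewer cells than this are
#'   removed.
#' @return Filtered [gene_expression_reference()] with a `qc_summary`
#'   attribute counting each filter's casualties.
#' @export
qc_filter <- function(ref, min_genes_per_cell = 200,
                      max_genes_per_cell = 3000,
                      max_mito_fraction = 0.5,
                      min_cells_per_gene = 10) {
  abort_if(min_genes_per_cell < 0 || min_cells_per_gene < 0 ||
             max_mito_fraction < 0, "thresholds must be non-negative")
  abort_if(min_genes_per_cell >= max_genes_per_cell,
           "min_genes_per_cell must be below max_genes_per_cell")
  counts <- ref$counts
  n_unique <- colSums(counts > 0)
  totals <- colSums(counts)
  mito_frac <- if (any(ref$mito_flags)) {
    colSums(counts[ref$mito_flags, , drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, ncol(counts))
  }
  band_fail <- n_unique < min_genes_per_cell | n_unique > max_genes_per_cell
  mito_fail <- mito_frac > max_mito_fraction
  keep_cells <- !band_fail & !mito_fail
  if (!any(keep_cells)) {
    rlang::abort(
      sprintf(paste0("all cells removed by QC (%d failed the unique-gene ",
                     "band, %d the mitochondrial fraction)"),
              sum(band_fail), sum(mito_fail)),
      class = "modulefish_empty_error")
  }
  counts <- counts[, keep_cells, drop = FALSE]
  prevalence <- rowSums(counts > 0)
  keep_genes <- prevalence >= min_cells_per_gene
  out <- gene_expression_reference(
    counts[keep_genes, , drop = FALSE],
    ref$gene_ids[keep_genes], ref$cell_ids[keep_cells],
    cell_labels = if (!is.null(ref$cell_labels)) ref$cell_labels[keep_cells],
    mito_flags = ref$mito_flags[keep_genes])
  attr(out, "qc_summary") <- c(cells_band = sum(band_fail),
                               cells_mito = sum(mito_fail & !band_fail),
                               genes_prevalence = sum(!keep_genes))
  out
}

#' Build the three normalized views of a count matrix
#'
#' Produces the three matrices downstream analyses consume: `cell_scaled`
#' (every cell's total scaled to `scale_factor`, used for signal prediction),
#' `log_view` (`log(cell_scaled + pseudo_count)`, natural log, used for
#' differential expression and gene-gene correlation), and `gene_scaled`
#' (per-gene standardized to mean 0 / sample variance 1, used for
#' dimensionality reduction; constant genes map to 0).
#'
#' @param ref A [gene_expression_reference()].
#' @param scale_factor Target total counts per cell.
#' @param pseudo_count Added before the log transform.
#' @return A `normalized_views` object (list of the three matrices plus the
#'   parameters and any cell labels carried over from `ref`).
#' @export
normalize_views <- function(ref, scale_factor = 10000, pseudo_count = 1) {
  counts <- ref$counts
  totals <- colSums(counts)
  if (any(totals == 0)) {
    rlang::abort(sprintf("cell(s) with zero total counts: %s",
                         paste(ref$cell_ids[totals == 0], collapse = ", ")),
                 class = "modulefish_zero_cell_error")
  }
  cell_scaled <- sweep(counts, 2, totals, `/`) * scale_factor
  log_view <- log(cell_scaled + pseudo_count)
  mu <- rowMeans(cell_scaled)
  sdv <- apply(cell_scaled, 1, stats::sd)  # sample (n - 1) convention
  gene_scaled <- (cell_scaled - mu) / ifelse(sdv > 0, sdv, 1)
  gene_scaled[sdv == 0, ] <- 0
  structure(list(cell_scaled = cell_scaled, log_view = log_view,
                 gene_scaled = gene_scaled, scale_factor = scale_factor,
                 pseudo_count = pseudo_count,
                 gene_ids = ref$gene_ids, cell_ids = ref$cell_ids,
                 cell_labels = ref$cell_labels),
            class = "normalized_views")
}

#' @export
print.normalized_views <- function(x, ...) {
  cat(sprintf(
    "<normalized_views> %d genes x %d cells (scale_factor %g, pseudo %g)\n",
    nrow(x$cell_scaled), ncol(x$cell_scaled), x$scale_factor, x$pseudo_count))
  invisible(x)
}

#' One-vs-rest differential expression per cluster
#'
#' For every cluster, genes are ranked by the one-vs-rest mean difference on
#' the log view (the log fold-change); genes below `min_log_fc` are dropped
#' and the list truncated at `max_genes`. A two-sided Wilcoxon rank-sum
#' p-value is reported alongside but does not drive the ranking; ties in
#' log fold-change are broken lexicographically by gene id.
#'
#' @param views A [normalize_views()] result.
#' @param labels Per-cell cluster labels (default: labels stored in `views`).
#' @param max_genes Maximum DE genes per cluster.
#' @param min_log_fc Minimum one-vs-rest log fold-change.
#' @return Tibble with columns `cluster`, `gene`, `avg_log_fc`, `p_value`,
#'   `rank`.
#' @export
find_de_genes <- function(views, labels = views$cell_labels,
                          max_genes = 50, min_log_fc = 0.25) {
  abort_if(is.null(labels), "cluster labels are required")
  labels <- as.character(labels)
  tab <- table(labels)
  abort_if(length(tab) < 2, "at least two clusters are required")
  if (any(tab < 2)) {
    rlang::abort(sprintf("cluster(s) with fewer than 2 cells: %s",
                         paste(names(tab)[tab < 2], collapse = ", ")),
                 class = "modulefish_small_cluster_error")
  }
  lv <- views$log_view
  out <- lapply(names(tab), function(cl) {
    in_cl <- labels == cl
    lfc <- rowMeans(lv[, in_cl, drop = FALSE]) -
      rowMeans(lv[, !in_cl, drop = FALSE])
    keep <- which(lfc >= min_log_fc)
    if (length(keep) == 0) return(NULL)
    ord <- keep[order(-lfc[keep], views$gene_ids[keep])]
    ord <- ord[seq_len(min(max_genes, length(ord)))]
    pvals <- vapply(ord, function(g) {
      suppressWarnings(
        stats::wilcox.test(lv[g, in_cl], lv[g, !in_cl])$p.value)
    }, numeric(1))
    tibble::tibble(cluster = cl, gene = views$gene_ids[ord],
                   avg_log_fc = unname(lfc[ord]), p_value = pvals,
                   rank = seq_along(ord))
  })
  dplyr::bind_rows(out)
}

#' Drop genes whose names are uninformative by nomenclature
#'
#' Removes ids that start with one of `drop_prefixes` immediately followed by
#' digits (case-sensitive): the convention that catches mitochondrial (`Mt`),
#' predicted (`Gm`) and ribosomal (`Rp`) gene models. With
#' `immediate_digits = FALSE` a digit anywhere after the prefix suffices.
#'
#' @param gene_ids Character vector.
#' @param drop_prefixes Prefixes to match.
#' @param immediate_digits Require the digit right after the prefix.
#' @return The retained ids.
#' @export
gene_name_filter <- function(gene_ids, drop_prefixes = c("Mt", "Gm", "Rp"),
                             immediate_digits = TRUE) {
  if (length(gene_ids) == 0 || length(drop_prefixes) == 0) return(gene_ids)
  mid <- if (immediate_digits) "" else ".*"
  pat <- sprintf("^(%s)%s[0-9]", paste(drop_prefixes, collapse = "|"), mid)
  gene_ids[!grepl(pat, gene_ids)]
}

#' Binarize expression at the global mean
#'
#' Sets an entry to 1 iff its cell-scaled value strictly exceeds the single
#' global mean of all entries of the cell-scaled matrix.
#'
#' @param views A [normalize_views()] result.
#' @return Binary genes x cells matrix with the threshold used stored in
#'   `attr(, "threshold")`.
#' @export
binarize_expression <- function(views) {
  threshold <- mean(views$cell_scaled)
  out <- (views$cell_scaled > threshold) * 1
  attr(out, "threshold") <- threshold
  out
}

#' Filter genes by expression prevalence
#'
#' Keeps genes expressed (nonzero, or 1 in a binarized matrix) in at least
#' `min_cells` cells and at most `max_fraction` of all cells.
#'
#' @param mat Genes x cells matrix (counts, scaled or binarized).
#' @param min_cells Prevalence floor (cells).
#' @param max_fraction Prevalence ceiling (fraction of cells).
#' @return Character vector of retained gene ids (row names), or retained row
#'   indices when the matrix is unnamed.
#' @export
prevalence_filter <- function(mat, min_cells = 5, max_fraction = 0.8) {
  prevalence <- rowSums(mat > 0)
  keep <- prevalence >= min_cells & prevalence <= max_fraction * ncol(mat)
  if (is.null(rownames(mat))) which(keep) else rownames(mat)[keep]
}
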
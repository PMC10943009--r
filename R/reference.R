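#' Single-cell expression reference
#'
#' Container for a genes-by-cells raw count matrix with gene/cell indices,
#' optional per-cell cluster labels and optional per-gene mitochondrial flags.
#' When `mito_flags` is absent, genes whose id starts with `"mt-"` or `"MT-"`
#' are treated as mitochondrial (standard nomenclature).
#'
#' @param counts Genes x cells matrix of non-negative integers (dense or
#'   `Matrix` sparse).
#' @param gene_ids,cell_ids Unique character indices matching the matrix
#'   dimensions (default: dimnames of `counts`).
#' @param cell_labels Optional per-cell cluster label.
#' @param mito_flags Optional per-gene logical.
#' @return A `gene_expression_reference` object.
#' @export
gene_expression_reference <- function(counts,
                                      gene_ids = rownames(counts),
                                      cell_ids = colnames(counts),
                                      cell_labels = NULL,
                                      mito_flags = NULL) {
  counts <- as_dense_matrix(counts)
  abort_if(is.null(gene_ids) || is.null(cell_ids),
           "gene_ids and cell_ids are required (or set dimnames on counts)")
  abort_if(length(gene_ids) != nrow(counts) ||
             length(cell_ids) != ncol(counts),
           "index lengths must match matrix dimensions")
  abort_if(anyDuplicated(gene_ids) > 0, "duplicate gene ids")
  abort_if(anyDuplicated(cell_ids) > 0, "duplicate cell ids")
  abort_if(any(counts < 0), "counts must be non-negative")
  if (!is.null(cell_labels)) {
    abort_if(length(cell_labels) != ncol(counts),
             "cell_labels must have one entry per cell")
    cell_labels <- as.character(cell_labels)
  }
  mito_flags <- mito_flags %||% grepl("^(mt-|MT-)", gene_ids)
  abort_if(length(mito_flags) != nrow(counts),
           "mito_flags must have one entry per gene")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_labels = cell_labels, mito_flags = mito_flags),
            class = "gene_expression_reference")
}

#' @export
print.gene_expression_reference <- function(x, ...) {
  cat(sprintf("<gene_expression_reference> %d genes x %d cells%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$cell_labels)) "" else
                sprintf(", %d cluster labels",
                        length(unique(x$cell_labels)))))
  invisible(x)
}

#' Read a reference from Matrix Market or dense delimited files
#'
#' `read_reference_mtx()` expects `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#' (first column used) and optionally `labels.tsv` in `dir`.
#' `read_reference_table()` reads a dense genes-by-cells CSV/TSV with gene ids
#' in the first column (set `transpose = TRUE` for cells-by-genes input).
#'
#' @param dir Directory holding the MTX triple.
#' @return A [gene_expression_reference()].
#' @export
read_reference_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)[, 1]
  cells <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)[, 1]
  labels_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(labels_path)) {
    utils::read.table(labels_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[, 1]
  }
  gene_expression_reference(m, genes, cells, cell_labels = labels)
}

#' @rdname read_reference_mtx
#' @param path Delimited file path.
#' @param sep Field separator (`","` or `"\t"`).
#' @param transpose Set `TRUE` when rows are cells.
#' @export
read_reference_table <- function(path, sep = ",", transpose = FALSE) {
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (transpose) m <- t(m)
  gene_expression_reference(m, rownames(m), colnames(m))
}

#' Write a reference as a Matrix Market triple
#'
#' @param ref A [gene_expression_reference()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_mtx <- function(ref, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(ref$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(ref$gene_ids, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ref$cell_ids, file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(ref$cell_labels)) {
    utils::write.table(ref$cell_labels, file.path(dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}
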
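#' Configure a synthetic single-cell reference
#'
#' Builds the configuration object consumed by [simulate_reference()]. The
#' generator plants cell types with negative-binomial counts and co-expressed
#' gene modules: each module's genes share an elevated mean (multiplied by
#' `fold_change`) in the module's target cell type, which makes them mutually
#' correlated across cells — the property module-FISH panel design exploits.
#'
#' @param n_cells,n_genes,n_cell_types Problem dimensions.
#' @param modules Tibble/data frame with columns `module` (id), `genes`
#'   (list-column of gene indices in `1:n_genes`), `target_type` (in
#'   `1:n_cell_types`) and `fold_change` (>= 1). Use [sim_modules()] to build
#'   a regular layout.
#' @param baseline_mean Negative-binomial mean of a module gene outside its
#'   target cell type (counts/cell).
#' @param background_mean Mean of non-module (background/housekeeping) genes;
#'   defaults to `baseline_mean`. Real references mix weak markers with
#'   well-expressed housekeeping genes, so a higher value here reproduces the
#'   global expression mean that mean-thresholded binarization relies on.
#' @param dispersion Negative-binomial size (shape) parameter; variance is
#'   `mu + mu^2 / dispersion`, so the Poisson limit is `dispersion = Inf`.
#' @param cell_type_proportions Probability vector of length `n_cell_types`
#'   (defaults to equal proportions); must sum to 1.
#' @param n_mito_genes Number of genes flagged (and named) as mitochondrial so
#'   QC filters are exercisable.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells, n_genes, n_cell_types,
                       modules,
                       baseline_mean = 2,
                       background_mean = NULL,
                       dispersion = 10,
                       cell_type_proportions = NULL,
                       n_mito_genes = 0,
                       seed = 1L) {
  cell_type_proportions <- cell_type_proportions %||%
    rep(1 / n_cell_types, n_cell_types)
  abort_if(length(cell_type_proportions) != n_cell_types,
           "cell_type_proportions must have one entry per cell type",
           class = "modulefish_config_error")
  abort_if(abs(sum(cell_type_proportions) - 1) > 1e-9,
           "cell_type_proportions must sum to 1",
           class = "modulefish_config_error")
  abort_if(any(cell_type_proportions < 0),
           "cell_type_proportions must be non-negative",
           class = "modulefish_config_error")
  modules <- tibble::as_tibble(modules)
  abort_if(!all(c("module", "genes", "target_type", "fold_change") %in%
                  names(modules)),
           "modules needs columns module, genes, target_type, fold_change",
           class = "modulefish_config_error")
  abort_if(any(lengths(modules$genes) == 0), "empty module gene set",
           class = "modulefish_config_error")
  gene_idx <- unlist(modules$genes)
  abort_if(any(gene_idx < 1 | gene_idx > n_genes),
           "module gene indices outside 1:n_genes",
           class = "modulefish_config_error")
  abort_if(any(modules$fold_change < 1), "fold_change must be >= 1",
           class = "modulefish_config_error")
  abort_if(any(modules$target_type < 1 | modules$target_type > n_cell_types),
           "module target_type outside 1:n_cell_types",
           class = "modulefish_config_error")
  abort_if(baseline_mean <= 0 || dispersion <= 0,
           "baseline_mean and dispersion must be positive",
           class = "modulefish_config_error")
  background_mean <- background_mean %||% baseline_mean
  abort_if(background_mean <= 0, "background_mean must be positive",
           class = "modulefish_config_error")
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_cell_types = as.integer(n_cell_types), modules = modules,
         baseline_mean = baseline_mean, background_mean = background_mean,
         dispersion = dispersion,
         cell_type_proportions = cell_type_proportions,
         n_mito_genes = as.integer(n_mito_genes), seed = as.integer(seed)),
    class = "sim_config")
}

#' Build a regular planted-module layout
#'
#' Convenience constructor for the `modules` field of [sim_config()]:
#' `n_modules` disjoint blocks of `genes_per_module` consecutive genes, module
#' `m` targeting cell type `m`.
#'
#' @param n_modules Number of modules (one per target cell type).
#' @param genes_per_module Genes per module.
#' @param fold_change Expression fold change in the target type (>= 1).
#' @param first_gene Index of the first planted gene.
#' @return Tibble suitable for `sim_config(modules = )`.
#' @export
sim_modules <- function(n_modules, genes_per_module, fold_change = 8,
                        first_gene = 1L) {
  tibble::tibble(
    module = paste0("M", seq_len(n_modules)),
    genes = lapply(seq_len(n_modules), function(m) {
      first_gene + (m - 1L) * genes_per_module + seq_len(genes_per_module) - 1L
    }),
    target_type = seq_len(n_modules),
    fold_change = fold_change)
}

#' Simulate a single-cell reference with planted cell types and modules
#'
#' Draws a genes-by-cells negative-binomial count matrix in which every gene
#' has mean `baseline_mean`, multiplied by its module's `fold_change` in the
#' module's target cell type. Cells are additionally laid out on a jittered
#' hexagonal lattice (in abstract lattice units) so that the same ground truth
#' can later be rendered into tissue images by [simulate_tissue_images()].
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `reference` (a
#'   [gene_expression_reference()]) and `truth` (class `sim_truth`): cell type
#'   labels, gene-to-module membership, lattice centroids, and the cells x
#'   modules matrix of summed module counts (`per_cell_module_signal`).
#' @export
simulate_reference <- function(config) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n_cells <- config$n_cells
  n_genes <- config$n_genes

  type_labels <- paste0("type", seq_len(config$n_cell_types))
  cell_types <- sample(type_labels, n_cells, replace = TRUE,
                       prob = config$cell_type_proportions)

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  mito_flags <- rep(FALSE, n_genes)
  if (config$n_mito_genes > 0) {
    mito_idx <- n_genes - seq_len(config$n_mito_genes) + 1L
    module_genes <- unlist(config$modules$genes)
    abort_if(any(mito_idx %in% module_genes),
             "mitochondrial genes overlap planted modules",
             class = "modulefish_config_error")
    mito_flags[mito_idx] <- TRUE
    gene_ids[mito_idx] <- sprintf("mt-gene%04d", mito_idx)
  }

  mu <- matrix(config$background_mean, n_genes, n_cells)
  mu[unique(unlist(config$modules$genes)), ] <- config$baseline_mean
  for (m in seq_len(nrow(config$modules))) {
    target <- type_labels[config$modules$target_type[m]]
    idx <- config$modules$genes[[m]]
    mu[idx, cell_types == target] <-
      mu[idx, cell_types == target] * config$modules$fold_change[m]
  }
  counts <- matrix(
    stats::rnbinom(n_genes * n_cells, mu = mu, size = config$dispersion),
    n_genes, n_cells)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(gene_ids, cell_ids)

  ref <- gene_expression_reference(counts, gene_ids, cell_ids,
                                   cell_labels = cell_types,
                                   mito_flags = mito_flags)

  membership <- stats::setNames(rep(NA_character_, n_genes), gene_ids)
  for (m in seq_len(nrow(config$modules))) {
    membership[config$modules$genes[[m]]] <- config$modules$module[m]
  }

  signal <- vapply(seq_len(nrow(config$modules)), function(m) {
    idx <- config$modules$genes[[m]]
    if (length(idx) == 1L) counts[idx, ] else colSums(counts[idx, , drop = FALSE])
  }, numeric(n_cells))
  colnames(signal) <- config$modules$module
  rownames(signal) <- cell_ids

  truth <- structure(
    list(cell_type_labels = stats::setNames(cell_types, cell_ids),
         module_membership = membership,
         cell_centroids = hex_lattice(n_cells, seed = derive_seed(config$seed, 7L)),
         per_cell_module_signal = signal,
         config = config),
    class = "sim_truth")
  list(reference = ref, truth = truth)
}

# Jittered hexagonal lattice in abstract units (nearest-neighbour spacing 1).
# Jitter is +/- 0.04 units per axis, so centres never approach closer than
# ~0.89 units and disks of radius < 0.44 units cannot overlap.
hex_lattice <- function(n, seed) {
  set.seed(seed)
  n_cols <- ceiling(sqrt(n))
  n_rows <- ceiling(n / n_cols)
  rows <- rep(seq_len(n_rows), each = n_cols)[seq_len(n)]
  cols <- rep(seq_len(n_cols), times = n_rows)[seq_len(n)]
  y <- (rows - 1) * sqrt(3) / 2
  x <- (cols - 1) + ifelse(rows %% 2 == 0, 0.5, 0)
  tibble::tibble(
    cell = seq_len(n),
    y = y + stats::runif(n, -0.04, 0.04),
    x = x + stats::runif(n, -0.04, 0.04))
}

#' Smooth multiplicative illumination field
#'
#' A second-order radial polynomial centred on the image, scaled to
#' `[1 - strength, 1]`. Used as the default non-flat illumination in
#' [simulate_tissue_images()] so that percentile-based illumination
#' correction has something to remove.
#'
#' @param shape `c(n_rows, n_cols)` in pixels.
#' @param strength Fractional dimming at the corners (0 = flat field).
#' @return Matrix of multiplicative factors.
#' @export
polynomial_illumination <- function(shape, strength = 0.2) {
  yy <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
  xx <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
  r2 <- outer(yy^2, xx^2, `+`)
  1 - strength * r2 / max(r2)
}

#' Render synthetic multi-round tissue images from planted ground truth
#'
#' Draws every simulated cell as a disk on a jittered hexagonal grid; in
#' module round `m` the disk's pixel value is the cell's planted module signal
#' scaled by the illumination field, plus a constant background and Gaussian
#' noise. Each module round is translated by its planted shift; the nuclear
#' round and ground-truth label map are unshifted. This is the measurement
#' model that downstream registration, correction and per-cell averaging are
#' tested against.
#'
#' @param truth A `sim_truth` from [simulate_reference()].
#' @param signal Cells x modules matrix of expected intensities; defaults to
#'   `truth$per_cell_module_signal`.
#' @param image_shape `c(n_rows, n_cols)` pixels; all cells must fit.
#' @param cell_radius_px Disk radius in pixels.
#' @param background_level Constant additive background (camera units).
#' @param illumination_field Matrix of multiplicative factors (default flat).
#' @param noise_sd Gaussian noise standard deviation (camera units).
#' @param shifts Modules x 2 matrix of planted `(dy, dx)` translations in
#'   pixels (default all zero).
#' @param nuclear_level Disk intensity of the nuclear round.
#' @param background_round If `TRUE`, add a round containing only background
#'   and noise.
#' @param pixel_size Physical pixel size recorded on the stack (micron/px).
#' @param seed Integer seed for jitter and noise.
#' @return A list: `stack` ([image_stack()]), `labels` (integer label matrix
#'   matching the unshifted disks), `centroids_px` (tibble cell/y/x),
#'   `shifts` (the applied matrix), `signal`.
#' @export
simulate_tissue_images <- function(truth, signal = NULL,
                                   image_shape = c(256L, 256L),
                                   cell_radius_px = 5,
                                   background_level = 0,
                                   illumination_field = NULL,
                                   noise_sd = 0,
                                   shifts = NULL,
                                   nuclear_level = NULL,
                                   background_round = FALSE,
                                   pixel_size = 1,
                                   seed = 1L) {
  abort_if(!inherits(truth, "sim_truth"), "truth must come from simulate_reference")
  signal <- signal %||% truth$per_cell_module_signal
  signal <- as_dense_matrix(signal)
  n_cells <- nrow(signal)
  modules <- colnames(signal) %||% paste0("M", seq_len(ncol(signal)))

  spacing <- 2 * cell_radius_px + max(4, ceiling(cell_radius_px / 2))
  margin <- cell_radius_px + 2
  cent <- truth$cell_centroids
  abort_if(nrow(cent) < n_cells, "truth has fewer centroids than cells")
  cy <- cent$y[seq_len(n_cells)] * spacing + margin + 1
  cx <- cent$x[seq_len(n_cells)] * spacing + margin + 1
  abort_if(max(cy) + cell_radius_px + 2 > image_shape[1] ||
             max(cx) + cell_radius_px + 2 > image_shape[2],
           "cells do not fit inside image_shape; enlarge the image",
           class = "modulefish_layout_error")
  # hex lattice guarantees non-overlap; verify anyway (layout error contract)
  if (n_cells > 1) {
    ord <- order(cy, cx)
    d2min <- min(stats::dist(cbind(cy, cx)[ord[seq_len(min(n_cells, 2000L))], ]))
    abort_if(d2min < 2 * cell_radius_px + 1,
             "cell disks overlap beyond tolerance",
             class = "modulefish_layout_error")
  }

  if (is.null(shifts)) shifts <- matrix(0, length(modules), 2)
  shifts <- matrix(as.numeric(shifts), ncol = 2)
  abort_if(nrow(shifts) != length(modules),
           "one (dy, dx) shift per module round required")
  abort_if(any(!is.finite(shifts)), "shifts must be finite")
  illum <- illumination_field %||% matrix(1, image_shape[1], image_shape[2])
  abort_if(!all(dim(illum) == image_shape),
           "illumination_field must match image_shape")
  nuclear_level <- nuclear_level %||% max(1, stats::median(signal[signal > 0]))

  set.seed(seed)
  # disks have a 1 px linear coverage ramp at the edge so that fractional
  # planted shifts act as true subpixel translations of the scene
  draw_round <- function(values, dy, dx) {
    img <- matrix(background_level, image_shape[1], image_shape[2])
    for (i in seq_len(n_cells)) {
      if (values[i] == 0) next
      px <- disk_pixels(cy[i] + dy, cx[i] + dx, cell_radius_px, image_shape)
      img[px$idx] <- img[px$idx] + values[i] * px$w * illum[px$idx]
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow(img), ncol(img))
      img[img < 0] <- 0
    }
    img
  }

  rounds <- list()
  for (m in seq_along(modules)) {
    rounds[[modules[m]]] <- draw_round(signal[, m], shifts[m, 1], shifts[m, 2])
  }
  rounds[["DAPI"]] <- draw_round(rep(nuclear_level, n_cells), 0, 0)
  if (background_round) rounds[["background"]] <- draw_round(rep(0, n_cells), 0, 0)

  # label map covers the full-coverage interior of each (unshifted) disk
  labels <- matrix(0L, image_shape[1], image_shape[2])
  for (i in seq_len(n_cells)) {
    px <- disk_pixels(cy[i], cx[i], cell_radius_px, image_shape)
    labels[px$idx[px$w >= 1, , drop = FALSE]] <- i
  }

  stack <- image_stack(rounds, nuclear = "DAPI",
                       background = if (background_round) "background" else NULL,
                       pixel_size = pixel_size)
  rownames(shifts) <- modules
  colnames(shifts) <- c("dy", "dx")
  list(stack = stack, labels = labels,
       centroids_px = tibble::tibble(cell = seq_len(n_cells), y = cy, x = cx),
       shifts = shifts, signal = signal)
}

# Disk with a C2-smooth 2 px edge roll-off (smootherstep), emulating the
# finite optical resolution of a real micrograph; the smooth spectrum keeps
# subpixel-rendered scenes registrable without aliasing bias. Weight is
# exactly 1 for d <= r - 1 (the label-map interior) and 0 beyond r + 1.
disk_pixels <- function(cy, cx, r, shape) {
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(shape[1], ceiling(cy + r + 1))
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(shape[2], ceiling(cx + r + 1))
  ys <- y0:y1; xs <- x0:x1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  t <- pmin(pmax((r + 1 - d) / 2, 0), 1)
  w <- t^3 * (6 * t^2 - 15 * t + 10)
  hit <- w > 0
  list(idx = cbind(rep(ys, times = length(xs))[as.vector(hit)],
                   rep(xs, each = length(ys))[as.vector(hit)]),
       w = w[hit])
}

#' Simulate a cell layout with planted proximity depletion
#'
#' Places two reference groups (`A` in the left half of the field, `B` in the
#' right half) and a uniform field of query cells that are then thinned to a
#' fraction `keep_fraction` inside `radius_um` of any `B` cell — the planted
#' analogue of an immuno-suppressive niche in which immune cells are depleted
#' around one fibroblast subtype.
#'
#' @param n_per_group Reference cells per group.
#' @param n_query Query cells before thinning.
#' @param keep_fraction Probability a query cell within `radius_um` of a `B`
#'   cell is retained (0.5 = two-fold depletion).
#' @param radius_um Depletion (and later counting) radius in micron.
#' @param field_um `c(height, width)` of the field in micron.
#' @param seed Integer seed.
#' @return Tibble with columns `cell`, `group` (`"A"`, `"B"`, `"query"`),
#'   `x_um`, `y_um`.
#' @export
simulate_proximity_layout <- function(n_per_group = 500, n_query = 3000,
                                      keep_fraction = 0.5, radius_um = 100,
                                      field_um = c(1000, 2000), seed = 1L) {
  set.seed(seed)
  h <- field_um[1]; w <- field_um[2]
  a <- tibble::tibble(group = "A",
                      y_um = stats::runif(n_per_group, 0, h),
                      x_um = stats::runif(n_per_group, 0, w / 2 - radius_um))
  b <- tibble::tibble(group = "B",
                      y_um = stats::runif(n_per_group, 0, h),
                      x_um = stats::runif(n_per_group, w / 2 + radius_um, w))
  q <- tibble::tibble(group = "query",
                      y_um = stats::runif(n_query, 0, h),
                      x_um = stats::runif(n_query, 0, w))
  near_b <- vapply(seq_len(n_query), function(i) {
    any((q$y_um[i] - b$y_um)^2 + (q$x_um[i] - b$x_um)^2 <= radius_um^2)
  }, logical(1))
  keep <- !near_b | stats::runif(n_query) < keep_fraction
  out <- dplyr::bind_rows(a, b, q[keep, ])
  out$cell <- seq_len(nrow(out))
  out[, c("cell", "group", "x_um", "y_um")]
}

#' Write a simulated reference to disk
#'
#' Counts go to Matrix Market (`matrix.mtx`) with `genes.tsv` and
#' `barcodes.tsv` sidecars; labels and truth to `labels.tsv` / `truth.json`.
#'
#' @param sim Output of [simulate_reference()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_reference <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_reference_mtx(sim$reference, dir)
  truth <- sim$truth
  jsonlite::write_json(
    list(cell_type_labels = unname(truth$cell_type_labels),
         module_membership = as.list(truth$module_membership[
           !is.na(truth$module_membership)])),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
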
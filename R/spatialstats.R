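#' Cluster cells of a cell-by-module matrix
#'
#' The imaged analogue of [simulate_clustering()]: modules are z-scaled,
#' principal components computed, a k-nearest-neighbour graph built and
#' partitioned by modularity-based community detection. Only QC-passing cells
#' are clustered.
#'
#' @param cbm A `cell_by_module` (from [intensity_matrix()] /
#'   [quantify_stack()]) or a plain cells x modules matrix.
#' @param resolution Community-detection resolution.
#' @param n_pcs,n_neighbors Graph parameters.
#' @param seed Integer seed.
#' @param algorithm `"louvain"` or `"leiden"`.
#' @return A `clustering_result` tibble: `cell`, `cluster`, with the
#'   parameters in `attr(, "params")`.
#' @export
cluster_cells <- function(cbm, resolution = 0.8, n_pcs = 10,
                          n_neighbors = 20, seed = 1L,
                          algorithm = c("louvain", "leiden")) {
  algorithm <- match.arg(algorithm)
  if (inherits(cbm, "cell_by_module")) {
    cbm <- qc_pass(cbm)
    x <- cbm$values
    ids <- cbm$cells$cell
  } else {
    x <- as_dense_matrix(cbm)
    ids <- seq_len(nrow(x))
  }
  labels <- cluster_feature_matrix(x, n_pcs = n_pcs,
                                   n_neighbors = n_neighbors,
                                   resolution = resolution, seed = seed,
                                   algorithm = algorithm)
  out <- tibble::tibble(cell = ids, cluster = as.integer(labels))
  attr(out, "params") <- attr(labels, "params")
  class(out) <- c("clustering_result", class(out))
  out
}

#' Assign cells to their brightest channel
#'
#' For a per-channel-normalized matrix: cells whose maximum channel intensity
#' is below `min_normalized_intensity` stay unassigned; the rest take the
#' argmax channel. Exact ties go to the first channel in column order, with a
#' warning.
#'
#' @param mat Cells x channels matrix (normalized per channel) or a
#'   `cell_by_module`.
#' @param min_normalized_intensity Drop threshold on the max channel.
#' @return Tibble `cell`, `channel` (`NA` when unassigned), `intensity`.
#' @export
assign_max_channel <- function(mat, min_normalized_intensity = 0.5) {
  if (inherits(mat, "cell_by_module")) mat <- mat$values
  mat <- as_dense_matrix(mat)
  channels <- colnames(mat) %||% paste0("ch", seq_len(ncol(mat)))
  top <- apply(mat, 1, max)
  which_top <- apply(mat, 1, which.max)
  ties <- apply(mat, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties & top >= min_normalized_intensity)) {
    rlang::warn(sprintf("%d cell(s) with tied maximum channel; first taken",
                        sum(ties & top >= min_normalized_intensity)))
  }
  assigned <- top >= min_normalized_intensity
  tibble::tibble(cell = seq_len(nrow(mat)),
                 channel = ifelse(assigned, channels[which_top],
                                  NA_character_),
                 intensity = top)
}

#' Manders overlap coefficients between two channels
#'
#' `M1` is the fraction of pixels above threshold in channel 1 that are also
#' above threshold in channel 2; `M2` the symmetric fraction with channel 2's
#' supra-threshold set as denominator. Low values between cell-type channels
#' mean little crosstalk. Thresholds default to Otsu per channel; an empty
#' denominator yields 0 with a warning.
#'
#' @param image1,image2 Equal-shape matrices.
#' @param t1,t2 Binarization thresholds (default: per-channel Otsu).
#' @return A `manders_result` list: `m1`, `m2`, `t1`, `t2`.
#' @export
manders_overlap <- function(image1, image2, t1 = NULL, t2 = NULL) {
  abort_if(!all(dim(image1) == dim(image2)), "images must share shape")
  t1 <- t1 %||% otsu_threshold(image1)
  t2 <- t2 %||% otsu_threshold(image2)
  a <- image1 > t1
  b <- image2 > t2
  both <- sum(a & b)
  m1 <- if (sum(a) == 0) {
    rlang::warn("no pixels above t1; M1 set to 0"); 0
  } else both / sum(a)
  m2 <- if (sum(b) == 0) {
    rlang::warn("no pixels above t2; M2 set to 0"); 0
  } else both / sum(b)
  structure(list(m1 = m1, m2 = m2, t1 = t1, t2 = t2),
            class = "manders_result")
}

otsu_threshold <- function(img) {
  rng <- range(img)
  if (rng[2] <= rng[1]) return(rng[2])
  scaled <- (img - rng[1]) / (rng[2] - rng[1])
  rng[1] + EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1])
}

#' @export
print.manders_result <- function(x, ...) {
  cat(sprintf("<manders_result> M1 = %.4g, M2 = %.4g (t1 = %.4g, t2 = %.4g)\n",
              x$m1, x$m2, x$t1, x$t2))
  invisible(x)
}

#' Per-cell gain of module imaging over single-molecule FISH
#'
#' Element-wise ratio of per-cell mean module intensity to per-cell mean
#' smFISH intensity measured with the same cell masks; cells with zero smFISH
#' mean are excluded (their count is reported). The per-channel median over
#' at least `min_cells` valid cells summarizes the gain.
#'
#' @param module_matrix,smfish_matrix Equal-shape cells x channels matrices
#'   over the same cells.
#' @param min_cells Minimum valid cells required for a channel median.
#' @return List with `gain` (cells x channels matrix, `NA` where excluded),
#'   `median` (per channel, `NA` when under `min_cells`), `n_excluded`.
#' @export
per_cell_gain <- function(module_matrix, smfish_matrix, min_cells = 10) {
  abort_if(!all(dim(module_matrix) == dim(smfish_matrix)),
           "matrices must cover the same cells and channels")
  valid <- smfish_matrix > 0
  abort_if(!any(valid), "no cells with nonzero smFISH signal",
           class = "modulefish_empty_error")
  gain <- module_matrix / smfish_matrix
  gain[!valid] <- NA_real_
  med <- apply(gain, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) >= min_cells) stats::median(g) else NA_real_
  })
  list(gain = gain, median = med, n_excluded = colSums(!valid))
}

#' Cortical geometry defined by two offset circles
#'
#' Two circles of equal radius approximate the pial surface (outer) and the
#' deep boundary (inner) of the cortex; the distance `d` between their
#' centres spans the cortical depth axis.
#'
#' @param outer_center,inner_center Numeric `(y, x)` in pixels.
#' @param radius Shared radius in pixels.
#' @return A `cortical_geometry` list with the derived centre distance `d`.
#' @export
cortical_geometry <- function(outer_center, inner_center, radius) {
  d <- sqrt(sum((outer_center - inner_center)^2))
  abort_if(d <= 0, "centre distance must be positive")
  structure(list(outer_center = outer_center, inner_center = inner_center,
                 radius = radius, d = d),
            class = "cortical_geometry")
}

#' Normalized cortical depth of cells
#'
#' Depth of a cell is its radial distance inward from the outer circle's
#' edge, divided by the distance between the circle centres:
#' `(R - |cell - outer_center|) / d`. Cells on the outer arc get 0, cells on
#' the inner arc along the centre axis get 1; cells outside `[0, 1]` are
#' flagged as outside the annulus but still reported.
#'
#' @param centroids Tibble/data frame with `y`, `x` (pixels; `y_px`/`x_px`
#'   accepted).
#' @param geometry A [cortical_geometry()].
#' @return Tibble `cell`, `depth`, `inside`.
#' @export
cortical_depth <- function(centroids, geometry) {
  y <- centroids$y %||% centroids$y_px
  x <- centroids$x %||% centroids$x_px
  r <- sqrt((y - geometry$outer_center[1])^2 +
              (x - geometry$outer_center[2])^2)
  depth <- (geometry$radius - r) / geometry$d
  tibble::tibble(cell = centroids$cell %||% seq_along(depth),
                 depth = depth,
                 inside = depth >= 0 & depth <= 1)
}

#' Kernel density of cell depths
#'
#' Gaussian kernel density estimate of normalized depths with a fixed kernel
#' standard deviation (`bandwidth`), evaluated on a padded support around
#' `[0, 1]` so the curve integrates to 1.
#'
#' @param depths Numeric vector.
#' @param bandwidth Gaussian kernel standard deviation.
#' @param n Number of grid points.
#' @return Tibble `depth`, `density`.
#' @export
depth_density <- function(depths, bandwidth = 0.05, n = 512) {
  abort_if(length(depths) == 0, "at least one depth is required")
  pad <- 4 * bandwidth
  dd <- stats::density(depths, bw = bandwidth, kernel = "gaussian", n = n,
                       from = min(depths, 0) - pad,
                       to = max(depths, 1) + pad)
  tibble::tibble(depth = dd$x, density = dd$y)
}

#' Neighbour counts around two reference groups with a rank test
#'
#' Counts, for every cell of reference groups A and B, the query cells within
#' `radius_um` (closed ball: boundary cells count), compares the two count
#' vectors with a two-sided Mann-Whitney U test, and reports the fold-change
#' of the group medians (B relative to A). A fold-change below 1 with a small
#' p-value means query cells are depleted around group B.
#'
#' @param cells_a,cells_b,query Tibbles/data frames with coordinate columns
#'   (`x_um`/`y_um`, or `x`/`y` interpreted through `pixel_size`).
#' @param radius_um Counting radius in micron.
#' @param pixel_size Micron per pixel for pixel-coordinate input.
#' @return A `proximity_result` list: `counts_a`, `counts_b`, `u_statistic`,
#'   `p_value`, `fold_change` (median B / median A), `radius_um`.
#' @export
proximity_counts <- function(cells_a, cells_b, query, radius_um = 100,
                             pixel_size = 1) {
  get_xy <- function(tab) {
    if (!is.null(tab$x_um)) cbind(tab$x_um, tab$y_um)
    else cbind(tab$x, tab$y) * pixel_size
  }
  a <- get_xy(cells_a); b <- get_xy(cells_b); q <- get_xy(query)
  abort_if(nrow(a) == 0 || nrow(b) == 0, "empty reference group",
           class = "modulefish_empty_error")
  count_near <- function(ref) {
    vapply(seq_len(nrow(ref)), function(i) {
      sum((q[, 1] - ref[i, 1])^2 + (q[, 2] - ref[i, 2])^2 <= radius_um^2)
    }, integer(1))
  }
  ca <- count_near(a); cb <- count_near(b)
  if (length(unique(c(ca, cb))) == 1) {
    # fully tied: no evidence either way
    wt <- list(statistic = length(ca) * length(cb) / 2, p.value = 1)
  } else {
    exact <- length(ca) < 20 && length(cb) < 20 &&
      !any(duplicated(c(ca, cb)))
    wt <- suppressWarnings(
      stats::wilcox.test(ca, cb, exact = exact, correct = TRUE))
  }
  med_a <- stats::median(ca); med_b <- stats::median(cb)
  structure(list(counts_a = ca, counts_b = cb,
                 u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 fold_change = if (med_a == 0) Inf else med_b / med_a,
                 radius_um = radius_um),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "<proximity_result> median fold-change (B/A) = %.3g, U = %g, p = %.3g\n",
    x$fold_change, x$u_statistic, x$p_value))
  invisible(x)
}
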
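#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cell-by-module matrix into long format
#'
#' @param x A `cell_by_module`.
#' @param ... Unused.
#' @return Tibble `cell`, `module`, `intensity`, joined with the cell
#'   sidecar (centroids, QC flags).
#' @export
tidy.cell_by_module <- function(x, ...) {
  long <- tibble::as_tibble(x$values) |>
    dplyr::mutate(cell = x$cells$cell) |>
    tidyr::pivot_longer(-"cell", names_to = "module",
                        values_to = "intensity")
  dplyr::left_join(long, x$cells, by = "cell")
}

#' @rdname tidy.cell_by_module
#' @export
glance.cell_by_module <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$values), n_modules = ncol(x$values),
                 n_flagged = sum(x$cells$qc_flag),
                 mean_intensity = mean(x$values, na.rm = TRUE))
}

#' Tidy panel score and result objects
#'
#' `panel_score` objects are already tibbles; `tidy()` returns them
#' unclassed, `glance()` summarizes the panel-level minima that matter for a
#' go/no-go decision (worst-case gain and specificity).
#'
#' @param x A `panel_score`.
#' @param ... Unused.
#' @export
tidy.panel_score <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.panel_score
#' @export
glance.panel_score <- function(x, ...) {
  tibble::tibble(n_modules = nrow(x),
                 min_sg_conservative = min(x$sg_conservative),
                 min_ssr_conservative = min(x$ssr_conservative),
                 median_sg_conservative = stats::median(x$sg_conservative))
}

#' @rdname tidy.cell_by_module
#' @param x A result object.
#' @export
tidy.manders_result <- function(x, ...) {
  tibble::tibble(coefficient = c("M1", "M2"), value = c(x$m1, x$m2),
                 threshold = c(x$t1, x$t2))
}

#' @rdname tidy.cell_by_module
#' @export
tidy.proximity_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(group = "A", neighbor_count = x$counts_a),
    tibble::tibble(group = "B", neighbor_count = x$counts_b))
}

#' @rdname tidy.cell_by_module
#' @export
glance.proximity_result <- function(x, ...) {
  tibble::tibble(median_a = stats::median(x$counts_a),
                 median_b = stats::median(x$counts_b),
                 fold_change = x$fold_change,
                 u_statistic = x$u_statistic, p_value = x$p_value,
                 radius_um = x$radius_um)
}
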
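# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg, class = "modulefish_error") {
  if (isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(NULL)
}

# Percentiles throughout the package use linear interpolation between order
# statistics (quantile type 7) so that fixture values are exact.
pctl <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE, na.rm = TRUE)
}

as_dense_matrix <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  abort_if(!is.matrix(x), "expected a matrix")
  x
}

# Deterministic sub-seed derivation; keeps results below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483587L
}
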
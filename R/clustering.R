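# Shared graph-clustering chain used by simulate_clustering() (on the
# module-cell meta-gene matrix) and cluster_cells() (on the imaged
# cell-by-module matrix): z-scale features, PCA, kNN graph, modularity-based
# community detection.

cluster_feature_matrix <- function(x, n_pcs = 10, n_neighbors = 20,
                                   resolution = 0.8, seed = 1L,
                                   algorithm = c("louvain", "leiden")) {
  algorithm <- match.arg(algorithm)
  x <- as_dense_matrix(x)
  n <- nrow(x)
  abort_if(n < n_neighbors + 1,
           "need more cells than n_neighbors",
           class = "modulefish_empty_error")
  if (n_pcs > ncol(x)) {
    rlang::warn(sprintf("n_pcs clipped from %d to the feature count %d",
                        n_pcs, ncol(x)))
    n_pcs <- ncol(x)
  }
  sdv <- apply(x, 2, stats::sd)
  z <- sweep(x, 2, colMeans(x), `-`)
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), `/`)
  set.seed(seed)
  n_pcs <- min(n_pcs, n - 1L)
  pcs <- stats::prcomp(z, center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x
  nn <- knn_indices(pcs, n_neighbors)
  g <- snn_graph(nn)
  w <- igraph::E(g)$weight
  memb <- if (algorithm == "louvain") {
    igraph::membership(igraph::cluster_louvain(g, weights = w,
                                               resolution = resolution))
  } else {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", weights = w,
      resolution = resolution, n_iterations = 5))
  }
  labels <- as.integer(memb)
  names(labels) <- rownames(x)
  attr(labels, "params") <- list(n_pcs = n_pcs, n_neighbors = n_neighbors,
                                 resolution = resolution, seed = seed,
                                 algorithm = algorithm)
  labels
}

# Shared-nearest-neighbour graph: nodes i, j in each other's kNN union are
# connected with Jaccard overlap of their neighbour sets as edge weight
# (edges with overlap below 1/15 pruned), the conventional weighting that
# keeps diffuse clusters from being split by modularity optimization.
snn_graph <- function(nn) {
  n <- nrow(nn); k <- ncol(nn)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn))
  keep <- from < to
  pairs <- unique(cbind(pmin(from, to), pmax(from, to)))
  w <- vapply(seq_len(nrow(pairs)), function(e) {
    a <- sets[[pairs[e, 1]]]; b <- sets[[pairs[e, 2]]]
    ov <- length(intersect(a, b))
    ov / (2 * (k + 1) - ov)
  }, numeric(1))
  good <- w >= 1 / 15
  g <- igraph::make_graph(as.vector(t(pairs[good, , drop = FALSE])),
                          n = n, directed = FALSE)
  igraph::E(g)$weight <- w[good]
  g
}

# Chunked exact k-nearest-neighbours (excluding self) on Euclidean distance;
# avoids materializing the full n x n distance matrix.
knn_indices <- function(x, k, chunk = 512L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, `+`) - 2 * x[idx, , drop = FALSE] %*% t(x)
    for (j in seq_along(idx)) {
      d2[j, idx[j]] <- Inf
      out[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  out
}
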
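# PCA embedding and shared-nearest-neighbor graph clustering.

#' Principal-component embedding of a scaled matrix
#'
#' Projects cells onto the top right singular directions of the cells x
#' genes scaled matrix restricted to the highly-variable mask. Signs are
#' fixed so that the largest-magnitude loading of each component is
#' positive, making the embedding reproducible across runs and platforms.
#'
#' @param sm a `scaled_matrix`.
#' @param n_pcs number of components; must not exceed
#'   `min(#masked genes, #cells)`.
#' @param seed integer seed for the truncated solver used on large inputs.
#' @return object of class `embedding` with fields `scores`
#'   (cells x n_pcs), `loadings` (genes x n_pcs), `explained_variance`
#'   and `n_pcs`.
#' @export
pca_embed <- function(sm, n_pcs = 30, seed = 0) {
  v <- sm$values[sm$hvg_mask, , drop = FALSE]
  .stop_if(n_pcs > min(dim(v)),
           "n_pcs = ", n_pcs, " exceeds min(#genes, #cells) = ", min(dim(v)))
  emb <- .pca_matrix(v, n_pcs, seed)
  rownames(emb$scores) <- sm$cell_ids
  rownames(emb$loadings) <- sm$gene_ids[sm$hvg_mask]
  emb
}

.pca_matrix <- function(values, n_pcs, seed = 0) {
  g <- nrow(values) # genes
  n <- ncol(values) # cells
  if (min(n, g) <= 150 || n_pcs > 0.5 * min(n, g)) {
    m <- t(values)
    m <- sweep(m, 2, colMeans(m))
    sv <- svd(m, nu = n_pcs, nv = n_pcs)
    d <- sv$d[seq_len(n_pcs)]
    scores <- sweep(sv$u, 2, d, "*")
    v <- sv$v
  } else if (g <= n) {
    # exact route through the gene-gene cross-product of the per-gene
    # centered data, formed without transposing or copying the matrix:
    # crossprod(centered cells x genes) = A A' - n mu mu'; cheaper than a
    # truncated SVD of the tall matrix and free of RNG
    mu <- rowMeans(values)
    cp <- tcrossprod(values) - n * tcrossprod(mu)
    ee <- if (n_pcs <= g / 8) {
      # truncated symmetric solver; seeded, so bit-reproducible
      set.seed(derive_seed(seed, "pca", n, g, n_pcs))
      irlba::partial_eigen(cp, n = n_pcs)
    } else {
      full <- eigen(cp, symmetric = TRUE)
      list(values = full$values[seq_len(n_pcs)],
           vectors = full$vectors[, seq_len(n_pcs), drop = FALSE])
    }
    v <- ee$vectors
    d <- sqrt(pmax(ee$values, 0))
    scores <- sweep(crossprod(values, v), 2, drop(crossprod(mu, v)))
  } else {
    m <- t(values)
    m <- sweep(m, 2, colMeans(m))
    set.seed(derive_seed(seed, "pca", n, g, n_pcs))
    sv <- irlba::irlba(m, nv = n_pcs)
    d <- sv$d
    scores <- sweep(sv$u, 2, d, "*")
    v <- sv$v
  }
  # deterministic sign: largest-magnitude loading positive per component
  for (p in seq_len(n_pcs)) {
    j <- which.max(abs(v[, p]))
    if (v[j, p] < 0) {
      v[, p] <- -v[, p]
      scores[, p] <- -scores[, p]
    }
  }
  structure(list(scores = scores, loadings = v,
                 explained_variance = d^2 / (n - 1),
                 n_pcs = n_pcs),
            class = "embedding")
}

# Shared-nearest-neighbor graph: Jaccard similarity over the k-nearest
# neighbour sets (self included, as in the standard single-cell toolkits),
# edges with weight below `prune` removed.
.snn_graph <- function(scores, k = 20, prune = 1 / 15) {
  n <- nrow(scores)
  .stop_if(k >= n, "k_neighbors = ", k, " requires more than ", k, " cells")
  nn <- .knn(scores, k = k)$idx # includes self in column 1
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj) # counts of shared neighbours
  shared <- methods::as(shared, "CsparseMatrix")
  shared@x <- shared@x / (2 * k - shared@x) # Jaccard: |A u B| = 2k - |A n B|
  shared@x[shared@x < prune] <- 0
  shared <- Matrix::drop0(shared)
  Matrix::diag(shared) <- 0
  igraph::graph_from_adjacency_matrix(Matrix::drop0(shared),
                                      mode = "undirected",
                                      weighted = TRUE)
}

# Modularity community detection on a prebuilt SNN graph; labels relabelled
# 0-based by decreasing cluster size for determinism.
.cluster_graph <- function(graph, resolution, seed = 0,
                           algorithm = c("louvain", "leiden")) {
  algorithm <- match.arg(algorithm)
  set.seed(derive_seed(seed, "cluster", resolution, algorithm))
  comm <- if (algorithm == "louvain") {
    igraph::cluster_louvain(graph, resolution = resolution)
  } else {
    igraph::cluster_leiden(graph, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10)
  }
  raw <- igraph::membership(comm)
  sizes <- table(raw)
  new_id <- stats::setNames(seq_along(sizes) - 1L,
                            names(sort(sizes, decreasing = TRUE)))
  labels <- as.integer(new_id[as.character(raw)])
  structure(list(labels = labels, resolution = resolution,
                 n_clusters = length(sizes),
                 sizes = as.integer(table(labels))),
            class = "clustering")
}

#' Graph-based clustering of an embedding
#'
#' Builds an exact Euclidean k-nearest-neighbour graph in PC space,
#' converts it to a shared-nearest-neighbor graph with Jaccard edge
#' weights (edges below 1/15 pruned), and optimizes modularity at the
#' given resolution. Labels are contiguous integers from 0, ordered by
#' decreasing cluster size, and deterministic given the seed.
#'
#' @param emb an `embedding`.
#' @param resolution positive resolution parameter; larger values give
#'   more clusters.
#' @param k_neighbors neighbourhood size, default 20.
#' @param seed integer seed.
#' @param algorithm `"louvain"` (default) or `"leiden"`.
#' @param prune Jaccard weight below which SNN edges are dropped.
#' @return object of class `clustering` with fields `labels`,
#'   `resolution`, `n_clusters`, `sizes`.
#' @export
graph_cluster <- function(emb, resolution, k_neighbors = 20, seed = 0,
                          algorithm = c("louvain", "leiden"),
                          prune = 1 / 15) {
  stopifnot(resolution > 0)
  graph <- .snn_graph(emb$scores, k = k_neighbors, prune = prune)
  .cluster_graph(graph, resolution, seed, match.arg(algorithm))
}
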
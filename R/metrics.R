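# Integration quality metrics: batch mixing, local structure preservation,
# average silhouette width and adjusted Rand index.

.scores_of <- function(emb) {
  if (inherits(emb, "embedding")) emb$scores else as.matrix(emb)
}

#' Batch mixing metric
#'
#' For every cell, the `k_max` nearest neighbours (Euclidean, excluding the
#' cell itself) are scanned for the rank at which the k-th neighbour from
#' each batch appears; a batch that never contributes k neighbours scores
#' `k_max + 1`. The cell's score is the median of these ranks over batches
#' and the metric is the mean over cells. Lower values indicate better
#' mixing; with two far-separated batches the metric saturates at
#' `(k + k_max + 1) / 2`.
#'
#' @param emb an `embedding` or a cells x dims score matrix.
#' @param batch_labels per-cell batch labels (>= 2 batches, each with at
#'   least `k` cells).
#' @param k neighbour depth per batch, default 5.
#' @param k_max neighbourhood width, default 300; must be smaller than the
#'   number of cells.
#' @return a single number.
#' @export
mixing_metric <- function(emb, batch_labels, k = 5, k_max = 300) {
  scores <- .scores_of(emb)
  n <- nrow(scores)
  batch_labels <- as.character(batch_labels)
  stopifnot(length(batch_labels) == n)
  batches <- sort(unique(batch_labels))
  .stop_if(length(batches) < 2, "need at least 2 batches")
  .stop_if(k_max < k, "k_max must be at least k")
  .stop_if(k_max >= n, "k_max must be smaller than the number of cells")
  small <- names(which(table(batch_labels) < k))
  .stop_if(length(small) > 0, "batch smaller than k = ", k, ": ",
           paste(small, collapse = ", "))
  idx <- .knn(scores, k = k_max + 1)$idx[, -1, drop = FALSE]
  ranks <- vapply(batches, function(b) {
    hit <- matrix(batch_labels[idx] == b, nrow = n)
    cum <- matrixStats::rowCumsums(hit)
    reached <- cum >= k
    out <- rep(k_max + 1, n)
    any_hit <- matrixStats::rowAnys(reached)
    out[any_hit] <- max.col(reached[any_hit, , drop = FALSE],
                            ties.method = "first")
    out
  }, numeric(n))
  mean(matrixStats::rowMedians(ranks))
}

#' Local structure preservation metric
#'
#' Mean Jaccard overlap between each cell's k nearest same-batch
#' neighbours in its original per-dataset embedding and in the integrated
#' embedding. 1 means the within-dataset neighbourhoods are untouched by
#' integration; random within-batch placement gives roughly
#' `k / (n_batch - 1)`.
#'
#' @param emb_orig_per_dataset named list of per-dataset embeddings (or
#'   score matrices), one per batch, rows in the same order as that
#'   batch's cells appear in `emb_integrated`.
#' @param emb_integrated integrated embedding covering all cells.
#' @param batch_labels per-cell batch labels.
#' @param k neighbourhood size, default 20; every batch needs more than
#'   `k` cells.
#' @return a number in `[0, 1]`.
#' @export
local_structure_metric <- function(emb_orig_per_dataset, emb_integrated,
                                   batch_labels, k = 20) {
  scores_int <- .scores_of(emb_integrated)
  batch_labels <- as.character(batch_labels)
  overlaps <- numeric(0)
  for (b in names(emb_orig_per_dataset)) {
    rows <- which(batch_labels == b)
    .stop_if(length(rows) <= k, "batch '", b, "' needs more than k = ", k,
             " cells")
    orig <- .scores_of(emb_orig_per_dataset[[b]])
    .stop_if(nrow(orig) != length(rows),
             "per-dataset embedding for '", b,
             "' does not cover exactly that batch's cells")
    nn_orig <- .knn(orig, k = k + 1)$idx[, -1, drop = FALSE]
    nn_int <- .knn(scores_int[rows, , drop = FALSE],
                   k = k + 1)$idx[, -1, drop = FALSE]
    overlaps <- c(overlaps, vapply(seq_along(rows), function(i) {
      s <- length(intersect(nn_orig[i, ], nn_int[i, ]))
      s / (2 * k - s)
    }, numeric(1)))
  }
  mean(overlaps)
}

#' Average silhouette width of annotated types
#'
#' Mean silhouette coefficient (Euclidean distance in the embedding) of
#' the given type labels; near 1 for tight well-separated types, near 0
#' for uninformative labels.
#'
#' @param emb an `embedding` or score matrix.
#' @param type_labels per-cell labels; at least 2 types with 2 cells each.
#' @return a number in `[-1, 1]`.
#' @export
silhouette_asw <- function(emb, type_labels) {
  scores <- .scores_of(emb)
  f <- factor(type_labels)
  .stop_if(nlevels(f) < 2, "need at least 2 types for a silhouette")
  .stop_if(min(table(f)) < 2, "every type needs at least 2 cells")
  sil <- cluster::silhouette(as.integer(f), stats::dist(scores))
  mean(sil[, "sil_width"])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(A + B) - E}}
#' with \eqn{A = \sum_i \binom{a_i}{2}}, \eqn{B = \sum_j \binom{b_j}{2}},
#' \eqn{E = AB/\binom{n}{2}}.
#'
#' @param labels_1,labels_2 equal-length label vectors.
#' @return a number, 1 for identical partitions, about 0 at chance level.
#' @export
ari <- function(labels_1, labels_2) {
  .stop_if(length(labels_1) != length(labels_2),
           "label vectors have different lengths")
  n <- length(labels_1)
  tab <- table(labels_1, labels_2)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(0) # both partitions trivial: chance level
  (sum_ij - expected) / denom
}

#' Fraction of cross-batch cells among nearest neighbours
#'
#' Per-cell fraction of the k nearest neighbours (excluding self) that
#' come from a different batch; near 0 when batches occupy disjoint
#' regions, near the cross-batch cell fraction under perfect mixing.
#'
#' @param emb an `embedding` or score matrix.
#' @param batch_labels per-cell batch labels.
#' @param k neighbourhood size, default 10.
#' @return numeric vector, one fraction per cell.
#' @export
crossbatch_knn_fraction <- function(emb, batch_labels, k = 10) {
  scores <- .scores_of(emb)
  batch_labels <- as.character(batch_labels)
  .stop_if(k >= nrow(scores), "k must be smaller than the number of cells")
  idx <- .knn(scores, k = k + 1)$idx[, -1, drop = FALSE]
  rowMeans(matrix(batch_labels[idx], nrow = nrow(scores)) != batch_labels)
}

#' Cluster an embedding to match an annotation's granularity
#'
#' Graph-clusters the embedding over a resolution grid and keeps the
#' resolution whose cluster count is closest to the number of annotated
#' types (ties towards the lower resolution) — the benchmark convention
#' that makes the adjusted Rand index compare partitions of comparable
#' granularity rather than penalising resolution mismatch.
#'
#' @param emb an `embedding`.
#' @param n_types target number of clusters.
#' @param config a [rescale_config()] (resolution grid, k_neighbors, seed).
#' @return a `clustering`.
#' @export
cluster_to_types <- function(emb, n_types, config = rescale_config()) {
  cfg <- rescale_config(config)
  graph <- .snn_graph(emb$scores, k = cfg$k_neighbors, prune = cfg$snn_prune)
  best <- NULL
  best_gap <- Inf
  for (r in .resolution_grid(cfg)) {
    cl <- .cluster_graph(graph, r, cfg$seed, cfg$cluster_algorithm)
    gap <- abs(cl$n_clusters - n_types)
    if (gap < best_gap) { # strict <: ties keep the lower resolution
      best <- cl
      best_gap <- gap
    }
  }
  best
}

#' Metric report for an integration result
#'
#' Computes the four quality metrics on an [integrate_pair()] /
#' [integrate_many()] result: batch mixing (lower is better), local
#' structure preservation (higher is better), average silhouette width of
#' the annotated types and the adjusted Rand index between a
#' granularity-matched graph clustering of the integrated embedding and
#' the annotated types.
#'
#' @param result an `integration_result`.
#' @param type_labels per-cell annotated types, in the column order of
#'   `result$integrated`.
#' @param config a [rescale_config()].
#' @return list of class `metric_report` with fields `mixing`,
#'   `local_structure`, `asw`, `ari`.
#' @export
evaluate_integration <- function(result, type_labels,
                                 config = rescale_config()) {
  cfg <- rescale_config(config)
  n <- ncol(result$integrated$values)
  stopifnot(length(type_labels) == n)
  cl <- cluster_to_types(result$embedding, length(unique(type_labels)), cfg)
  rep <- list(
    mixing = mixing_metric(result$embedding, result$batch_labels,
                           k = cfg$mixing_k,
                           k_max = min(cfg$mixing_k_max, n - 1)),
    local_structure = local_structure_metric(result$orig_embeddings,
                                             result$embedding,
                                             result$batch_labels,
                                             k = cfg$local_k),
    asw = silhouette_asw(result$embedding, type_labels),
    ari = ari(cl$labels, type_labels))
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("integration metrics: mixing %.2f | local structure ",
                     "%.3f | ASW %.3f | ARI %.3f\n"),
              x$mixing, x$local_structure, x$asw, x$ari))
  invisible(x)
}
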
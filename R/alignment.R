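# Cluster alignment across two datasets in a joint PC space: nearest-center
# candidates, the 75%-quantile spread criterion, and the proportion-matched
# subsampling retry for clusters whose abundance differs between datasets.

#' Per-cluster centers in an embedding
#'
#' @param emb_joint an `embedding` (typically of the concatenated datasets).
#' @param clustering a `clustering` whose i-th label corresponds to
#'   `which_cells[i]`.
#' @param which_cells integer row indices of `emb_joint$scores` for the
#'   clustered cells; defaults to all rows.
#' @return list with `centers` (clusters x n_pcs, rownames = cluster ids)
#'   and `cluster_sizes`.
#' @export
cluster_centers <- function(emb_joint, clustering,
                            which_cells = seq_len(nrow(emb_joint$scores))) {
  scores <- emb_joint$scores[which_cells, , drop = FALSE]
  .centers_of(scores, clustering$labels)
}

.centers_of <- function(scores, labels) {
  ids <- sort(unique(labels))
  centers <- t(vapply(ids, function(id) {
    rows <- which(labels == id)
    .stop_if(length(rows) == 0, "empty cluster ", id)
    colMeans(scores[rows, , drop = FALSE])
  }, numeric(ncol(scores))))
  rownames(centers) <- ids
  list(centers = centers,
       cluster_sizes = stats::setNames(as.integer(table(labels)), ids))
}

#' Quantile spread criterion for cluster alignment
#'
#' An anchor cluster may align with a query cluster only when the squared
#' distance between their centers falls strictly below the 75% quantile
#' (linear interpolation, type 7) of the squared distances from the query
#' cluster's cells to their own center.
#'
#' @param center_a anchor cluster center (numeric vector).
#' @param query_cells matrix of the query cluster's cell scores (one row
#'   per cell).
#' @param query_center query cluster center.
#' @return `TRUE` when the criterion holds.
#' @export
quantile_criterion <- function(center_a, query_cells, query_center) {
  query_cells <- rbind(query_cells)
  if (nrow(query_cells) < 2) {
    warning("query cluster has a single cell; spread quantile is 0 and the ",
            "criterion can only reject")
  }
  d2 <- rowSums(sweep(query_cells, 2, query_center)^2)
  q75 <- stats::quantile(d2, 0.75, type = 7, names = FALSE)
  sum((center_a - query_center)^2) < q75
}

#' Candidate query clusters for an anchor cluster
#'
#' Up to `m` query clusters ranked by ascending squared center distance;
#' ties broken by smaller cluster id.
#'
#' @param anchor_center numeric vector.
#' @param query_centers result of [cluster_centers()] for the query
#'   clustering.
#' @param m maximum number of candidates, default 5.
#' @return integer vector of query cluster ids.
#' @export
candidate_queries <- function(anchor_center, query_centers, m = 5) {
  centers <- query_centers$centers
  ids <- as.integer(rownames(centers))
  d2 <- rowSums(sweep(centers, 2, anchor_center)^2)
  ids[order(d2, ids)][seq_len(min(m, length(ids)))]
}

#' Subsample size matching a target cluster proportion
#'
#' The largest integer n' such that a cluster of n' cells inside its
#' otherwise unchanged dataset has proportion at most `p_target`:
#' `n' = floor(p_target * (N - n) / (1 - p_target))`.
#'
#' @param n_cluster cells in the over-represented cluster.
#' @param N_dataset cells in its dataset.
#' @param p_target target within-subset proportion, in (0, 1), at most the
#'   cluster's current proportion.
#' @return integer n' >= 1.
#' @export
retry_subsample_size <- function(n_cluster, N_dataset, p_target) {
  stopifnot(p_target > 0, p_target < 1, n_cluster <= N_dataset)
  .stop_if(n_cluster / N_dataset < p_target,
           "cluster is not over-represented relative to p_target")
  n_prime <- floor(p_target * (N_dataset - n_cluster) / (1 - p_target))
  .stop_if(n_prime < 1,
           "cluster too small to match proportion ", p_target)
  as.integer(n_prime)
}

# Steps (1)-(3) for one anchor cluster: nearest candidate query cluster
# (among the m nearest) passing the quantile criterion, or NA.
.align_one <- function(a_center, scores_q, labels_q, q_centers, m = 5) {
  for (b in candidate_queries(a_center, q_centers, m)) {
    cells_b <- scores_q[labels_q == b, , drop = FALSE]
    ok <- suppressWarnings(
      quantile_criterion(a_center, cells_b,
                         q_centers$centers[as.character(b), ]))
    if (ok) return(b)
  }
  NA_integer_
}

#' Align anchor clusters to query clusters
#'
#' For each anchor cluster, accepts the nearest of its five nearest query
#' clusters (by center distance in the joint embedding) that passes the
#' quantile spread criterion. Anchor clusters left unaligned get a retry:
#' whichever side over-represents its cluster is subsampled to the other
#' side's proportion, the per-gene standard deviation over that subset
#' re-scales the whole over-represented dataset on a scratch copy, the
#' joint embedding is recomputed and the criterion re-tested
#' (nearest-first over the original candidate order). Anchor clusters
#' sharing a query cluster are merged.
#'
#' @param emb_joint joint `embedding` whose rows are the anchor cells
#'   followed by the query cells.
#' @param anchor_clustering,query_clustering `clustering` objects for the
#'   two datasets.
#' @param scaled_anchor,scaled_query `scaled_matrix` objects on the shared
#'   gene panel (needed by the retry's re-scaling).
#' @param seed integer seed driving the retry subsampling.
#' @param n_candidates candidate pool size, default 5.
#' @return object of class `alignment_map`: `pairs` (data.frame with
#'   columns anchor, query, via_retry), `merged_anchor_groups`,
#'   `unaligned_anchor_clusters`, `retry_log`.
#' @export
align_clusters <- function(emb_joint, anchor_clustering, query_clustering,
                           scaled_anchor, scaled_query, seed = 0,
                           n_candidates = 5) {
  n_a <- length(anchor_clustering$labels)
  n_q <- length(query_clustering$labels)
  stopifnot(nrow(emb_joint$scores) == n_a + n_q)
  scores_a <- emb_joint$scores[seq_len(n_a), , drop = FALSE]
  scores_q <- emb_joint$scores[n_a + seq_len(n_q), , drop = FALSE]
  labels_a <- anchor_clustering$labels
  labels_q <- query_clustering$labels
  a_centers <- .centers_of(scores_a, labels_a)
  q_centers <- .centers_of(scores_q, labels_q)
  a_ids <- as.integer(rownames(a_centers$centers))

  aligned <- stats::setNames(rep(NA_integer_, length(a_ids)), a_ids)
  via_retry <- stats::setNames(rep(FALSE, length(a_ids)), a_ids)
  for (a in a_ids) {
    aligned[as.character(a)] <-
      .align_one(a_centers$centers[as.character(a), ], scores_q, labels_q,
                 q_centers, n_candidates)
  }

  retry_log <- list()
  n_pcs <- ncol(emb_joint$scores)
  for (a in a_ids[is.na(aligned)]) {
    cand <- candidate_queries(a_centers$centers[as.character(a), ],
                              q_centers, n_candidates)
    for (b in cand) {
      size_a <- a_centers$cluster_sizes[as.character(a)]
      size_b <- q_centers$cluster_sizes[as.character(b)]
      p_a <- size_a / n_a
      p_b <- size_b / n_q
      if (p_a == p_b) next
      side <- if (p_a > p_b) "anchor" else "query"
      res <- tryCatch(
        .retry_attempt(a, b, side, labels_a, labels_q,
                       scaled_anchor, scaled_query, n_pcs, seed,
                       n_candidates),
        error = function(e) NULL)
      if (is.null(res)) next
      retry_log[[length(retry_log) + 1]] <-
        data.frame(anchor = a, candidate = b, side = side,
                   n_subsample = res$n_subsample,
                   accepted_query = res$accepted %||% NA_integer_,
                   accepted = !is.na(res$accepted))
      if (!is.na(res$accepted)) {
        aligned[as.character(a)] <- res$accepted
        via_retry[as.character(a)] <- TRUE
        break
      }
    }
  }

  pairs <- data.frame(anchor = a_ids[!is.na(aligned)],
                      query = as.integer(aligned[!is.na(aligned)]),
                      via_retry = via_retry[!is.na(aligned)],
                      row.names = NULL)
  groups <- split(pairs$anchor, pairs$query)
  structure(list(
    pairs = pairs,
    merged_anchor_groups = unname(groups[lengths(groups) > 1]),
    unaligned_anchor_clusters = a_ids[is.na(aligned)],
    retry_log = if (length(retry_log)) do.call(rbind, retry_log) else
      data.frame(anchor = integer(), candidate = integer(),
                 side = character(), n_subsample = integer(),
                 accepted_query = integer(), accepted = logical())),
    class = "alignment_map")
}

# One retry: subsample the over-represented side's cluster to the matched
# proportion, re-scale that whole dataset by the subset's per-gene sd,
# recompute the joint embedding and re-run steps (1)-(3) for cluster `a`.
# Evaluated on scratch copies; only the alignment decision escapes.
.retry_attempt <- function(a, b, side, labels_a, labels_q,
                           scaled_anchor, scaled_query, n_pcs, seed,
                           n_candidates) {
  n_a <- length(labels_a)
  n_q <- length(labels_q)
  if (side == "anchor") {
    p_target <- sum(labels_q == b) / n_q
    members <- which(labels_a == a)
    n_sub <- retry_subsample_size(length(members), n_a, p_target)
    set.seed(derive_seed(seed, "retry", a, b, side))
    keep <- sort(sample(members, n_sub))
    subset_idx <- sort(c(setdiff(seq_len(n_a), members), keep))
    sub <- scaled_anchor$values[, subset_idx, drop = FALSE]
    va <- (scaled_anchor$values - rowMeans(sub)) / .safe_sd(sub)
    vq <- scaled_query$values
  } else {
    p_target <- sum(labels_a == a) / n_a
    members <- which(labels_q == b)
    n_sub <- retry_subsample_size(length(members), n_q, p_target)
    set.seed(derive_seed(seed, "retry", a, b, side))
    keep <- sort(sample(members, n_sub))
    subset_idx <- sort(c(setdiff(seq_len(n_q), members), keep))
    sub <- scaled_query$values[, subset_idx, drop = FALSE]
    va <- scaled_anchor$values
    vq <- (scaled_query$values - rowMeans(sub)) / .safe_sd(sub)
  }
  joint <- .pca_matrix(cbind(va, vq), n_pcs,
                       derive_seed(seed, "retry_pca", a, b))
  sa <- joint$scores[seq_len(n_a), , drop = FALSE]
  sq <- joint$scores[n_a + seq_len(n_q), , drop = FALSE]
  qc <- .centers_of(sq, labels_q)
  a_center <- colMeans(sa[labels_a == a, , drop = FALSE])
  list(accepted = .align_one(a_center, sq, labels_q, qc, n_candidates),
       n_subsample = n_sub)
}

# Per-gene sample sd with zero-variance genes mapped to 1 (no re-scaling),
# warning once about how many were affected.
.safe_sd <- function(values) {
  s <- .row_sd(values)
  n_zero <- sum(s == 0)
  if (n_zero > 0) {
    warning(n_zero, " gene(s) with zero variance on the subset; ",
            "left un-rescaled")
    s[s == 0] <- 1
  }
  s
}
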
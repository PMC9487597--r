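# k-nearest-neighbour label transfer from the anchor dataset to the query
# dataset in the integrated embedding, plus match scores for cell types
# possibly absent from the anchor.

#' Transfer cell-type labels through the integrated embedding
#'
#' Each query cell takes the modal type among its k nearest anchor cells
#' (Euclidean distance in the integrated PC space); vote ties are broken
#' by the type of the single nearest anchor cell.
#'
#' @param emb_integrated integrated `embedding` (or score matrix) covering
#'   all cells.
#' @param batch_labels per-cell batch labels.
#' @param anchor_batch label identifying the annotated (anchor) batch.
#' @param anchor_types per-anchor-cell type labels, in the order the
#'   anchor cells appear in the embedding; no missing values.
#' @param k neighbours per query cell, default 10.
#' @param match_threshold optional match-score threshold below which a
#'   query cell is flagged `unknown`; no flagging when `NULL` (the
#'   threshold is data-dependent and deliberately has no default).
#' @return list of class `transfer_result`: per-query-cell `labels`,
#'   `neighbor_votes` (query cells x types), `match_score`,
#'   `unknown_mask`, and `query_cells` (their indices in the embedding).
#' @export
transfer_labels <- function(emb_integrated, batch_labels, anchor_batch,
                            anchor_types, k = 10, match_threshold = NULL) {
  scores <- .scores_of(emb_integrated)
  batch_labels <- as.character(batch_labels)
  anchor_rows <- which(batch_labels == anchor_batch)
  query_rows <- which(batch_labels != anchor_batch)
  .stop_if(length(anchor_rows) == 0, "no cells in anchor batch '",
           anchor_batch, "'")
  .stop_if(length(anchor_rows) < k,
           "anchor batch has fewer than k = ", k, " cells")
  .stop_if(length(anchor_types) != length(anchor_rows),
           "anchor_types must have one label per anchor cell")
  untyped <- which(is.na(anchor_types) | anchor_types == "")
  .stop_if(length(untyped) > 0, "untyped anchor cells at positions: ",
           paste(utils::head(untyped, 10), collapse = ", "))
  anchor_types <- as.character(anchor_types)

  nn <- .knn(scores[anchor_rows, , drop = FALSE],
             scores[query_rows, , drop = FALSE], k)
  types <- sort(unique(anchor_types))
  votes <- matrix(0L, nrow = length(query_rows), ncol = length(types),
                  dimnames = list(NULL, types))
  labels <- character(length(query_rows))
  for (i in seq_along(query_rows)) {
    tt <- anchor_types[nn$idx[i, ]]
    tab <- table(tt)
    votes[i, names(tab)] <- as.integer(tab)
    top <- names(tab)[tab == max(tab)]
    labels[i] <- if (length(top) == 1) top else tt[1] # nearest breaks ties
  }
  scores_q <- match_score(emb_integrated, batch_labels, anchor_batch, k)
  structure(list(labels = labels, neighbor_votes = votes,
                 match_score = scores_q,
                 unknown_mask = if (is.null(match_threshold))
                   rep(FALSE, length(labels)) else
                     flag_unknown(scores_q, match_threshold),
                 query_cells = query_rows),
            class = "transfer_result")
}

#' Match score: is a query cell's type present in the anchor data?
#'
#' For each query cell, the mean distance to its k nearest same-batch
#' cells divided by the mean distance to its k nearest anchor-batch
#' cells, in the integrated embedding (self excluded on both sides).
#' A cell of a type present in both datasets scores near 1; a cell whose
#' type is missing from the anchor scores much lower. The score is
#' invariant to a global rescaling of the coordinates.
#'
#' @inheritParams transfer_labels
#' @return numeric vector, one score per query cell (in embedding order of
#'   the non-anchor cells).
#' @export
match_score <- function(emb_integrated, batch_labels, anchor_batch,
                        k = 10) {
  scores <- .scores_of(emb_integrated)
  batch_labels <- as.character(batch_labels)
  anchor_rows <- which(batch_labels == anchor_batch)
  query_rows <- which(batch_labels != anchor_batch)
  .stop_if(length(anchor_rows) < k || length(query_rows) < k + 1,
           "both batches need more than k = ", k, " cells")
  q <- scores[query_rows, , drop = FALSE]
  # same-batch: k+1 then drop the self column
  d_same <- .knn(q, q, k + 1)$dist[, -1, drop = FALSE]
  d_anchor <- .knn(scores[anchor_rows, , drop = FALSE], q, k)$dist
  denom <- rowMeans(d_anchor)
  zero <- denom <= 0
  if (any(zero)) {
    warning(sum(zero), " query cell(s) coincide with anchor cells; ",
            "denominator floored at machine epsilon")
    denom[zero] <- .Machine$double.eps
  }
  rowMeans(d_same) / denom
}

#' Flag query cells with low match scores as unknown
#'
#' @param scores per-cell match scores.
#' @param threshold cells with `score < threshold` are flagged. There is
#'   no default: inspect the score distribution (e.g. a histogram) and
#'   choose.
#' @return logical mask.
#' @export
flag_unknown <- function(scores, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  scores < threshold
}
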
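# Sequential integration of more than two datasets, most similar pair
# (most shared highly variable genes) first.

# HVG list for a raw dataset or an integrated intermediate. Intermediates
# carry re-scaled values, so their genes are ranked by variance of those
# values; raw datasets go through the standard selection.
.dataset_hvgs <- function(x, cfg) {
  if (inherits(x, "count_matrix")) {
    select_hvg(lognormalize(x, cfg$scale_factor), cfg$n_hvg, cfg$hvg_method)
  } else { # scaled_matrix intermediate
    v <- matrixStats::rowVars(x$values)
    ord <- order(-v, x$gene_ids)
    x$gene_ids[ord][seq_len(min(cfg$n_hvg, length(ord)))]
  }
}

#' Pairwise shared-HVG counts between datasets
#'
#' @param datasets list of [count_matrix] objects.
#' @param n_hvg highly variable genes per dataset.
#' @param config a [rescale_config()]; `n_hvg` overrides its value.
#' @return symmetric integer matrix of shared-HVG counts; the diagonal is
#'   each dataset's own HVG count.
#' @export
similarity_matrix <- function(datasets, n_hvg = 4000,
                              config = rescale_config()) {
  cfg <- rescale_config(config)
  cfg$n_hvg <- n_hvg
  .stop_if(length(datasets) < 2, "need at least 2 datasets")
  hvgs <- lapply(datasets, .dataset_hvgs, cfg = cfg)
  n <- length(datasets)
  sim <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sim[i, j] <- length(intersect(hvgs[[i]], hvgs[[j]]))
    }
  }
  nm <- vapply(datasets, function(d) d$platform, character(1))
  dimnames(sim) <- list(nm, nm)
  sim
}

#' Greedy merge order from a similarity matrix
#'
#' Repeatedly merges the most similar pair (ties towards the smallest
#' dataset-index pair). A merged intermediate's similarity to the rest is
#' the maximum over its members (single linkage); [integrate_many()]
#' instead recomputes similarities from the merged data at every round.
#'
#' @param sim symmetric similarity matrix (e.g. [similarity_matrix()]).
#' @return list of class `integration_plan`: `order` (list of merge steps
#'   with member indices) and the input `similarity`.
#' @export
plan_order <- function(sim) {
  n <- nrow(sim)
  .stop_if(n < 2, "need at least 2 datasets")
  groups <- as.list(seq_len(n))
  active <- seq_len(n)
  s <- sim
  steps <- list()
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_val <- -Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        v <- s[active[ii], active[jj]]
        if (v > best_val) {
          best_val <- v
          best <- c(active[ii], active[jj])
        }
      }
    }
    i <- best[1]
    j <- best[2]
    steps[[length(steps) + 1]] <- list(members = c(groups[[i]], groups[[j]]),
                                       left = groups[[i]],
                                       right = groups[[j]],
                                       similarity = best_val)
    groups[[i]] <- c(groups[[i]], groups[[j]])
    s[i, ] <- pmax(s[i, ], s[j, ])
    s[, i] <- pmax(s[, i], s[, j])
    active <- setdiff(active, j)
  }
  structure(list(order = steps, similarity = sim),
            class = "integration_plan")
}

#' Integrate more than two datasets sequentially
#'
#' At every round the pair of current datasets (raw or already-integrated
#' intermediates) sharing the most highly variable genes is integrated
#' with the pairwise procedure; the intermediate re-enters the pool as a
#' single dataset whose features are its re-scaled shared-gene panel.
#' Ties go to the smallest index pair, so the plan is deterministic.
#'
#' @param datasets list of two or more [count_matrix] objects with
#'   distinct platform tags.
#' @param config a [rescale_config()].
#' @return an `integration_result` whose `batch_labels` are the original
#'   per-cell dataset tags and with a `merge_steps` provenance record.
#' @export
integrate_many <- function(datasets, config = rescale_config()) {
  cfg <- rescale_config(config)
  .stop_if(length(datasets) < 2, "need at least 2 datasets")
  tags <- vapply(datasets, function(d) d$platform, character(1))
  .stop_if(anyDuplicated(tags) > 0, "platform tags must be distinct")

  pool <- datasets
  origin <- lapply(tags, function(t) NULL) # per-pool-item per-cell labels
  names(pool) <- tags
  merge_steps <- list()
  result <- NULL

  while (length(pool) > 1) {
    hvgs <- lapply(pool, .dataset_hvgs, cfg = cfg)
    n <- length(pool)
    best <- c(1L, 2L)
    best_val <- -Inf
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        v <- length(intersect(hvgs[[i]], hvgs[[j]]))
        if (v > best_val) {
          best_val <- v
          best <- c(i, j)
        }
      }
    }
    i <- best[1]
    j <- best[2]
    res <- .integrate_step(pool[[i]], pool[[j]], hvgs[[i]], hvgs[[j]], cfg)
    # per-cell origin labels follow the anchor/query order of the result
    lab_i <- origin[[i]] %||% rep(names(pool)[i], ncol(pool[[i]]$values))
    lab_j <- origin[[j]] %||% rep(names(pool)[j], ncol(pool[[j]]$values))
    labs <- if (res$anchor_was_first) c(lab_i, lab_j) else c(lab_j, lab_i)
    merge_steps[[length(merge_steps) + 1]] <-
      list(left = names(pool)[i], right = names(pool)[j],
           shared_hvg = best_val, baseline_used = res$result$baseline_used,
           mixing = res$result$mixing_score)
    new_name <- paste(names(pool)[i], names(pool)[j], sep = "+")
    inter <- res$result$integrated
    inter$platform <- new_name
    keep <- setdiff(seq_len(n), c(i, j))
    pool <- c(pool[keep], stats::setNames(list(inter), new_name))
    origin <- c(origin[keep], list(labs))
    result <- res$result
    result$dataset_labels <- labs # original per-cell dataset of origin
  }
  result$merge_steps <- merge_steps
  result
}

# One pairwise step where either side may be a raw count matrix or a
# scaled intermediate; intermediates are re-scaled to unit variance on the
# shared panel (they are "one dataset" entering preprocessing at the
# scaling stage).
.integrate_step <- function(a, b, hvg_a, hvg_b, cfg) {
  shared <- shared_hvg(hvg_a, hvg_b)
  prep <- function(x) {
    if (inherits(x, "count_matrix")) {
      scale_genes(.restrict_genes(lognormalize(x, cfg$scale_factor), shared))
    } else {
      idx <- match(shared, x$gene_ids)
      scaled_matrix(.scale_rows(x$values[idx, , drop = FALSE]), shared,
                    x$cell_ids, x$platform)
    }
  }
  sm_a <- prep(a)
  sm_b <- prep(b)
  anchor_first <- length(sm_a$cell_ids) >= length(sm_b$cell_ids)
  res <- if (anchor_first) .integrate_scaled(sm_a, sm_b, cfg) else
    .integrate_scaled(sm_b, sm_a, cfg)
  list(result = res, anchor_was_first = anchor_first)
}
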
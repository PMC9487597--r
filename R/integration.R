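# Proportion-matched subsets, per-gene scaling factors, re-scaling,
# concatenation, the resolution grid search and the baseline fallback.

#' Composition-matched subsets for aligned clusters
#'
#' For each aligned cluster pair (anchor clusters merged into their group),
#' both sides contribute `min(n_anchor, n_query)` cells, the larger side
#' subsampled uniformly without replacement. The two subsets then contain
#' the same cell types in identical proportions, which is what makes their
#' per-gene standard deviations comparable.
#'
#' @param alignment an `alignment_map` with at least one pair.
#' @param anchor_clustering,query_clustering the `clustering` objects the
#'   alignment was computed from.
#' @param seed integer seed for the subsampling.
#' @return list with integer cell index vectors `anchor_idx`, `query_idx`.
#' @export
build_matched_subsets <- function(alignment, anchor_clustering,
                                  query_clustering, seed = 0) {
  .stop_if(nrow(alignment$pairs) == 0,
           "no aligned cluster pairs; use the baseline model")
  labels_a <- anchor_clustering$labels
  labels_q <- query_clustering$labels
  anchor_idx <- integer(0)
  query_idx <- integer(0)
  for (q in sort(unique(alignment$pairs$query))) {
    anchors <- alignment$pairs$anchor[alignment$pairs$query == q]
    cells_a <- which(labels_a %in% anchors)
    cells_q <- which(labels_q == q)
    n <- min(length(cells_a), length(cells_q))
    set.seed(derive_seed(seed, "match", q))
    if (length(cells_a) > n) cells_a <- sort(sample(cells_a, n))
    if (length(cells_q) > n) cells_q <- sort(sample(cells_q, n))
    anchor_idx <- c(anchor_idx, cells_a)
    query_idx <- c(query_idx, cells_q)
  }
  list(anchor_idx = sort(anchor_idx), query_idx = sort(query_idx))
}

#' Per-gene standard deviation over a cell subset
#'
#' Sample standard deviation (ddof = 1) of the already-scaled values over
#' the indexed cells — the scaling factor of the re-scaling step.
#'
#' @param sm a `scaled_matrix`.
#' @param idx integer cell indices, at least 2.
#' @return numeric vector, one sd per gene.
#' @export
subset_sd <- function(sm, idx) {
  .stop_if(length(idx) < 2, "need at least 2 cells to compute a sample sd")
  .row_sd(sm$values[, idx, drop = FALSE])
}

#' Re-scale a whole dataset by per-gene factors
#'
#' Divides every cell's value for gene i by `s[i]`, optionally after
#' subtracting a per-gene shift `m[i]`. Applied dataset-wide with `s` and
#' `m` computed on a composition-matched subset, this standardises each
#' gene to the subset's moments, equalising what whole-dataset centering
#' and unit-variance scaling distorted under unequal compositions.
#'
#' @param sm a `scaled_matrix`.
#' @param s strictly positive per-gene factors (zero-variance replacements
#'   already applied).
#' @param m optional per-gene shift subtracted before division (default
#'   none, i.e. pure division).
#' @return a `scaled_matrix`.
#' @export
rescale <- function(sm, s, m = NULL) {
  .stop_if(length(s) != nrow(sm$values),
           "factor length ", length(s), " does not match ",
           nrow(sm$values), " genes")
  .stop_if(any(s <= 0), "scaling factors must be strictly positive")
  v <- if (is.null(m)) sm$values else sm$values - m
  scaled_matrix(v / s, sm$gene_ids, sm$cell_ids, sm$platform,
                sm$hvg_mask)
}

#' Concatenate two scaled matrices column-wise
#'
#' @param a,b `scaled_matrix` objects with identical gene ids in identical
#'   order.
#' @return list with the combined `scaled_matrix` (`matrix`) and per-cell
#'   `batch_labels` (the input platform tags).
#' @export
concatenate_scaled <- function(a, b) {
  .stop_if(!identical(a$gene_ids, b$gene_ids),
           "gene ids differ or are ordered differently")
  batch <- c(rep(a$platform, length(a$cell_ids)),
             rep(b$platform, length(b$cell_ids)))
  cells <- make.unique(c(a$cell_ids, b$cell_ids))
  list(matrix = scaled_matrix(cbind(a$values, b$values), a$gene_ids, cells,
                              paste(a$platform, b$platform, sep = "+"),
                              a$hvg_mask & b$hvg_mask),
       batch_labels = batch)
}

# Per-gene standardisation moments over the matched subsets: the scaling
# factors s (subset sd, zero-variance genes left at 1) and shifts m
# (subset mean) for each side.
.subset_factors <- function(sm_a, sm_b, subsets) {
  va <- sm_a$values[, subsets$anchor_idx, drop = FALSE]
  vb <- sm_b$values[, subsets$query_idx, drop = FALSE]
  list(s_anchor = stats::setNames(.safe_sd(va), sm_a$gene_ids),
       s_query = stats::setNames(.safe_sd(vb), sm_b$gene_ids),
       m_anchor = stats::setNames(rowMeans(va), sm_a$gene_ids),
       m_query = stats::setNames(rowMeans(vb), sm_b$gene_ids),
       subset_anchor_idx = subsets$anchor_idx,
       subset_query_idx = subsets$query_idx)
}

# Joint PCA of two (already re-scaled) matrices plus the mixing metric.
.joint_mixing <- function(values_a, values_b, batch, cfg, seed_tag) {
  joint <- .pca_matrix(cbind(values_a, values_b), cfg$n_pcs, seed_tag)
  n <- length(batch)
  list(embedding = joint,
       mixing = mixing_metric(joint, batch, k = cfg$mixing_k,
                              k_max = min(cfg$mixing_k_max, n - 1)))
}

#' Baseline integration: direct concatenation
#'
#' Concatenates the independently scaled matrices over the shared gene
#' panel without any re-scaling — the model chosen whenever re-scaling
#' does not lower the mixing metric, and the only option when no cluster
#' pair aligns (for example, datasets with no shared cell types).
#'
#' @param a,b `scaled_matrix` objects on the same gene panel (anchor
#'   first).
#' @param config a [rescale_config()].
#' @return an `integration_result` with `baseline_used = TRUE`.
#' @export
baseline_integrate <- function(a, b, config = rescale_config()) {
  cfg <- rescale_config(config)
  cc <- concatenate_scaled(a, b)
  jm <- .joint_mixing(a$values, b$values, cc$batch_labels, cfg,
                      derive_seed(cfg$seed, "joint", "baseline"))
  .integration_result(cc$matrix, cc$batch_labels, jm, cfg,
                      baseline_used = TRUE)
}

.integration_result <- function(integrated, batch_labels, jm, cfg,
                                baseline_used, chosen_resolutions = NULL,
                                alignment = NULL, factors = NULL,
                                search_trace = NULL, best_rescaled = NULL,
                                orig_embeddings = NULL,
                                baseline_mixing = jm$mixing) {
  structure(list(integrated = integrated,
                 batch_labels = batch_labels,
                 embedding = jm$embedding,
                 mixing_score = jm$mixing,
                 baseline_mixing = baseline_mixing,
                 baseline_used = baseline_used,
                 chosen_resolutions = chosen_resolutions,
                 alignment = alignment,
                 factors = factors,
                 search_trace = search_trace,
                 best_rescaled = best_rescaled,
                 orig_embeddings = orig_embeddings,
                 config = cfg),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration_result: %d genes x %d cells, mixing %.2f, %s\n",
              nrow(x$integrated$values), ncol(x$integrated$values),
              x$mixing_score,
              if (x$baseline_used) "baseline concatenation" else
                sprintf("re-scaled at resolutions (%.1f, %.1f)",
                        x$chosen_resolutions[1], x$chosen_resolutions[2])))
  invisible(x)
}

# Grid search over clustering resolutions on two prepared scaled matrices
# (anchor first, both restricted to the shared gene panel, unit variance).
.integrate_scaled <- function(sm_a, sm_b, cfg) {
  n_a <- length(sm_a$cell_ids)
  n_b <- length(sm_b$cell_ids)
  batch <- c(rep(sm_a$platform, n_a), rep(sm_b$platform, n_b))

  emb_a <- pca_embed(sm_a, cfg$n_pcs, derive_seed(cfg$seed, "emb_a"))
  emb_b <- pca_embed(sm_b, cfg$n_pcs, derive_seed(cfg$seed, "emb_b"))
  graph_a <- .snn_graph(emb_a$scores, cfg$k_neighbors, cfg$snn_prune)
  graph_b <- .snn_graph(emb_b$scores, cfg$k_neighbors, cfg$snn_prune)

  # joint embedding of the un-rescaled concatenation: the alignment space
  # and the baseline model
  jm0 <- .joint_mixing(sm_a$values, sm_b$values, batch, cfg,
                       derive_seed(cfg$seed, "joint", "baseline"))
  joint0 <- jm0$embedding

  grid <- .resolution_grid(cfg)
  cl_a <- lapply(grid, function(r)
    .cluster_graph(graph_a, r, cfg$seed, cfg$cluster_algorithm))
  cl_b <- lapply(grid, function(r)
    .cluster_graph(graph_b, r, cfg$seed, cfg$cluster_algorithm))
  names(cl_a) <- names(cl_b) <- format(grid)

  # distinct clustering pairs only: many resolution pairs repeat the same
  # partition, and the evaluation is a pure function of the partitions
  pair_grid <- expand.grid(qi = seq_along(grid), ai = seq_along(grid))
  pair_grid <- pair_grid[order(pair_grid$ai, pair_grid$qi), ]
  keys <- vapply(seq_len(nrow(pair_grid)), function(i)
    .label_key(cl_a[[pair_grid$ai[i]]]$labels,
               cl_b[[pair_grid$qi[i]]]$labels), character(1))
  first_of_key <- !duplicated(keys)

  eval_key <- function(i) {
    ca <- cl_a[[pair_grid$ai[i]]]
    cb <- cl_b[[pair_grid$qi[i]]]
    key <- keys[i]
    align <- align_clusters(joint0, ca, cb, sm_a, sm_b,
                            seed = derive_seed(cfg$seed, "align", key),
                            n_candidates = cfg$n_candidates)
    if (nrow(align$pairs) == 0) {
      return(list(mixing = NA_real_, n_pairs = 0L, align = align,
                  factors = NULL))
    }
    subsets <- build_matched_subsets(align, ca, cb,
                                     seed = derive_seed(cfg$seed, "subset",
                                                        key))
    f <- .subset_factors(sm_a, sm_b, subsets)
    jm <- .joint_mixing((sm_a$values - f$m_anchor) / f$s_anchor,
                        (sm_b$values - f$m_query) / f$s_query, batch, cfg,
                        derive_seed(cfg$seed, "joint", key))
    list(mixing = jm$mixing, n_pairs = nrow(align$pairs), align = align,
         factors = f)
  }

  todo <- which(first_of_key)
  evals <- if (cfg$n_workers > 1) {
    parallel::mclapply(todo, function(i) suppressWarnings(eval_key(i)),
                       mc.cores = cfg$n_workers)
  } else {
    lapply(todo, function(i) suppressWarnings(eval_key(i)))
  }
  names(evals) <- keys[todo]

  trace <- data.frame(
    r_anchor = grid[pair_grid$ai],
    r_query = grid[pair_grid$qi],
    n_clusters_anchor = vapply(pair_grid$ai, function(i)
      cl_a[[i]]$n_clusters, integer(1)),
    n_clusters_query = vapply(pair_grid$qi, function(i)
      cl_b[[i]]$n_clusters, integer(1)),
    n_aligned_pairs = vapply(keys, function(k) evals[[k]]$n_pairs,
                             integer(1)),
    mixing = vapply(keys, function(k) evals[[k]]$mixing, numeric(1)),
    row.names = NULL)

  orig_embeddings <- stats::setNames(list(emb_a, emb_b),
                                     c(sm_a$platform, sm_b$platform))

  best_rescaled <- NULL
  if (any(!is.na(trace$mixing))) {
    best_i <- which(trace$mixing == min(trace$mixing, na.rm = TRUE))[1]
    best <- evals[[keys[best_i]]]
    best_rescaled <- list(
      resolutions = c(anchor = trace$r_anchor[best_i],
                      query = trace$r_query[best_i]),
      mixing = best$mixing, factors = best$factors, alignment = best$align)
  }

  if (!is.null(best_rescaled) &&
      best_rescaled$mixing < jm0$mixing - 1e-12) {
    f <- best_rescaled$factors
    ra <- rescale(sm_a, f$s_anchor, f$m_anchor)
    rb <- rescale(sm_b, f$s_query, f$m_query)
    cc <- concatenate_scaled(ra, rb)
    best_i <- which(trace$mixing == best_rescaled$mixing)[1]
    jm <- .joint_mixing(ra$values, rb$values, batch, cfg,
                        derive_seed(cfg$seed, "joint", keys[best_i]))
    return(.integration_result(cc$matrix, cc$batch_labels, jm, cfg,
                               baseline_used = FALSE,
                               chosen_resolutions = best_rescaled$resolutions,
                               alignment = best_rescaled$alignment,
                               factors = f, search_trace = trace,
                               best_rescaled = best_rescaled,
                               orig_embeddings = orig_embeddings,
                               baseline_mixing = jm0$mixing))
  }

  cc <- concatenate_scaled(sm_a, sm_b)
  .integration_result(cc$matrix, cc$batch_labels, jm0, cfg,
                      baseline_used = TRUE, chosen_resolutions = NULL,
                      alignment = best_rescaled$alignment,
                      factors = NULL, search_trace = trace,
                      best_rescaled = best_rescaled,
                      orig_embeddings = orig_embeddings)
}

# Preprocess one count matrix: log-normalize, pick HVGs.
.prep_dataset <- function(cm, cfg) {
  nm <- lognormalize(cm, cfg$scale_factor)
  list(nm = nm, hvg = select_hvg(nm, cfg$n_hvg, cfg$hvg_method))
}

#' Integrate a pair of datasets
#'
#' The full pipeline for two count matrices: per-dataset log-normalization,
#' unit-variance scaling and highly-variable-gene selection; PCA and
#' shared-nearest-neighbor clustering of each dataset over a grid of
#' resolution pairs; cluster alignment with the quantile criterion and
#' subsampling retry; per-gene re-scaling from composition-matched
#' subsets; and selection of the resolution pair minimising the mixing
#' metric. When no re-scaled candidate mixes strictly better than plain
#' concatenation, the baseline model is returned. The dataset with more
#' cells is the anchor.
#'
#' @param ds_a,ds_b [count_matrix] objects with distinct platform tags.
#' @param config a [rescale_config()] or arguments for one.
#' @return an `integration_result`: the integrated `scaled_matrix` over
#'   the shared highly variable genes, per-cell `batch_labels`, the joint
#'   `embedding`, `mixing_score`, `chosen_resolutions`, the winning
#'   `alignment`, the scaling `factors` (absent for the baseline),
#'   the full `search_trace` and the per-dataset input embeddings.
#' @export
integrate_pair <- function(ds_a, ds_b, config = rescale_config()) {
  cfg <- rescale_config(config)
  .stop_if(ncol(ds_a$values) == 0 || ncol(ds_b$values) == 0,
           "empty dataset")
  if (ds_a$platform == ds_b$platform) {
    ds_a$platform <- paste0(ds_a$platform, "_1")
    ds_b$platform <- paste0(ds_b$platform, "_2")
  }
  # anchor = dataset with more cells
  if (ncol(ds_b$values) > ncol(ds_a$values)) {
    tmp <- ds_a
    ds_a <- ds_b
    ds_b <- tmp
  }
  prep_a <- .prep_dataset(ds_a, cfg)
  prep_b <- .prep_dataset(ds_b, cfg)
  shared <- shared_hvg(prep_a$hvg, prep_b$hvg)
  sm_a <- scale_genes(.restrict_genes(prep_a$nm, shared))
  sm_b <- scale_genes(.restrict_genes(prep_b$nm, shared))
  res <- .integrate_scaled(sm_a, sm_b, cfg)
  if (cfg$emit_all_genes && !res$baseline_used) {
    res$integrated_all <- .rescale_all_genes(prep_a$nm, prep_b$nm, res)
  }
  res
}

# Extend the winning factors gene-wise to the full gene universe: scale all
# common genes per dataset, recompute subset sds on the matched subsets.
.rescale_all_genes <- function(nm_a, nm_b, res) {
  genes <- sort(intersect(nm_a$gene_ids, nm_b$gene_ids))
  sm_a <- scale_genes(.restrict_genes(nm_a, genes))
  sm_b <- scale_genes(.restrict_genes(nm_b, genes))
  f <- .subset_factors(sm_a, sm_b,
                       list(anchor_idx = res$factors$subset_anchor_idx,
                            query_idx = res$factors$subset_query_idx))
  concatenate_scaled(rescale(sm_a, f$s_anchor, f$m_anchor),
                     rescale(sm_b, f$s_query, f$m_query))$matrix
}
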
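#' Run configuration
#'
#' Central, validated configuration for the whole pipeline. Unknown keys
#' are rejected so typos fail before any computation.
#'
#' @param ... named overrides of the defaults:
#' \describe{
#'   \item{scale_factor}{library-size target of log-normalization (10000).}
#'   \item{n_hvg}{highly variable genes per dataset (4000).}
#'   \item{hvg_method}{`"vst"` or `"dispersion"`.}
#'   \item{n_pcs}{principal components (30); the method is insensitive to
#'     this within a sensible range.}
#'   \item{k_neighbors}{kNN graph neighbourhood size for clustering (20).}
#'   \item{cluster_algorithm}{`"louvain"` or `"leiden"`.}
#'   \item{snn_prune}{SNN Jaccard pruning threshold (1/15).}
#'   \item{resolution_range}{clustering resolution search range
#'     (`c(0.1, 2)`).}
#'   \item{resolution_step}{grid step per axis (0.1; 0.3 gives the coarse
#'     grid used for fast runs).}
#'   \item{seed}{integer run seed (0), fanned out to every stage.}
#'   \item{n_workers}{fork-level parallelism for the resolution grid (1);
#'     the result is independent of the worker count.}
#'   \item{emit_all_genes}{also re-scale genes outside the shared HVG
#'     panel in the integrated output (FALSE).}
#'   \item{mixing_k, mixing_k_max}{mixing metric parameters (5, 300).}
#'   \item{local_k}{local structure metric neighbourhood (20).}
#'   \item{transfer_k}{label transfer / match score neighbourhood (10).}
#'   \item{n_candidates}{candidate query clusters per anchor cluster (5).}
#' }
#' @return a validated list of class `rescale_config`.
#' @export
rescale_config <- function(...) {
  cfg <- list(
    scale_factor = 10000,
    n_hvg = 4000L,
    hvg_method = "vst",
    n_pcs = 30L,
    k_neighbors = 20L,
    cluster_algorithm = "louvain",
    snn_prune = 1 / 15,
    resolution_range = c(0.1, 2),
    resolution_step = 0.1,
    seed = 0L,
    n_workers = 1L,
    emit_all_genes = FALSE,
    mixing_k = 5L,
    mixing_k_max = 300L,
    local_k = 20L,
    transfer_k = 10L,
    n_candidates = 5L
  )
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) &&
      inherits(user[[1]], "rescale_config")) {
    return(user[[1]])
  }
  unknown <- setdiff(names(user), names(cfg))
  .stop_if(length(unknown) > 0, "unknown config keys: ",
           paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  .stop_if(cfg$scale_factor <= 0, "scale_factor must be positive")
  .stop_if(cfg$n_hvg < 1, "n_hvg must be a positive integer")
  .stop_if(!cfg$hvg_method %in% c("vst", "dispersion"),
           "hvg_method must be 'vst' or 'dispersion'")
  .stop_if(cfg$n_pcs < 2, "n_pcs must be at least 2")
  .stop_if(cfg$k_neighbors < 2, "k_neighbors must be at least 2")
  .stop_if(!cfg$cluster_algorithm %in% c("louvain", "leiden"),
           "cluster_algorithm must be 'louvain' or 'leiden'")
  .stop_if(length(cfg$resolution_range) != 2 ||
             cfg$resolution_range[1] <= 0 ||
             diff(cfg$resolution_range) < 0,
           "resolution_range must be positive and increasing")
  .stop_if(cfg$resolution_step <= 0, "resolution_step must be positive")
  .stop_if(cfg$mixing_k_max < cfg$mixing_k,
           "mixing_k_max must be at least mixing_k")
  structure(cfg, class = "rescale_config")
}

# Resolution grid along one axis.
.resolution_grid <- function(cfg) {
  seq(cfg$resolution_range[1], cfg$resolution_range[2],
      by = cfg$resolution_step)
}
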
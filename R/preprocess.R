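# Normalization, per-gene scaling and highly variable gene selection.

#' Log-normalize a count matrix
#'
#' Depth-normalizes each cell to `scale_factor` total counts and applies
#' `log(1 + x)`: entry \eqn{(i,j)} becomes
#' \eqn{\ln(1 + X_{ij} / \sum_i X_{ij} \times s)}. Zero counts stay zero, so
#' sparse storage is preserved.
#'
#' @param cm a [count_matrix].
#' @param scale_factor positive library-size target, default 10,000.
#' @return an object of class `normalized_matrix`.
#' @export
lognormalize <- function(cm, scale_factor = 10000) {
  stopifnot(inherits(cm, "count_matrix"), scale_factor > 0)
  totals <- Matrix::colSums(cm$values)
  zero <- which(totals == 0)
  .stop_if(length(zero) > 0, "cells with zero total counts: ",
           paste(utils::head(cm$cell_ids[zero], 10), collapse = ", "))
  if (methods::is(cm$values, "sparseMatrix")) {
    v <- methods::as(cm$values, "CsparseMatrix")
    # scale column j by scale_factor / totals[j] without densifying
    v@x <- log1p(v@x * rep.int(scale_factor / totals, diff(v@p)))
  } else {
    v <- log1p(sweep(cm$values, 2, totals / scale_factor, "/"))
  }
  structure(list(values = v, scale_factor = scale_factor,
                 gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                 platform = cm$platform),
            class = "normalized_matrix")
}

#' Center and scale each gene to unit variance
#'
#' Each gene row is centered to mean zero and divided by its sample
#' standard deviation (ddof = 1); genes with zero variance become
#' all-zero rows. Centering absorbs the platform mean shifts that
#' different sequencing depths imprint on log-normalized counts (through
#' their different sampling-zero rates); it is what makes the joint
#' embedding usable for cluster alignment. The composition-dependent
#' distortion that centering + unit variance introduce is what the
#' re-scaling step later corrects on matched subsets.
#'
#' @param nm a `normalized_matrix` (or any object with a `values` matrix,
#'   `gene_ids`, `cell_ids`, `platform`).
#' @param hvg_mask optional logical per-gene mask carried through to the
#'   result; defaults to all `TRUE`.
#' @param center subtract the gene mean (default `TRUE`).
#' @return an object of class `scaled_matrix` with dense `values`.
#' @export
scale_genes <- function(nm, hvg_mask = NULL, center = TRUE) {
  v <- .dense(nm$values)
  scaled_matrix(.scale_rows(v, center), nm$gene_ids, nm$cell_ids,
                nm$platform, hvg_mask %||% rep(TRUE, nrow(v)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise unit variance (centered by default); zero-variance rows -> 0.
.scale_rows <- function(v, center = TRUE) {
  sd <- matrixStats::rowSds(v)
  out <- (if (center) v - rowMeans(v) else v) / ifelse(sd > 0, sd, 1)
  out[sd == 0, ] <- 0
  out
}

#' Scaled-expression container
#'
#' Holds the unit-variance expression values `Y` used throughout alignment
#' and re-scaling, plus the per-gene highly-variable mask.
#'
#' @param values dense numeric matrix, genes x cells.
#' @param gene_ids,cell_ids identifiers matching the dimensions.
#' @param platform batch tag.
#' @param hvg_mask logical per gene.
#' @return object of class `scaled_matrix`.
#' @export
scaled_matrix <- function(values, gene_ids, cell_ids, platform,
                          hvg_mask = rep(TRUE, nrow(values))) {
  stopifnot(length(gene_ids) == nrow(values),
            length(cell_ids) == ncol(values),
            length(hvg_mask) == nrow(values))
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 platform = as.character(platform)[1],
                 hvg_mask = as.logical(hvg_mask)),
            class = "scaled_matrix")
}

#' Select highly variable genes
#'
#' Default method `"vst"` follows the variance-stabilizing procedure used by
#' the standard single-cell toolkits: a loess regression (span 0.3, degree 2)
#' of log10 variance on log10 mean of the depth-normalized counts predicts
#' each gene's expected standard deviation; the variance of the standardized
#' values, clipped at `sqrt(n_cells)`, ranks the genes. Method
#' `"dispersion"` ranks by variance/mean of the log-normalized values.
#' Ties are broken by lexicographically smaller gene id, so the ranking is
#' deterministic and invariant to cell order.
#'
#' @param nm a `normalized_matrix`.
#' @param n number of genes to return (default 4000). When `n` exceeds the
#'   number of genes, all genes are returned with a warning.
#' @param method `"vst"` or `"dispersion"`.
#' @return character vector of gene ids, highest-ranked first.
#' @export
select_hvg <- function(nm, n = 4000, method = c("vst", "dispersion")) {
  method <- match.arg(method)
  n_genes <- length(nm$gene_ids)
  if (n > n_genes) {
    warning("n = ", n, " exceeds the ", n_genes,
            " available genes; returning all genes")
    n <- n_genes
  }
  stat <- if (method == "vst") .hvg_vst(nm) else .hvg_dispersion(nm)
  ord <- order(-stat, nm$gene_ids)
  nm$gene_ids[ord][seq_len(n)]
}

.hvg_vst <- function(nm) {
  # depth-normalized counts (expm1 of the log-normalized values)
  v <- nm$values
  if (methods::is(v, "sparseMatrix")) {
    v <- methods::as(v, "CsparseMatrix")
    v@x <- expm1(v@x)
  } else {
    v <- expm1(v)
  }
  n <- ncol(v)
  mu <- as.numeric(Matrix::rowMeans(v))
  ex2 <- as.numeric(Matrix::rowMeans(v^2))
  var <- (ex2 - mu^2) * n / (n - 1)
  var[var < 0] <- 0
  stat <- numeric(length(mu))
  use <- var > 0 & mu > 0
  if (sum(use) < 3) return(var) # too few informative genes for a trend fit
  fit <- tryCatch(
    stats::loess(log10(var[use]) ~ log10(mu[use]), span = 0.3, degree = 2),
    error = function(e) NULL)
  if (is.null(fit)) return(var) # degenerate fixture: rank by raw variance
  sd_exp <- sqrt(10^stats::fitted(fit))
  clip <- sqrt(n)
  vd <- .dense(v)[use, , drop = FALSE]
  z <- (vd - mu[use]) / sd_exp
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  stat[use] <- matrixStats::rowVars(z)
  stat
}

.hvg_dispersion <- function(nm) {
  v <- nm$values
  n <- ncol(v)
  mu <- as.numeric(Matrix::rowMeans(v))
  ex2 <- as.numeric(Matrix::rowMeans(v^2))
  var <- pmax((ex2 - mu^2) * n / (n - 1), 0)
  ifelse(mu > 0, var / mu, 0)
}

#' Genes highly variable in both datasets
#'
#' Set intersection of two highly-variable-gene lists, sorted
#' lexicographically; the feature universe used for a pairwise integration.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @return sorted character vector.
#' @export
shared_hvg <- function(list_a, list_b) {
  shared <- sort(intersect(list_a, list_b))
  .stop_if(length(shared) == 0,
           "no shared highly variable genes; increase n_hvg")
  shared
}

# Restrict a normalized matrix to a gene subset (in the given order).
.restrict_genes <- function(nm, genes) {
  idx <- match(genes, nm$gene_ids)
  .stop_if(anyNA(idx), "genes absent from the matrix: ",
           paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  nm$values <- nm$values[idx, , drop = FALSE]
  nm$gene_ids <- nm$gene_ids[idx]
  nm
}
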
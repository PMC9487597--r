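# Internal helpers shared across the pipeline.

#' Derive a stage-specific RNG seed from the run seed
#'
#' A single run seed fans out to per-stage seeds through a small string hash,
#' so adding or reordering stages does not perturb the randomness of the
#' others. The result is always a valid 32-bit integer seed.
#'
#' @param seed integer run seed.
#' @param ... character or numeric tags identifying the stage.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), function(x) paste(format(x), collapse = "_"),
                      character(1)), collapse = "|")
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 1000003 + h) %% 2147483647)
}

# Exact Euclidean k-nearest neighbours; rows of `query` against rows of `data`.
# Returns list(idx, dist) without any self-exclusion (callers handle that).
.knn <- function(data, query = data, k) {
  stopifnot(k >= 1, k <= nrow(data))
  res <- RANN::nn2(data = data, query = query, k = k,
                   treetype = "kd", searchtype = "standard")
  list(idx = res$nn.idx, dist = res$nn.dists)
}

# Sample standard deviation (ddof = 1) per row of a dense matrix.
.row_sd <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 columns for a sample sd")
  matrixStats::rowSds(m)
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# Dense copy of a possibly sparse matrix.
.dense <- function(m) if (methods::is(m, "sparseMatrix")) as.matrix(m) else m

# Signature string for a pair of label vectors, used to de-duplicate grid
# evaluations that produced identical clusterings.
.label_key <- function(labels_a, labels_b) {
  paste(paste(labels_a, collapse = ","), paste(labels_b, collapse = ","),
        sep = "|")
}
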
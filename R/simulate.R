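# Synthetic multi-platform scRNA-seq generator: type-specific expression
# programs shared across datasets, per-dataset sequencing depth, logistic
# dropout and controllable cell-type compositions.

#' Simulation configuration
#'
#' Describes two or more synthetic datasets over a common gene universe:
#' each cell type has an expression program (a sparse log-normal mean
#' vector with a block of marker genes elevated `marker_fc`-fold), each
#' dataset has a cell count, a composition over the types, a mean library
#' size and a logistic dropout curve in log mean expression. Platform
#' differences are depth + dropout only.
#'
#' @param n_genes genes in the universe.
#' @param type_names character vector of cell type names.
#' @param compositions numeric matrix, datasets x types, rows summing
#'   to 1.
#' @param n_cells integer vector of cells per dataset.
#' @param depth mean library size per dataset (counts).
#' @param dropout_mid logistic dropout midpoint per dataset on the
#'   `log1p(mean)` scale; `-Inf` disables dropout.
#' @param dropout_slope logistic slope per dataset.
#' @param platforms dataset tags (unique).
#' @param seed integer seed; the draw is fully deterministic given it.
#' @param dispersion negative binomial dispersion (1/size), default 0.3.
#' @param marker_frac fraction of genes that are markers of each type
#'   (default 0.1).
#' @param marker_fc fold elevation of marker genes (default 8).
#' @param program_sdlog gene-wise log-sd of each type's diffuse divergence
#'   from the baseline program (default 0.4): distinct types differ
#'   across the whole transcriptome, not only on their marker blocks,
#'   as real cell types do.
#' @param lib_sdlog log-sd of the lognormal library size draw
#'   (default 0.3).
#' @param within_het within-type heterogeneity: log-sd per latent factor
#'   of a rank-3 multiplicative factor model perturbing each cell's
#'   expression program (default 0.2), emulating continuous cell-state
#'   variation; 0 disables it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes, type_names, compositions, n_cells, depth,
                       dropout_mid = rep(-Inf, length(n_cells)),
                       dropout_slope = rep(1, length(n_cells)),
                       platforms = paste0("ds", seq_along(n_cells)),
                       seed = 0, dispersion = 0.3, marker_frac = 0.1,
                       marker_fc = 8, program_sdlog = 0.4, lib_sdlog = 0.3,
                       within_het = 0.15) {
  compositions <- rbind(compositions)
  n_ds <- length(n_cells)
  stopifnot(nrow(compositions) == n_ds,
            ncol(compositions) == length(type_names),
            length(depth) == n_ds, length(dropout_mid) == n_ds,
            length(dropout_slope) == n_ds, length(platforms) == n_ds,
            anyDuplicated(platforms) == 0, all(depth > 0))
  .stop_if(any(abs(rowSums(compositions) - 1) > 1e-8),
           "compositions must sum to 1 per dataset")
  .stop_if(any(compositions < 0), "compositions must be non-negative")
  m <- max(1L, round(marker_frac * n_genes))
  .stop_if(m * length(type_names) > n_genes,
           "n_genes too small for ", length(type_names),
           " marker blocks of ", m, " genes")
  structure(list(n_genes = as.integer(n_genes), type_names = type_names,
                 compositions = compositions,
                 n_cells = as.integer(n_cells), depth = depth,
                 dropout_mid = dropout_mid, dropout_slope = dropout_slope,
                 platforms = platforms, seed = seed,
                 dispersion = dispersion, marker_frac = marker_frac,
                 marker_fc = marker_fc, program_sdlog = program_sdlog,
                 lib_sdlog = lib_sdlog, within_het = within_het),
            class = "sim_config")
}

# Deterministic largest-remainder allocation of n cells to proportions.
.allocate_counts <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    frac <- raw - base
    give <- order(-frac, seq_along(p))[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Simulate multi-platform datasets
#'
#' Draws, per dataset: type labels by deterministic largest-remainder
#' allocation of the composition, lognormal library sizes around the
#' dataset depth, negative binomial counts around the type program scaled
#' to library size, and Bernoulli dropout with keep probability logistic
#' in `log1p(mean)`. Programs are shared across datasets, so cells of one
#' type resemble each other everywhere; only depth, dropout and
#' composition differ.
#'
#' @param cfg a [sim_config()] (e.g. from [scenario()]).
#' @return list with `datasets` (list of [count_matrix]), `truth`
#'   (data.frame cell_id, dataset, type) and `programs` (genes x types
#'   expression proportions).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "programs"))
  base <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  m <- max(1L, round(cfg$marker_frac * cfg$n_genes))
  programs <- vapply(seq_along(cfg$type_names), function(t) {
    # diffuse transcriptome-wide divergence plus a marker block: distinct
    # types differ generically, same types are identical across datasets
    p <- base * stats::rlnorm(cfg$n_genes, sdlog = cfg$program_sdlog)
    p[((t - 1) * m + 1):(t * m)] <- p[((t - 1) * m + 1):(t * m)] *
      cfg$marker_fc
    p / sum(p)
  }, numeric(cfg$n_genes))
  colnames(programs) <- cfg$type_names
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
  rownames(programs) <- gene_ids
  # shared low-rank cell-state directions: within-type variation is
  # correlated across genes, as in real data, not pure sampling noise;
  # the lognormal factor is normalised to mean 1 per gene so the depth
  # contract is preserved
  W <- matrix(stats::rnorm(cfg$n_genes * 3, sd = cfg$within_het),
              cfg$n_genes)
  het_norm <- exp(-0.5 * rowSums(W^2))

  datasets <- vector("list", length(cfg$n_cells))
  truth <- list()
  for (d in seq_along(cfg$n_cells)) {
    set.seed(derive_seed(cfg$seed, "dataset", d))
    n <- cfg$n_cells[d]
    nt <- .allocate_counts(cfg$compositions[d, ], n)
    types <- rep(cfg$type_names, nt)
    lib <- stats::rlnorm(n, meanlog = log(cfg$depth[d]) -
                           cfg$lib_sdlog^2 / 2, sdlog = cfg$lib_sdlog)
    mu <- programs[, types, drop = FALSE] *
      rep(lib, each = cfg$n_genes) # genes x cells mean matrix
    if (cfg$within_het > 0) {
      eta <- matrix(stats::rnorm(3 * n), 3)
      mu <- mu * (het_norm * exp(W %*% eta)) # per-cell state, mean 1
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes)
    if (is.finite(cfg$dropout_mid[d])) {
      keep_p <- stats::plogis(cfg$dropout_slope[d] *
                                (log1p(mu) - cfg$dropout_mid[d]))
      counts <- counts * matrix(stats::rbinom(length(mu), 1,
                                              as.vector(keep_p)),
                                nrow = cfg$n_genes)
    }
    empty <- colSums(counts) == 0
    if (any(empty)) counts[1, empty] <- 1 # guard: no all-zero cells
    cell_ids <- sprintf("%s_c%04d", cfg$platforms[d], seq_len(n))
    datasets[[d]] <- count_matrix(
      methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      gene_ids, cell_ids, cfg$platforms[d])
    truth[[d]] <- data.frame(cell_id = cell_ids,
                             dataset = cfg$platforms[d], type = types)
  }
  list(datasets = datasets, truth = do.call(rbind, truth),
       programs = programs)
}

#' Named simulation scenarios
#'
#' Documented presets reproducing the canonical situations a
#' cross-platform integration method must handle:
#' \describe{
#'   \item{equal_composition}{two platforms, two types at 50/50 in both
#'     datasets; re-scaling should be (near) neutral.}
#'   \item{skewed_composition}{50/50 versus 80/20 over the same two
#'     types; the composition effect distorts unit-variance scaling and
#'     re-scaling should rescue mixing.}
#'   \item{disjoint_types}{no shared types at all; nothing should align
#'     and the baseline must be chosen (the overcorrection guard).}
#'   \item{rare_type}{four shared types, one at 0.4% frequency; label
#'     transfer should still recover it.}
#'   \item{multi_tissue}{four datasets sharing one immune-like type, each
#'     with its own exclusive type.}
#' }
#' The two-platform presets pair a deep, low-dropout plate-like platform
#' (30,000 counts/cell) with a 3x shallower, higher-dropout droplet-like
#' platform (10,000 counts/cell).
#'
#' @param name one of the presets above.
#' @param seed integer seed stored in the config.
#' @return a [sim_config()].
#' @export
scenario <- function(name = c("equal_composition", "skewed_composition",
                              "disjoint_types", "rare_type",
                              "multi_tissue"),
                     seed = 0) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown scenario '", name[1], "'; presets: ",
                          "equal_composition, skewed_composition, ",
                          "disjoint_types, rare_type, multi_tissue",
                          call. = FALSE))
  two_platform <- function(compositions, type_names,
                           n_cells = c(2000L, 2000L)) {
    sim_config(n_genes = 1500, type_names = type_names,
               compositions = compositions, n_cells = n_cells,
               depth = c(30000, 10000), dropout_mid = c(-4, -2),
               dropout_slope = c(1, 1), platforms = c("SS2", "10X"),
               seed = seed)
  }
  switch(name,
    equal_composition = two_platform(rbind(c(0.5, 0.5), c(0.5, 0.5)),
                                     c("type1", "type2")),
    skewed_composition = two_platform(rbind(c(0.5, 0.5), c(0.8, 0.2)),
                                      c("type1", "type2")),
    disjoint_types = sim_config(
      n_genes = 1500, type_names = c("typeA", "typeB", "typeC", "typeD"),
      compositions = rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)),
      n_cells = c(1200L, 1200L), depth = c(30000, 10000),
      dropout_mid = c(-4, -2), dropout_slope = c(1, 1),
      platforms = c("SS2", "10X"), seed = seed),
    rare_type = two_platform(
      rbind(c(0.4, 0.3, 0.296, 0.004), c(0.4, 0.3, 0.296, 0.004)),
      c("type1", "type2", "type3", "rare")),
    multi_tissue = sim_config(
      n_genes = 1500,
      type_names = c("immune", "excl1", "excl2", "excl3", "excl4"),
      compositions = rbind(c(0.65, 0.35, 0, 0, 0), c(0.70, 0, 0.30, 0, 0),
                           c(0.75, 0, 0, 0.25, 0), c(0.60, 0, 0, 0, 0.40)),
      n_cells = rep(800L, 4), depth = c(30000, 10000, 30000, 10000),
      dropout_mid = c(-4, -2, -4, -2), dropout_slope = rep(1, 4),
      platforms = c("tissue1_SS2", "tissue2_10X", "tissue3_SS2",
                    "tissue4_10X"),
      seed = seed))
}
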
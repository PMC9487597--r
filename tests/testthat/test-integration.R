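clust_of <- function(labels) {
  structure(list(labels = as.integer(labels),
                 resolution = NA_real_,
                 n_clusters = length(unique(labels)),
                 sizes = as.integer(table(labels))),
            class = "clustering")
}
align_of <- function(anchor, query) {
  structure(list(pairs = data.frame(anchor = anchor, query = query,
                                    via_retry = logical(length(anchor))),
                 merged_anchor_groups = list(),
                 unaligned_anchor_clusters = integer(),
                 retry_log = data.frame()),
            class = "alignment_map")
}
test_that("matched subsets equalise pair compositions", {
  # equal sizes: everything kept
  al <- align_of(0L, 0L)
  cl10 <- clust_of(rep(0, 10))
  sub <- build_matched_subsets(al, cl10, cl10, seed = 0)
  expect_equal(sub$anchor_idx, 1:10)
  expect_equal(sub$query_idx, 1:10)
  # pairs {(100, 20), (30, 60)} -> 20 + 30 cells per side
  al2 <- align_of(c(0L, 1L), c(0L, 1L))
  cl_a <- clust_of(rep(c(0, 1), c(100, 30)))
  cl_q <- clust_of(rep(c(0, 1), c(20, 60)))
  sub2 <- build_matched_subsets(al2, cl_a, cl_q, seed = 0)
  expect_length(sub2$anchor_idx, 50)
  expect_length(sub2$query_idx, 50)
  comp_a <- table(cl_a$labels[sub2$anchor_idx]) / 50
  comp_q <- table(cl_q$labels[sub2$query_idx]) / 50
  expect_equal(as.numeric(comp_a), c(0.4, 0.6))
  expect_equal(as.numeric(comp_a), as.numeric(comp_q))
  # empty alignment is an error (baseline territory)
  empty <- align_of(integer(), integer())
  expect_error(build_matched_subsets(empty, cl_a, cl_q), "baseline")
})

test_that("subset sd and rescale are mutually consistent", {
  set.seed(4)
  v <- matrix(rexp(30 * 40), 30)
  sm <- scaled_matrix(.scale_rows(v), sprintf("g%02d", 1:30),
                      sprintf("c%02d", 1:40), "x")
  # over all cells the scaled data has unit sd by construction
  expect_equal(unname(subset_sd(sm, 1:40)), rep(1, 30), tolerance = 1e-8)
  # hand-computed two-cell case
  sm2 <- scaled_matrix(matrix(c(0, 2), 1), "g", c("a", "b"), "x")
  expect_equal(unname(subset_sd(sm2, 1:2)), sqrt(2))
  expect_error(subset_sd(sm2, 1), "at least 2")
  # rescale: neutral factors, scalar division, length check
  expect_equal(rescale(sm, rep(1, 30))$values, sm$values)
  expect_equal(unname(rescale(sm2, 2)$values[1, ]), c(0, 1))
  expect_error(rescale(sm, rep(1, 7)), "does not match")
  # self-consistency: rescaling by a subset sd gives unit sd on the subset
  idx <- sample(40, 15)
  rs <- rescale(sm, subset_sd(sm, idx))
  expect_equal(unname(subset_sd(rs, idx)), rep(1, 30), tolerance = 1e-8)
})

test_that("concatenation checks gene panels and tracks batches", {
  a <- scaled_matrix(matrix(1, 3, 2), c("g1", "g2", "g3"),
                     c("a1", "a2"), "SS2")
  b <- scaled_matrix(matrix(2, 3, 4), c("g1", "g2", "g3"),
                     sprintf("b%d", 1:4), "10X")
  cc <- concatenate_scaled(a, b)
  expect_equal(dim(cc$matrix$values), c(3L, 6L))
  expect_equal(cc$batch_labels, rep(c("SS2", "10X"), c(2, 4)))
  # self-concatenation doubles the columns
  self <- concatenate_scaled(a, a)
  expect_equal(ncol(self$matrix$values), 4L)
  bad <- scaled_matrix(matrix(2, 3, 4), c("g2", "g1", "g3"),
                       sprintf("b%d", 1:4), "10X")
  expect_error(concatenate_scaled(a, bad), "gene ids")
})

test_that("re-scaling preserves within-dataset rank correlation structure", {
  set.seed(6)
  v <- .scale_rows(matrix(rexp(40 * 30), 40))
  sm <- scaled_matrix(v, sprintf("g%02d", 1:40), sprintf("c%02d", 1:30),
                      "x")
  rs <- rescale(sm, runif(40, 0.5, 2))
  ranks <- function(m) apply(m, 1, rank)
  cors <- function(m) stats::cor(ranks(m))
  expect_equal(cors(rs$values), cors(sm$values), tolerance = 1e-10)
})

test_that("pairwise integration on matched compositions is near-neutral
           and deterministic", {
  cfg <- rescale_config(resolution_step = 0.5, resolution_range = c(0.4, 1.9),
                        n_hvg = 300, n_pcs = 10, seed = 0,
                        mixing_k_max = 120)
  sc <- sim_config(n_genes = 400, type_names = c("t1", "t2"),
                   compositions = rbind(c(0.5, 0.5), c(0.5, 0.5)),
                   n_cells = c(250L, 250L), depth = c(20000, 20000),
                   platforms = c("p1", "p2"), seed = 0)
  sim <- simulate_pair(sc)
  res <- suppressWarnings(
    integrate_pair(sim$datasets[[1]], sim$datasets[[2]], cfg))
  # identical generative model on both sides: factors hover around 1
  f <- if (is.null(res$factors)) res$best_rescaled$factors else res$factors
  expect_gt(mean(abs(f$s_anchor / f$s_query - 1) < 0.1), 0.9)
  # chosen model never mixes worse than the baseline
  expect_lte(res$mixing_score, res$baseline_mixing)
  # trace covers the full grid and the reported score is its minimum
  grid_n <- length(seq(0.4, 1.9, by = 0.5))^2
  expect_equal(nrow(res$search_trace), grid_n)
  expect_equal(res$mixing_score,
               min(res$search_trace$mixing, res$baseline_mixing,
                   na.rm = TRUE))
  # bit-identical rerun under the same config and seed
  res2 <- suppressWarnings(
    integrate_pair(sim$datasets[[1]], sim$datasets[[2]], cfg))
  expect_identical(res$search_trace, res2$search_trace)
  expect_identical(res$integrated$values, res2$integrated$values)
  expect_identical(res$chosen_resolutions, res2$chosen_resolutions)
})

test_that("the anchor is the larger dataset", {
  sc <- sim_config(n_genes = 300, type_names = c("t1", "t2"),
                   compositions = rbind(c(0.5, 0.5), c(0.5, 0.5)),
                   n_cells = c(120L, 260L), depth = c(20000, 20000),
                   platforms = c("small", "big"), seed = 1)
  sim <- simulate_pair(sc)
  cfg <- rescale_config(resolution_step = 1, resolution_range = c(0.5, 1.5),
                        n_hvg = 200, n_pcs = 8, seed = 0,
                        mixing_k_max = 100)
  res <- suppressWarnings(
    integrate_pair(sim$datasets[[1]], sim$datasets[[2]], cfg))
  # anchor-first column order: the bigger dataset comes first
  expect_equal(res$batch_labels[1], "big")
  expect_setequal(names(res$orig_embeddings), c("small", "big"))
})

test_that("baseline integration mirrors direct concatenation", {
  blobs <- make_blobs(60, p = 6, sep = 3, seed = 10)
  v <- .scale_rows(t(blobs$scores))
  a <- scaled_matrix(v, sprintf("g%d", 1:6), sprintf("a%d", 1:120), "A")
  b <- scaled_matrix(v, sprintf("g%d", 1:6), sprintf("b%d", 1:120), "B")
  cfg <- rescale_config(n_pcs = 4, mixing_k_max = 100, seed = 0)
  res <- baseline_integrate(a, b, cfg)
  expect_true(res$baseline_used)
  expect_null(res$factors)
  expect_equal(ncol(res$integrated$values), 240L)
  # duplicated data interleaves perfectly: mixing near the k=5 optimum
  expect_lt(res$mixing_score, 12)
})
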
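emb_of <- function(scores) {
  structure(list(scores = scores, n_pcs = ncol(scores)),
            class = "embedding")
}
clust_of <- function(labels) {
  structure(list(labels = as.integer(labels),
                 resolution = NA_real_,
                 n_clusters = length(unique(labels)),
                 sizes = as.integer(table(labels))),
            class = "clustering")
}

test_that("cluster centers are per-cluster means", {
  scores <- rbind(c(1, 2), c(-1, -2), c(3, 0), c(5, 2), c(1, 4))
  cc <- cluster_centers(emb_of(scores), clust_of(c(0, 0, 1, 1, 1)))
  expect_equal(unname(cc$centers["0", ]), c(0, 0))        # +v and -v
  expect_equal(unname(cc$centers["1", ]), colMeans(scores[3:5, ]))
  single <- cluster_centers(emb_of(scores[1, , drop = FALSE]),
                            clust_of(0))
  expect_equal(unname(single$centers["0", ]), c(1, 2))
})

test_that("quantile criterion agrees with hand-computed quantiles", {
  center_b <- c(0, 0)
  # radii^2 all 1, center distance^2 = 4 -> reject
  cells1 <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_false(quantile_criterion(c(2, 0), cells1, center_b))
  # squared radii {0,1,2,3}: Q75 = 2.25 by interpolation; distance^2 2 passes
  cells2 <- rbind(c(0, 0), c(1, 0), c(sqrt(2), 0), c(sqrt(3), 0))
  expect_equal(quantile_oracle(c(0, 1, 2, 3), 0.75), 2.25)
  expect_true(quantile_criterion(c(sqrt(2), 0), cells2, center_b))
  # coincident centers always pass against any spread
  expect_true(quantile_criterion(center_b, cells1, center_b))
  # singleton query cluster warns and rejects
  expect_warning(
    ok <- quantile_criterion(c(1, 0), rbind(c(0, 0)), c(0, 0)),
    "single cell")
  expect_false(ok)
})

test_that("quantile criterion matches a sort-based oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:12, 1)
    cells <- matrix(rnorm(n * 3), n)
    center_b <- colMeans(cells)
    center_a <- center_b + rnorm(3, sd = runif(1, 0, 2))
    d2 <- rowSums(sweep(cells, 2, center_b)^2)
    want <- sum((center_a - center_b)^2) < quantile_oracle(d2, 0.75)
    expect_identical(quantile_criterion(center_a, cells, center_b), want)
  }
})

test_that("candidate queries are distance-ranked with id tie-breaks", {
  qc <- list(centers = rbind("0" = c(3, 0), "1" = c(1, 0), "2" = c(0, 2)),
             cluster_sizes = c("0" = 5L, "1" = 5L, "2" = 5L))
  expect_equal(candidate_queries(c(0, 0), qc, m = 5), c(1L, 2L, 0L))
  expect_equal(candidate_queries(c(0, 0), qc, m = 2), c(1L, 2L))
  # equidistant centers: lower id first
  qc2 <- list(centers = rbind("3" = c(1, 0), "1" = c(-1, 0)),
              cluster_sizes = c("3" = 2L, "1" = 2L))
  expect_equal(candidate_queries(c(0, 0), qc2, m = 5), c(1L, 3L))
})

test_that("retry subsample size solves the proportion equation", {
  n_prime <- retry_subsample_size(500, 1000, 0.25)
  expect_identical(n_prime, 166L)
  expect_lte(n_prime / (1000 - 500 + n_prime), 0.25)
  # fixed point: target equal to the current proportion keeps the cluster
  expect_identical(retry_subsample_size(200, 1000, 0.2), 200L)
  expect_error(retry_subsample_size(2, 1000, 1e-4), "too small")
  # bracketing property on random triples
  set.seed(1)
  for (rep in 1:1000) {
    N <- sample(50:5000, 1)
    n <- sample(2:N, 1)
    p <- runif(1, 1e-3, n / N)
    np <- tryCatch(retry_subsample_size(n, N, p), error = function(e) NULL)
    if (is.null(np)) next
    expect_lte(np / (N - n + np), p)
    expect_gt((np + 1) / (N - n + np + 1), p)
  }
})

test_that("identical datasets self-align perfectly without retries", {
  blobs <- make_blobs(40, p = 4, sep = 25, seed = 8)
  sm <- scaled_matrix(t(blobs$scores),
                      sprintf("g%d", 1:4),
                      sprintf("c%d", seq_len(nrow(blobs$scores))), "a")
  joint <- emb_of(rbind(blobs$scores, blobs$scores))
  cl <- clust_of(blobs$labels)
  am <- align_clusters(joint, cl, cl, sm, sm, seed = 0)
  expect_equal(nrow(am$pairs), 2L)
  expect_equal(am$pairs$anchor, am$pairs$query)
  expect_false(any(am$pairs$via_retry))
  expect_length(am$unaligned_anchor_clusters, 0)
  expect_equal(nrow(am$retry_log), 0L)
})

test_that("anchor clusters sharing a query cluster are merged", {
  set.seed(13)
  # query: one blob; anchor: the same blob split artificially in two
  base <- matrix(rnorm(200 * 3, sd = 0.5), 200)
  far <- sweep(matrix(rnorm(60 * 3, sd = 0.5), 60), 2, c(40, 0, 0), "+")
  anchor_scores <- rbind(base[1:100, ], far[1:30, ])
  query_scores <- rbind(base[101:200, ], far[31:60, ])
  joint <- emb_of(rbind(anchor_scores, query_scores))
  cl_a <- clust_of(c(rep(0, 50), rep(1, 50), rep(2, 30))) # 0,1 same blob
  cl_q <- clust_of(c(rep(0, 100), rep(1, 30)))
  sm_a <- scaled_matrix(t(anchor_scores), sprintf("g%d", 1:3),
                        sprintf("a%d", 1:130), "a")
  sm_q <- scaled_matrix(t(query_scores), sprintf("g%d", 1:3),
                        sprintf("q%d", 1:130), "q")
  am <- align_clusters(joint, cl_a, cl_q, sm_a, sm_q, seed = 0)
  expect_equal(nrow(am$pairs), 3L)
  expect_equal(sort(am$pairs$query[am$pairs$anchor %in% c(0, 1)]),
               c(0L, 0L))
  expect_length(am$merged_anchor_groups, 1)
  expect_setequal(am$merged_anchor_groups[[1]], c(0L, 1L))
})

test_that("alignment is invariant to cluster id relabeling", {
  blobs <- make_blobs(40, p = 3, sep = 25, seed = 15)
  joint <- emb_of(rbind(blobs$scores, blobs$scores))
  sm <- scaled_matrix(t(blobs$scores), sprintf("g%d", 1:3),
                      sprintf("c%d", 1:80), "x")
  cl <- clust_of(blobs$labels)
  cl_swapped <- clust_of(1L - blobs$labels)
  am <- align_clusters(joint, cl, cl, sm, sm, seed = 0)
  am_sw <- align_clusters(joint, cl_swapped, cl, sm, sm, seed = 0)
  # same pairing after mapping ids back (0 <-> 1 on the anchor side)
  mapped <- data.frame(anchor = 1L - am_sw$pairs$anchor,
                       query = am_sw$pairs$query)
  expect_equal(mapped[order(mapped$anchor), ],
               am$pairs[order(am$pairs$anchor), c("anchor", "query")],
               ignore_attr = TRUE)
})
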
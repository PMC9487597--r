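# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (sorting, explicit loops, all-pairs distances) and share
# no code with the implementation they check.

# Linear-interpolation quantile computed from first principles.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Pair-counting adjusted Rand index: enumerate all unordered pairs.
ari_oracle <- function(a, b) {
  n <- length(a)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) ss <- ss + 1
      else if (same_a) sd <- sd + 1
      else if (same_b) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  total <- ss + sd + ds + dd
  expected <- (ss + sd) * (ss + ds) / total
  denom <- ((ss + sd) + (ss + ds)) / 2 - expected
  if (denom == 0) return(0)
  (ss - expected) / denom
}

# Quadratic-time mixing metric: full distance matrix, explicit rank scan.
mixing_oracle <- function(scores, batch, k, k_max) {
  n <- nrow(scores)
  d <- as.matrix(stats::dist(scores))
  batches <- sort(unique(batch))
  cell_scores <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])           # neighbours by increasing distance
    nb <- batch[-i][ord][seq_len(k_max)]
    ranks <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      pos <- which(nb == batches[bi])
      ranks[bi] <- if (length(pos) >= k) pos[k] else k_max + 1
    }
    cell_scores[i] <- stats::median(ranks)
  }
  mean(cell_scores)
}

# Brute-force mean silhouette width.
silhouette_oracle <- function(scores, labels) {
  n <- nrow(scores)
  d <- as.matrix(stats::dist(scores))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Two well-separated Gaussian blobs in `p` dimensions.
make_blobs <- function(n_per, p = 5, sep = 20, seed = 1) {
  set.seed(seed)
  scores <- rbind(matrix(rnorm(n_per * p), n_per),
                  matrix(rnorm(n_per * p, mean = sep), n_per))
  list(scores = scores, labels = rep(c(0L, 1L), each = n_per))
}
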
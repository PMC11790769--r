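# Independent oracles used by the property tests.  These deliberately avoid
# the package's own dynamic-programming / Lance-Williams code paths.

# DTW by exhaustive enumeration of all monotone warping paths from (1,1) to
# (n,m).  Exponential; only for sequences of length <= ~7.
oracleDTW <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 1) else as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  localCost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + localCost(i, j)
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (acc >= best) return(invisible())   # a prefix cannot shrink: costs >= 0
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    invisible()
  }
  rec(1, 1, 0)
  best
}

# Brute-force greedy agglomeration where the distance between two clusters is
# recomputed from scratch at every step by `clusterDist`.  Returns the merge
# heights and the canonicalized partition after each merge.
oracleAgglomerate <- function(n, clusterDist) {
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  membership <- function() {
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    match(lab, unique(lab))
  }
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(length(clusters) - 1L)) for (j in (i + 1L):length(clusters)) {
      d <- clusterDist(clusters[[i]], clusters[[j]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    partitions[[length(partitions) + 1L]] <- membership()
  }
  list(heights = heights, partitions = partitions)
}

# Cluster-distance definitions for the oracle.  single/complete/average work
# on an arbitrary dissimilarity matrix; centroid and ward work on a 2-D
# point configuration whose pairwise squared Euclidean distances form the
# input matrix (centroid distance = squared distance between centroids; the
# Ward merge objective, scaled so singleton pairs match the input matrix).
oracleClusterDist <- function(method, D = NULL, pts = NULL) {
  switch(method,
    single = function(A, B) min(D[A, B]),
    complete = function(A, B) max(D[A, B]),
    average = function(A, B) mean(D[A, B, drop = FALSE]),
    centroid = function(A, B) {
      sum((colMeans(pts[A, , drop = FALSE]) - colMeans(pts[B, , drop = FALSE]))^2)
    },
    ward = function(A, B) {
      nA <- length(A); nB <- length(B)
      2 * nA * nB / (nA + nB) *
        sum((colMeans(pts[A, , drop = FALSE]) - colMeans(pts[B, , drop = FALSE]))^2)
    },
    stop("unknown method"))
}

# Partition after each merge of a HierarchyResult, canonicalized the same way
# as the oracle's.
implPartitions <- function(hier) {
  n <- length(hier@labels)
  lab <- seq_len(n)
  out <- list()
  groupOf <- list()
  for (s in seq_len(nrow(hier@merge))) {
    mem <- function(node) if (node < 0L) -node else groupOf[[node]]
    g <- c(mem(hier@merge[s, 1L]), mem(hier@merge[s, 2L]))
    groupOf[[s]] <- g
    lab[g] <- min(lab[g])
    out[[s]] <- match(lab, unique(lab))
  }
  out
}

totalVariation <- function(x) sum(abs(diff(x)))

euclidDist <- function(a, b) sqrt(sum((a - b)^2))
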
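#' Heading-angle series of a trajectory
#'
#' The heading at each step is the direction of the displacement in a
#' mathematically conventional frame: image y points down, so the angle of
#' `(dx, -dy)` is taken, making counterclockwise positive and 0 degrees =
#' rightward (a displacement straight "up" on screen is +90).
#' Displacements shorter than `minStepPx` (including zero-length ones) have
#' no reliable direction and reuse the previous heading; leading undefined
#' headings are backfilled from the first defined one.  The series is then
#' unwrapped so successive differences lie in (-180, 180] and turns
#' accumulate continuously past +-360.
#'
#' @param traj matrix of positions (columns x, y, pixels or normalized).
#' @param minStepPx minimum displacement length for a defined heading.
#' @return numeric vector of unwrapped headings in degrees, length
#'   `nrow(traj) - 1`.
#' @export
headingSeries <- function(traj, minStepPx = 0) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 2L) stop("need at least two points")
  dx <- diff(traj[, 1L]); dy <- diff(traj[, 2L])
  len <- sqrt(dx^2 + dy^2)
  valid <- len > 0 & len >= minStepPx
  if (!any(valid)) stop("no displacement reaches minStepPx: heading undefined")
  raw <- rep(NA_real_, length(dx))
  raw[valid] <- atan2(-dy[valid] + 0, dx[valid]) * 180 / pi  # +0 kills -0
  # carry the previous defined heading into sub-threshold steps
  firstValid <- which(valid)[1L]
  raw[seq_len(firstValid - 1L)] <- raw[firstValid]
  for (i in seq_along(raw)[-1L]) if (is.na(raw[i])) raw[i] <- raw[i - 1L]
  unwrapDegrees(raw)
}

#' Unwrap a heading series
#'
#' Adds or subtracts multiples of 360 degrees so that successive differences
#' lie in (-180, 180], removing the wrap-around discontinuity (e.g. raw
#' headings 170, -170 become 170, 190).  Re-wrapping the result modulo 360
#' recovers the raw headings.
#'
#' @param raw numeric vector of headings in degrees.
#' @return unwrapped series (same length; first value unchanged).
#' @export
unwrapDegrees <- function(raw) {
  if (length(raw) < 2L) return(raw)
  d <- diff(raw)
  wd <- ((d + 180) %% 360) - 180
  wd[wd == -180] <- 180
  c(raw[1L], raw[1L] + cumsum(wd))
}

#' Wrap angles back to (-180, 180]
#'
#' Inverse of the unwrapping step up to multiples of 360 degrees.
#'
#' @param u numeric vector, degrees.
#' @return wrapped angles in (-180, 180].
#' @export
wrapDegrees <- function(u) {
  w <- ((u + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Gaussian smoothing of an angle series
#'
#' 1-D convolution with a normalized discrete Gaussian.  A "kernel size" of
#' `k` means a window of `2k + 1` samples with standard deviation `k / 2`,
#' so kernel sizes 3 and 10 give progressively smoother series.  Reflect
#' padding (edge value included in the mirror) keeps the output length equal
#' to the input length; a constant series is a fixed point because the
#' weights sum to 1.
#'
#' @param x numeric vector (unwrapped degrees; smoothing on the unwrapped
#'   scale avoids 359 -> 1 artifacts).
#' @param kernelSize integer >= 1.
#' @return smoothed series, same length.
#' @export
gaussianSmooth <- function(x, kernelSize) {
  kernelSize <- as.integer(kernelSize)
  if (kernelSize < 1L) stop("kernelSize must be >= 1")
  n <- length(x)
  if (n < 2L) stop("series must have at least 2 samples")
  k <- kernelSize
  w <- exp(-((-k):k)^2 / (2 * (k / 2)^2))
  w <- w / sum(w)
  # reflect-pad: mirror with the edge sample duplicated, period 2n
  idx <- (1L - k):(n + k)
  j <- (idx - 1L) %% (2L * n)
  j[j < 0L] <- j[j < 0L] + 2L * n
  j <- ifelse(j >= n, 2L * n - 1L - j, j) + 1L
  xp <- x[j]
  y <- stats::filter(xp, w, sides = 2)
  as.numeric(y[(k + 1L):(k + n)])
}

#' Gaussian kernel weights used by [gaussianSmooth()]
#'
#' @param kernelSize integer >= 1.
#' @return normalized weights of length `2 * kernelSize + 1`.
#' @export
gaussianKernel <- function(kernelSize) {
  k <- as.integer(kernelSize)
  stopifnot(k >= 1L)
  w <- exp(-((-k):k)^2 / (2 * (k / 2)^2))
  w / sum(w)
}

# ---- agglomerative hierarchy via Lance-Williams updates ---------------------

# Post-merge distance from the merged cluster (i, j) to cluster k.
lanceWilliamsUpdate <- function(dik, djk, dij, ni, nj, nk, method) {
  switch(method,
    single = pmin(dik, djk),
    complete = pmax(dik, djk),
    average = (ni * dik + nj * djk) / (ni + nj),
    centroid = (ni * dik + nj * djk) / (ni + nj) -
      ni * nj * dij / (ni + nj)^2,
    ward = ((ni + nk) * dik + (nj + nk) * djk - nk * dij) / (ni + nj + nk),
    stop(sprintf("unknown linkage method '%s'", method)))
}

#' Agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' Classic agglomeration: start from singletons, repeatedly merge the two
#' closest clusters, and update all distances to the merged cluster with the
#' Lance--Williams recurrence of the chosen linkage.  `ward` minimizes the
#' within-group variance increase at each merge (applied directly to the
#' provided dissimilarities, the common practice for DTW distances);
#' `single`, `complete`, `average` and `centroid` are also available.  Ties
#' in the closest pair break deterministically toward the earliest pair in
#' row-major order.
#'
#' The flat clustering is obtained by deleting every merge whose height
#' exceeds `cutoffHeight` and taking connected components of the remaining
#' merge forest — the dendrogram cut drawn as a horizontal line at the
#' chosen height.
#'
#' @param dmat a [DissimilarityMatrix-class] or square symmetric matrix.
#' @param method one of `"ward"`, `"single"`, `"complete"`, `"average"`,
#'   `"centroid"`.
#' @param cutoffHeight cut height in the units of the input dissimilarities
#'   (for DTW over degree-valued series these are accumulated degrees, where
#'   cut values in the thousands are typical).  `Inf` yields one cluster.
#' @return a [HierarchyResult-class].
#' @export
hierarchicalCluster <- function(dmat, method = c("ward", "single", "complete",
                                                 "average", "centroid"),
                                cutoffHeight = Inf) {
  method <- match.arg(method)
  m <- if (is(dmat, "DissimilarityMatrix")) as.matrix(dmat) else as.matrix(dmat)
  n <- nrow(m)
  if (n < 2L) stop("need at least two subjects")
  subj <- rownames(m) %||% paste0("s", seq_len(n))
  d <- m
  size <- rep(1L, n)
  code <- -(seq_len(n))      # hclust convention: negative = singleton
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- Inf; bi <- 0L; bj <- 0L
    for (ii in seq_len(length(idx) - 1L)) {
      i <- idx[ii]
      for (jj in (ii + 1L):length(idx)) {
        j <- idx[jj]
        if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
      }
    }
    height[step] <- best
    pair <- c(code[bi], code[bj])
    pair <- pair[order(pair >= 0, abs(pair))]  # singletons first, then by id
    merge[step, ] <- pair
    for (k in idx) {
      if (k == bi || k == bj) next
      d[bi, k] <- d[k, bi] <- lanceWilliamsUpdate(
        d[bi, k], d[bj, k], d[bi, bj], size[bi], size[bj], size[k], method)
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
    code[bi] <- step
  }
  ord <- dendroOrder(merge, n)
  flat <- cutMergeForest(merge, height, n, cutoffHeight, subj)
  new("HierarchyResult", method = method, merge = merge, height = height,
      order = ord, labels = subj, cutoff = as.numeric(cutoffHeight),
      flatLabels = flat)
}

# Leaf order by left-to-right traversal of the merge tree.
dendroOrder <- function(merge, n) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  as.integer(rec(nrow(merge)))
}

# Connected components after deleting merges above the cutoff; labels are
# 1-based in order of first appearance over the subjects.
cutMergeForest <- function(merge, height, n, cutoff, subj) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  anyLeaf <- integer(nrow(merge))
  leafOf <- function(node, step) if (node < 0L) -node else anyLeaf[node]
  for (s in seq_len(nrow(merge))) {
    a <- leafOf(merge[s, 1L], s); b <- leafOf(merge[s, 2L], s)
    anyLeaf[s] <- a
    if (height[s] <= cutoff) parent[find(a)] <- find(b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  stats::setNames(as.integer(factor(comp, levels = unique(comp))), subj)
}

#' Recut an existing hierarchy at a new height
#'
#' @param hier a [HierarchyResult-class].
#' @param cutoffHeight new cut height.
#' @return a [HierarchyResult-class] with updated cutoff and flat labels.
#' @export
cutHierarchy <- function(hier, cutoffHeight) {
  n <- length(hier@labels)
  flat <- cutMergeForest(hier@merge, hier@height, n, cutoffHeight, hier@labels)
  initialize(hier, cutoff = as.numeric(cutoffHeight), flatLabels = flat)
}

#' Convert a hierarchy to a base-R hclust object
#'
#' Lets standard tooling ([stats::plot.hclust()], [stats::cutree()],
#' [stats::as.dendrogram()]) operate on the result.
#'
#' @param hier a [HierarchyResult-class].
#' @return an object of class `hclust`.
#' @export
asHclust <- function(hier) {
  structure(list(merge = hier@merge, height = hier@height,
                 order = hier@order, labels = hier@labels,
                 method = hier@method, call = match.call(),
                 dist.method = "dtw"),
            class = "hclust")
}

#' Mean angle profile of each cluster
#'
#' Every member series is linearly resampled to a common length `L`
#' (default: the shortest member), then the pointwise arithmetic mean and
#' population standard deviation are taken across members on the unwrapped
#' scale — the mean curve with its SD band.
#'
#' @param seriesList named list of numeric angle series (unwrapped degrees).
#' @param labels cluster labels named by (or ordered as) the series.
#' @param L resample length.
#' @return named list of [ClusterProfile-class] objects, one per cluster.
#' @export
clusterMeanProfile <- function(seriesList, labels, L = NULL) {
  if (is.null(names(labels))) names(labels) <- names(seriesList)
  if (is.null(L)) L <- min(lengths(seriesList))
  L <- as.integer(L)
  stopifnot(L >= 2L)
  resample <- function(x) {
    if (length(x) == L) return(as.numeric(x))
    stats::approx(seq(0, 1, length.out = length(x)), x,
                  xout = seq(0, 1, length.out = L))$y
  }
  out <- list()
  for (cl in unique(labels)) {
    mem <- names(labels)[labels == cl]
    if (!length(mem)) stop("every cluster must be non-empty")
    mat <- vapply(seriesList[mem], resample, numeric(L))
    mu <- rowMeans(mat)
    sdv <- sqrt(rowMeans((mat - mu)^2))   # population SD
    out[[as.character(cl)]] <- new("ClusterProfile",
                                   cluster = as.character(cl),
                                   mean = mu, sd = sdv)
  }
  out
}

#' Cumulative DTW cost matrix between two cluster profiles
#'
#' The full accumulated-cost matrix of DTW (absolute-difference cost)
#' between the mean angle curves of two clusters; the bottom-right cell is
#' the reported between-cluster distance, and a greater value indicates
#' lower similarity.
#'
#' @param profileA,profileB [ClusterProfile-class] objects.
#' @return list with `costMatrix` and `distance`.
#' @export
clusterCostMatrix <- function(profileA, profileB) {
  r <- dtwDistance(profileA@mean, profileB@mean, localCost = "absdiff1d",
                   returnMatrix = TRUE)
  list(costMatrix = r$costMatrix, distance = r$distance)
}
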
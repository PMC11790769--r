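#' Clip a time window out of a track
#'
#' Selects the samples with `startS <= t < startS + durationS`, where `t` is
#' measured from the first frame of the track — e.g. the initial 30 s of the
#' tracking period, the window used to compare early exploration styles.
#'
#' @param track a [Track-class].
#' @param startS window start, seconds from the track start.
#' @param durationS window length, seconds.
#' @param dropUndefined drop samples with undefined (pre-first-detection)
#'   positions?
#' @return matrix of pixel positions (columns x, y) with attribute `fps`.
#' @export
clipWindow <- function(track, startS, durationS, dropUndefined = TRUE) {
  if (durationS <= 0) stop("durationS must be positive")
  s <- track@samples
  t <- (s$frame - track@startFrame) / track@fps
  trackLenS <- (track@endFrame - track@startFrame + 1L) / track@fps
  if (startS < 0 || startS + durationS > trackLenS + 1e-9)
    stop("window extends beyond the track")
  keep <- t >= startS & t < startS + durationS
  if (dropUndefined) keep <- keep & !is.na(s$x)
  if (!any(keep)) stop("window contains no samples")
  out <- cbind(x = s$x[keep], y = s$y[keep])
  attr(out, "fps") <- track@fps
  out
}

#' Normalize a trajectory to the unit square
#'
#' Adjusts trajectories recorded in different arenas to the same area: a
#' per-axis affine map sends the arena rectangle to `[0,1]^2`, so
#' geometrically similar paths in different-sized arenas become identical.
#'
#' @param trajPx matrix of pixel positions (columns x, y).
#' @param arenaRect arena rectangle `c(x0, y0, x1, y1)` or polygon matrix
#'   (its bounding box is used).
#' @return matrix of positions in `[0,1]^2`.
#' @export
normalizeTrajectory <- function(trajPx, arenaRect) {
  if (!is.null(dim(arenaRect)))
    arenaRect <- c(min(arenaRect[, 1]), min(arenaRect[, 2]),
                   max(arenaRect[, 1]), max(arenaRect[, 2]))
  w <- arenaRect[3L] - arenaRect[1L]; h <- arenaRect[4L] - arenaRect[2L]
  if (w <= 0 || h <= 0) stop("degenerate arena rectangle")
  eps <- 1e-9 * max(w, h)
  if (any(trajPx[, 1] < arenaRect[1L] - eps | trajPx[, 1] > arenaRect[3L] + eps |
          trajPx[, 2] < arenaRect[2L] - eps | trajPx[, 2] > arenaRect[4L] + eps))
    stop("trajectory leaves the arena rectangle")
  out <- cbind(x = (trajPx[, 1] - arenaRect[1L]) / w,
               y = (trajPx[, 2] - arenaRect[2L]) / h)
  pmin(pmax(out, 0), 1)
}

#' Embed a dissimilarity matrix in the plane
#'
#' Metric multidimensional scaling by classical (Torgerson) scaling: the
#' double-centered squared-dissimilarity matrix is eigendecomposed and the
#' top `dims` components are returned.  For matrices that are exactly
#' Euclidean in `dims` dimensions this reproduces the configuration up to
#' rigid motion (stress ~ 0); it is deterministic, so repeated runs give
#' identical embeddings.  The normalized residual stress
#' `sqrt(sum((d - dhat)^2) / sum(d^2))` is reported.
#'
#' @param dmat a [DissimilarityMatrix-class] (or square symmetric matrix).
#' @param dims embedding dimension (default 2, the space of the MDS scatter
#'   plot with the k-means centroids).
#' @return list with `coords` (n x dims, rownames = subjects) and `stress`.
#' @export
mdsEmbed <- function(dmat, dims = 2L) {
  m <- if (is(dmat, "DissimilarityMatrix")) as.matrix(dmat) else as.matrix(dmat)
  n <- nrow(m)
  co <- suppressWarnings(stats::cmdscale(m, k = min(dims, n - 1L)))
  if (ncol(co) < dims)
    co <- cbind(co, matrix(0, n, dims - ncol(co)))
  rownames(co) <- rownames(m)
  dhat <- as.matrix(stats::dist(co))
  num <- sum((m - dhat)[upper.tri(m)]^2)
  den <- sum(m[upper.tri(m)]^2)
  list(coords = co, stress = if (den > 0) sqrt(num / den) else 0)
}

#' Choose k by silhouette and cluster with k-means
#'
#' For each candidate k, seeded k-means (multiple restarts) is run on the
#' MDS coordinates and the mean silhouette width is computed in the same
#' space; the k maximizing the mean silhouette is selected (ties go to the
#' smaller k).  Cluster labels are 0-based (clusters 0, 1, 2, ...).  Each
#' cluster's medoid — the member minimizing the summed DTW distance to its
#' co-members — is reported as the representative subject.
#'
#' @param coords n x d MDS coordinates (rownames = subjects); see
#'   [mdsEmbed()].
#' @param dmat the [DissimilarityMatrix-class] the coordinates came from
#'   (used for medoids); optional.
#' @param kRange candidate cluster counts (default `2:min(n-1, 10)`).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts per k.
#' @param stress MDS stress to record in the result.
#' @return a [TrajClusterResult-class].
#' @export
selectKAndCluster <- function(coords, dmat = NULL, kRange = NULL, seed = 1L,
                              nstart = 10L, stress = NA_real_) {
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 subjects")
  if (is.null(kRange)) kRange <- 2L:min(n - 1L, 10L)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L) || any(kRange > n - 1L))
    stop("kRange must lie in 2..n-1")
  subj <- rownames(coords) %||% paste0("s", seq_len(n))
  dcoord <- stats::dist(coords)
  fits <- list(); sil <- numeric(length(kRange))
  withr::with_seed(as.integer(seed), {
    for (ki in seq_along(kRange)) {
      k <- kRange[ki]
      fit <- stats::kmeans(coords, centers = k, nstart = nstart,
                           iter.max = 100L)
      fits[[ki]] <- fit
      sil[ki] <- mean(cluster::silhouette(fit$cluster, dcoord)[, "sil_width"])
    }
  })
  names(sil) <- kRange
  bestIdx <- which.max(sil)   # ties resolve to the smaller k (first index)
  fit <- fits[[bestIdx]]
  labels <- stats::setNames(as.integer(fit$cluster) - 1L, subj)
  medoids <- character(0)
  if (!is.null(dmat)) {
    dm <- as.matrix(dmat)[subj, subj, drop = FALSE]
    medoids <- vapply(sort(unique(labels)), function(cl) {
      mem <- subj[labels == cl]
      mem[which.min(rowSums(dm[mem, mem, drop = FALSE]))]
    }, character(1))
    names(medoids) <- sort(unique(labels))
  }
  new("TrajClusterResult", k = kRange[bestIdx], labels = labels,
      silhouetteByK = sil, coords = as.matrix(coords),
      centroids = fit$centers, medoids = medoids,
      stress = as.numeric(stress))
}

#' Full trajectory-clustering pipeline
#'
#' Normalized trajectories -> pairwise DTW dissimilarities -> 2-D MDS
#' embedding -> silhouette-selected k-means.  Deterministic under a fixed
#' seed.
#'
#' @param trajectories named list of two-column matrices (unit-square
#'   coordinates; see [normalizeTrajectory()]).
#' @param kRange,seed,nstart passed to [selectKAndCluster()].
#' @param dims MDS embedding dimension.
#' @param band optional Sakoe--Chiba radius for DTW.
#' @return list with `dissimilarity` ([DissimilarityMatrix-class]), `mds`
#'   (see [mdsEmbed()]) and `clustering` ([TrajClusterResult-class]).
#' @export
clusterTrajectories <- function(trajectories, kRange = NULL, seed = 1L,
                                nstart = 10L, dims = 2L, band = NULL) {
  dmat <- dissimilarityMatrix(trajectories, band = band)
  mds <- mdsEmbed(dmat, dims = dims)
  res <- selectKAndCluster(mds$coords, dmat, kRange = kRange, seed = seed,
                           nstart = nstart, stress = mds$stress)
  list(dissimilarity = dmat, mds = mds, clustering = res)
}
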
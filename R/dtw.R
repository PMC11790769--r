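#' Dynamic time warping distance between two sequences
#'
#' Classic unnormalized DTW: the sequences are aligned by a monotone warping
#' path and the distance is the minimal summed local cost,
#' `D(i,j) = cost(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))` with
#' `D(1,1) = cost(1,1)`.  The local cost is the absolute difference for 1-D
#' series (heading angles in degrees) or the Euclidean distance for 2-D
#' trajectories.  No path-length normalization is applied, so longer
#' sequences accumulate larger costs — the convention used throughout the
#' clustering pipelines.
#'
#' @param a,b numeric vectors (1-D) or two-column matrices (2-D); both
#'   non-empty and of the same dimensionality.
#' @param localCost `"euclidean2d"` or `"absdiff1d"`; inferred from the
#'   input shape when omitted.
#' @param band optional Sakoe--Chiba band radius (samples); warping paths
#'   are restricted to a corridor around the (length-scaled) diagonal.
#'   `NULL` (default) imposes no constraint.
#' @param returnMatrix return the full accumulated-cost matrix (needed for
#'   the cumulative cost-matrix heatmaps)?
#' @return list with `distance` (the bottom-right accumulated cost) and
#'   `costMatrix` (n x m matrix, or `NULL` if not requested).
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 2, 3))$distance  # 0: warping absorbs the repeat
#' @export
dtwDistance <- function(a, b, localCost = NULL, band = NULL,
                        returnMatrix = TRUE) {
  a <- seqAsMatrix(a); b <- seqAsMatrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("sequences must be non-empty")
  if (ncol(a) != ncol(b)) stop("sequences must have the same dimensionality")
  if (!is.null(localCost)) {
    localCost <- match.arg(localCost, c("euclidean2d", "absdiff1d"))
    needed <- if (localCost == "euclidean2d") 2L else 1L
    if (ncol(a) != needed)
      stop(sprintf("localCost '%s' needs %d-dimensional sequences", localCost, needed))
  }
  D <- dtwAccumulatedCost(a, b, if (is.null(band)) -1L else as.integer(band))
  dist <- D[nrow(a), nrow(b)]
  if (!is.finite(dist)) stop("no warping path within the band; widen it")
  list(distance = dist, costMatrix = if (returnMatrix) D else NULL)
}

seqAsMatrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  as.matrix(x)
}

#' Pairwise DTW dissimilarity matrix of 2-D trajectories
#'
#' Computes all pairwise DTW distances (Euclidean local cost) among a set of
#' trajectories, typically normalized to the unit square first so arenas of
#' different sizes are comparable.
#'
#' @param trajectories named list of two-column matrices.
#' @param band optional Sakoe--Chiba radius passed to [dtwDistance()].
#' @return a [DissimilarityMatrix-class].
#' @seealso [angleDissimilarityMatrix()], [mdsEmbed()], [selectKAndCluster()]
#' @export
dissimilarityMatrix <- function(trajectories, band = NULL) {
  pairwiseDTW(lapply(trajectories, seqAsMatrix), band)
}

#' Pairwise DTW dissimilarity matrix of heading-angle series
#'
#' Absolute-difference local cost on unwrapped degrees.
#'
#' @param seriesList named list of numeric vectors (unwrapped degrees).
#' @param band optional Sakoe--Chiba radius.
#' @return a [DissimilarityMatrix-class].
#' @export
angleDissimilarityMatrix <- function(seriesList, band = NULL) {
  pairwiseDTW(lapply(seriesList, seqAsMatrix), band)
}

pairwiseDTW <- function(mats, band = NULL) {
  n <- length(mats)
  if (n < 2L) stop("need at least two series")
  if (is.null(names(mats))) names(mats) <- paste0("s", seq_len(n))
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v[i, j] <- v[j, i] <- dtwDistance(mats[[i]], mats[[j]], band = band,
                                      returnMatrix = FALSE)$distance
  }
  new("DissimilarityMatrix", values = v, subjects = names(mats))
}
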
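#' Plot a trajectory
#'
#' Path of the centroid in image coordinates (y axis flipped so the plot
#' matches the video orientation).
#'
#' @param traj two-column matrix of positions, or a [Track-class].
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plotTrajectory <- function(traj, main = "Trajectory", ...) {
  if (is(traj, "Track")) traj <- cbind(traj@samples$x, traj@samples$y)
  graphics::plot(traj[, 1L], traj[, 2L], type = "l", asp = 1,
                 ylim = rev(range(traj[, 2L], na.rm = TRUE)),
                 xlab = "x (px)", ylab = "y (px)", main = main, ...)
  graphics::points(traj[1L, 1L], traj[1L, 2L], pch = 16, col = "forestgreen")
  graphics::points(traj[nrow(traj), 1L], traj[nrow(traj), 2L], pch = 17,
                   col = "firebrick")
}

#' Plot an occupancy heatmap
#'
#' @param grid count matrix from [occupancyHeatmap()].
#' @param main plot title.
#' @export
plotOccupancy <- function(grid, main = "Occupancy") {
  xb <- attr(grid, "xBreaks"); yb <- attr(grid, "yBreaks")
  graphics::image(x = xb, y = yb, z = t(grid), ylim = rev(range(yb)),
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "x (px)", ylab = "y (px)", main = main, useRaster = TRUE)
}

#' Distance heatmap ordered by an average-linkage dendrogram
#'
#' The standard display of a dissimilarity matrix: rows/columns reordered by
#' average-linkage agglomeration so similar subjects sit together.
#'
#' @param dmat a [DissimilarityMatrix-class].
#' @param main plot title.
#' @return the display ordering of the subjects, invisibly.
#' @export
plotDistanceHeatmap <- function(dmat, main = "DTW dissimilarity") {
  m <- as.matrix(dmat)
  ord <- hierarchicalCluster(dmat, "average")@order
  m <- m[ord, ord]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "", ylab = "", axes = FALSE, main = main)
  graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  invisible(rownames(m))
}

#' Silhouette-versus-k curve
#'
#' @param result a [TrajClusterResult-class].
#' @export
plotSilhouetteByK <- function(result) {
  k <- as.integer(names(result@silhouetteByK))
  graphics::plot(k, result@silhouetteByK, type = "b", pch = 16,
                 xlab = "number of clusters k", ylab = "mean silhouette width",
                 main = "Silhouette analysis")
  graphics::abline(v = result@k, lty = 2, col = "firebrick")
}

#' MDS scatter with k-means clusters and centroids
#'
#' @param result a [TrajClusterResult-class].
#' @export
plotMDSClusters <- function(result) {
  cols <- result@labels + 1L
  graphics::plot(result@coords[, 1L], result@coords[, 2L], col = cols + 1L,
                 pch = 16, xlab = "MDS 1", ylab = "MDS 2",
                 main = sprintf("MDS embedding, k-means k = %d", result@k))
  graphics::points(result@centroids[, 1L], result@centroids[, 2L], pch = 8,
                   cex = 2, lwd = 2)
  graphics::legend("topright", legend = paste("cluster", sort(unique(result@labels))),
                   col = sort(unique(cols)) + 1L, pch = 16, cex = 0.8)
}

#' Dendrogram with the cutoff line
#'
#' @param hier a [HierarchyResult-class].
#' @param main plot title.
#' @export
plotDendrogram <- function(hier, main = NULL) {
  if (is.null(main))
    main <- sprintf("%s linkage (cutoff %.4g)", hier@method, hier@cutoff)
  graphics::plot(asHclust(hier), main = main, xlab = "", sub = "",
                 ylab = "merge height")
  if (is.finite(hier@cutoff))
    graphics::abline(h = hier@cutoff, lty = 2, col = "firebrick")
}

#' Mean angle profiles with SD bands
#'
#' @param profiles list of [ClusterProfile-class] objects (see
#'   [clusterMeanProfile()]).
#' @export
plotClusterProfiles <- function(profiles) {
  rng <- range(unlist(lapply(profiles, function(p) c(p@mean - p@sd, p@mean + p@sd))))
  L <- length(profiles[[1L]]@mean)
  graphics::plot(NULL, xlim = c(1, L), ylim = rng, xlab = "resampled time",
                 ylab = "heading (deg, unwrapped)", main = "Cluster mean angles")
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    graphics::polygon(c(seq_len(L), rev(seq_len(L))),
                      c(p@mean + p@sd, rev(p@mean - p@sd)),
                      col = grDevices::adjustcolor(i + 1L, 0.2), border = NA)
    graphics::lines(seq_len(L), p@mean, col = i + 1L, lwd = 2)
  }
  graphics::legend("topleft", legend = names(profiles), col = seq_along(profiles) + 1L,
                   lwd = 2, cex = 0.8)
}

#' Cumulative DTW cost-matrix heatmap
#'
#' @param costMatrix accumulated-cost matrix (see [clusterCostMatrix()]).
#' @param main plot title.
#' @export
plotCostMatrix <- function(costMatrix, main = "Cumulative cost matrix") {
  graphics::image(seq_len(nrow(costMatrix)), seq_len(ncol(costMatrix)),
                  costMatrix, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "profile A index", ylab = "profile B index",
                  main = main, useRaster = TRUE)
}
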
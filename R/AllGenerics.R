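#' Accessors for arenatrack objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x an arenatrack S4 object.
#' @name accessors
NULL

#' @describeIn accessors subject identifiers of a dissimilarity matrix or
#'   clustering result.
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @describeIn accessors cluster labels of a clustering result (integer,
#'   named by subject; 0-based for k-means results, 1-based for hierarchies).
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @describeIn accessors per-frame sample table of a track.
#' @export
setGeneric("trackSamples", function(x) standardGeneric("trackSamples"))

#' @describeIn accessors frames per second.
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @describeIn accessors arena identifier of a track.
#' @export
setGeneric("arenaId", function(x) standardGeneric("arenaId"))

#' @rdname accessors
#' @export
setMethod("subjects", "DissimilarityMatrix", function(x) x@subjects)

#' @rdname accessors
#' @export
setMethod("subjects", "TrajClusterResult", function(x) names(x@labels))

#' @rdname accessors
#' @export
setMethod("subjects", "HierarchyResult", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "TrajClusterResult", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "HierarchyResult", function(x) x@flatLabels)

#' @rdname accessors
#' @export
setMethod("trackSamples", "Track", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("fps", "Track", function(x) x@fps)

#' @rdname accessors
#' @export
setMethod("arenaId", "Track", function(x) x@arenaId)

#' Coerce a DissimilarityMatrix to a base matrix
#'
#' @param x a [DissimilarityMatrix-class] object.
#' @param ... ignored.
#' @return the numeric distance matrix with subjects as dimnames.
#' @export
setMethod("as.matrix", "DissimilarityMatrix", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@subjects, x@subjects)
  m
})

setMethod("show", "Track", function(object) {
  s <- object@samples
  cat(sprintf("Track for arena '%s': frames %d..%d (%d samples, %.6g fps)\n",
              object@arenaId, object@startFrame, object@endFrame, nrow(s), object@fps))
  cat(sprintf("  detected: %d/%d, interpolated: %d\n",
              sum(s$detected), nrow(s), sum(s$interpolated)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d px, background %g, %d arena(s), blob %gx%g @ %g, noise sd %g, seed %d\n",
              object@frameSize[1], object@frameSize[2], object@backgroundLevel,
              length(object@arenas), object@blobMajor, object@blobMinor,
              object@blobIntensity, object@noiseSigma, object@seed))
})

setMethod("show", "DissimilarityMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf("DissimilarityMatrix: %d subjects", n))
  if (n > 1) {
    off <- object@values[upper.tri(object@values)]
    cat(sprintf(", distances in [%.4g, %.4g]", min(off), max(off)))
  }
  cat("\n")
})

setMethod("show", "TrajClusterResult", function(object) {
  cat(sprintf("TrajClusterResult: k = %d (silhouette %.3f), %d subjects, MDS stress %.4g\n",
              object@k, object@silhouetteByK[[as.character(object@k)]],
              length(object@labels), object@stress))
  print(table(cluster = object@labels))
})

setMethod("show", "HierarchyResult", function(object) {
  cat(sprintf("HierarchyResult (%s linkage): %d subjects, cutoff %.4g -> %d cluster(s)\n",
              object@method, length(object@labels), object@cutoff,
              length(unique(object@flatLabels))))
})

setMethod("show", "BehaviorMetrics", function(object) {
  cat(sprintf("BehaviorMetrics over [%.3g, %.3g] s: total distance %.4g cm, %d transition(s)\n",
              object@window[1], object@window[2], object@totalDistanceCm,
              object@transitions))
  print(object@perRoi, row.names = FALSE)
})
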
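#' @import methods
NULL

#' Scripted polyline path for the synthetic scene renderer
#'
#' A `ScriptedPath` describes where the synthetic animal blob is at every
#' moment of a rendered clip: an ordered polyline of pixel waypoints that is
#' traversed at constant speed over `durationS` seconds and sampled at `fps`
#' frames per second.
#'
#' @slot waypoints numeric matrix with columns `x`, `y` (pixels, origin at
#'   the top-left corner, x rightward, y downward).
#' @slot durationS clip duration in seconds (> 0).
#' @slot fps sampling rate in frames per second (> 0).
#'
#' @seealso [scriptedPath()], [sampleScriptedPath()], [renderVideo()]
#' @export
setClass("ScriptedPath",
  representation(waypoints = "matrix", durationS = "numeric", fps = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@waypoints) < 1L) msg <- c(msg, "need at least one waypoint")
    if (ncol(object@waypoints) != 2L) msg <- c(msg, "waypoints must have two columns (x, y)")
    if (!all(is.finite(object@waypoints))) msg <- c(msg, "waypoints must be finite")
    if (length(object@durationS) != 1L || object@durationS <= 0)
      msg <- c(msg, "durationS must be a single positive number")
    if (length(object@fps) != 1L || object@fps <= 0)
      msg <- c(msg, "fps must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Synthetic scene specification
#'
#' Describes a static arena background with 1--4 pairwise-disjoint
#' axis-aligned rectangular arenas, a dark (or light) elliptical animal blob,
#' and additive per-pixel Gaussian sensor noise.  The rendered clip starts
#' with an animal-free leader so that background estimation from the video
#' itself is testable.
#'
#' @slot frameSize integer vector `c(width, height)` in pixels.
#' @slot backgroundLevel background intensity in 0--255.
#' @slot arenas named list of rectangles, each `c(x0, y0, x1, y1)` in pixels.
#' @slot blobMajor,blobMinor ellipse semi-axes of the blob, pixels.
#' @slot blobIntensity blob fill intensity in 0--255; must differ from the
#'   background level.
#' @slot noiseSigma standard deviation of the additive Gaussian pixel noise
#'   (intensity units; 0 disables noise).
#' @slot seed integer seed controlling the noise stream.
#'
#' @seealso [sceneSpec()], [renderVideo()]
#' @export
setClass("SceneSpec",
  representation(frameSize = "integer", backgroundLevel = "numeric",
                 arenas = "list", blobMajor = "numeric", blobMinor = "numeric",
                 blobIntensity = "numeric", noiseSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@arenas)
    if (n < 1L || n > 4L) msg <- c(msg, "between 1 and 4 arenas are supported")
    if (is.null(names(object@arenas)) || anyDuplicated(names(object@arenas)))
      msg <- c(msg, "arenas must be uniquely named")
    for (a in object@arenas)
      if (length(a) != 4L || a[1] >= a[3] || a[2] >= a[4])
        msg <- c(msg, "each arena must be c(x0, y0, x1, y1) with x0 < x1, y0 < y1")
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        a <- object@arenas[[i]]; b <- object@arenas[[j]]
        if (a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4])
          msg <- c(msg, "arenas must be pairwise disjoint")
      }
    }
    if (object@blobIntensity == object@backgroundLevel)
      msg <- c(msg, "blob intensity must differ from the background level")
    if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
    if (length(msg)) unique(msg) else TRUE
  })

#' Per-arena centroid track
#'
#' The backbone of the pipeline: one time-stamped centroid position per video
#' frame for one arena.  Frames where the detector found no blob carry the
#' last detected position forward and are flagged `detected = FALSE`;
#' [fillGaps()] can replace short runs of such frames by linear
#' interpolation (flagged `interpolated = TRUE`).
#'
#' @slot arenaId arena identifier (matches the layout).
#' @slot fps frames per second of the source video.
#' @slot samples data.frame with columns `frame` (0-based, strictly
#'   increasing), `x`, `y` (pixels), `detected`, `interpolated` (logical).
#' @slot startFrame,endFrame inclusive 0-based frame window of the track.
#'
#' @seealso [trackVideo()], [fillGaps()], [totalDistance()], [roiMetrics()]
#' @export
setClass("Track",
  representation(arenaId = "character", fps = "numeric", samples = "data.frame",
                 startFrame = "integer", endFrame = "integer"),
  validity = function(object) {
    msg <- character()
    need <- c("frame", "x", "y", "detected", "interpolated")
    if (!all(need %in% names(object@samples)))
      msg <- c(msg, paste("samples needs columns:", paste(need, collapse = ", ")))
    else {
      f <- object@samples$frame
      if (length(f) && any(diff(f) <= 0)) msg <- c(msg, "frame indices must be strictly increasing")
      if (length(f) && (min(f) < object@startFrame || max(f) > object@endFrame))
        msg <- c(msg, "frames must lie within [startFrame, endFrame]")
    }
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (length(msg)) msg else TRUE
  })

#' Detector configuration for background-subtraction tracking
#'
#' @slot threshold minimum absolute intensity difference from the background
#'   (0--255, exclusive) for a pixel to be considered foreground.
#' @slot minBlobAreaPx connected components smaller than this many pixels
#'   are discarded (reflections, droppings, specks).
#' @slot polarity `"darker"` keeps pixels darker than the background,
#'   `"lighter"` the opposite, `"either"` uses the absolute difference.
#' @slot morphologyRadiusPx radius of the disc used for a morphological
#'   open/close of the foreground mask; 0 disables morphology.
#' @slot fpsOverride frames per second to use instead of the container
#'   metadata; `NA` defers to the video.
#'
#' @seealso [detectionSettings()], [detectInFrame()], [trackVideo()]
#' @export
setClass("DetectionSettings",
  representation(threshold = "numeric", minBlobAreaPx = "integer",
                 polarity = "character", morphologyRadiusPx = "integer",
                 fpsOverride = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@threshold <= 0 || object@threshold >= 255)
      msg <- c(msg, "threshold must satisfy 0 < threshold < 255")
    if (object@minBlobAreaPx < 1L) msg <- c(msg, "minBlobAreaPx must be >= 1")
    if (!object@polarity %in% c("darker", "lighter", "either"))
      msg <- c(msg, "polarity must be one of darker, lighter, either")
    if (object@morphologyRadiusPx < 0L) msg <- c(msg, "morphologyRadiusPx must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Background reference frame
#'
#' @slot image grayscale matrix (rows = y, columns = x, intensities 0--255).
#' @slot source how the background was obtained: an animal-free leader frame,
#'   an external photo, or a per-pixel median over a frame stack.
#'
#' @seealso [estimateBackground()]
#' @export
setClass("BackgroundModel",
  representation(image = "matrix", source = "character"),
  validity = function(object) {
    if (!object@source %in% c("leader_frame", "external_photo", "median_stack", "none"))
      "source must be one of leader_frame, external_photo, median_stack, none" else TRUE
  })

#' Pixel-to-centimeter calibration
#'
#' Two image points a known real-world distance apart define an isotropic
#' scale in centimeters per pixel.
#'
#' @slot pointA,pointB pixel coordinates of the two reference points.
#' @slot realLengthCm real distance between them in centimeters.
#' @slot scale derived scale, cm per pixel.
#'
#' @seealso [calibrate()]
#' @export
setClass("Calibration",
  representation(pointA = "numeric", pointB = "numeric",
                 realLengthCm = "numeric", scale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (all(object@pointA == object@pointB)) msg <- c(msg, "calibration points must be distinct")
    if (object@realLengthCm <= 0) msg <- c(msg, "realLengthCm must be positive")
    if (length(msg)) msg else TRUE
  })

#' Arena and region-of-interest geometry
#'
#' Arenas are named polygons in pixel coordinates; each arena may carry named
#' ROI polygons (e.g. `center`, `lighted`) plus an optional complement ROI
#' (e.g. `periphery`, `dark`) defined as the arena minus the drawn ROIs.
#' A point on a drawn ROI boundary belongs to that ROI, and among
#' overlapping drawn ROIs the first-declared one wins.
#'
#' @slot arenas named list of polygon matrices (columns x, y, pixels).
#' @slot rois named list (by arena) of named lists of ROI polygon matrices.
#' @slot complementRoi named character: per arena, the label assigned to
#'   points inside the arena but outside all drawn ROIs (`NA` for none).
#'
#' @seealso [arenaLayout()], [roiMembership()], [roiMetrics()]
#' @export
setClass("ArenaLayout",
  representation(arenas = "list", rois = "list", complementRoi = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@arenas) < 1L) msg <- c(msg, "need at least one arena")
    if (is.null(names(object@arenas)) || anyDuplicated(names(object@arenas)))
      msg <- c(msg, "arenas must be uniquely named")
    bad <- setdiff(names(object@rois), names(object@arenas))
    if (length(bad)) msg <- c(msg, paste("rois refer to unknown arenas:", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Behavioral metrics for one track
#'
#' Standard open-field / light--dark-box quantities over an analysis window:
#' total distance, and per ROI the time, distance, and mean speed, plus the
#' number of zone transitions.  Time and distance decompose exactly over
#' ROIs: each frame contributes its frame period to its own ROI, and each
#' step contributes its length to the ROI of the *earlier* frame.
#'
#' @slot totalDistanceCm total path length in centimeters.
#' @slot perRoi data.frame with columns `roi`, `timeS`, `distanceCm`,
#'   `meanSpeedCmS`, `defined` (FALSE when the ROI was never visited and the
#'   reported speed of 0 is a placeholder).
#' @slot transitions number of confirmed zone changes.
#' @slot window analysis window `c(startS, endS)` in seconds.
#'
#' @seealso [roiMetrics()], [countTransitions()]
#' @export
setClass("BehaviorMetrics",
  representation(totalDistanceCm = "numeric", perRoi = "data.frame",
                 transitions = "integer", window = "numeric"))

#' Pairwise DTW dissimilarity matrix
#'
#' Symmetric, zero-diagonal matrix of dynamic-time-warping distances among
#' subjects, the input to both clustering pipelines.
#'
#' @slot values numeric matrix of distances.
#' @slot subjects subject identifiers (row/column order).
#'
#' @seealso [dissimilarityMatrix()], [angleDissimilarityMatrix()],
#'   [hierarchicalCluster()], [mdsEmbed()]
#' @export
setClass("DissimilarityMatrix",
  representation(values = "matrix", subjects = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
    if (length(object@subjects) != nrow(v)) msg <- c(msg, "one subject per row")
    if (nrow(v)) {
      if (any(v < -1e-12)) msg <- c(msg, "distances must be non-negative")
      if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
      if (max(abs(diag(v))) > 1e-8) msg <- c(msg, "diagonal must be zero")
    }
    if (length(msg)) msg else TRUE
  })

#' k-means trajectory clustering result
#'
#' @slot k the selected number of clusters.
#' @slot labels integer cluster labels in `0..k-1`, named by subject.
#' @slot silhouetteByK mean silhouette width for every candidate k scanned.
#' @slot coords 2-D (or higher) MDS coordinates of the subjects.
#' @slot centroids k-means centroids in MDS space.
#' @slot medoids per cluster, the subject minimizing the summed DTW distance
#'   to its co-members.
#' @slot stress normalized residual stress of the MDS embedding.
#'
#' @seealso [selectKAndCluster()], [mdsEmbed()]
#' @export
setClass("TrajClusterResult",
  representation(k = "integer", labels = "integer", silhouetteByK = "numeric",
                 coords = "matrix", centroids = "matrix", medoids = "character",
                 stress = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@labels) && (min(object@labels) < 0L ||
        max(object@labels) > object@k - 1L))
      msg <- c(msg, "labels must lie in 0..k-1")
    if (length(msg)) msg else TRUE
  })

#' Agglomerative hierarchy over a dissimilarity matrix
#'
#' Merge tree produced by Lance--Williams agglomeration, plus the flat
#' clustering obtained by removing all merges above a cutoff height and
#' taking connected components.
#'
#' @slot method linkage: `ward`, `single`, `complete`, `average`, `centroid`.
#' @slot merge (n-1) x 2 merge matrix in [stats::hclust()] convention
#'   (negative = singleton, positive = earlier merge).
#' @slot height merge heights in input-distance units.
#' @slot order leaf order for dendrogram display.
#' @slot labels subject identifiers.
#' @slot cutoff the height above which merges were discarded.
#' @slot flatLabels integer cluster labels (1-based, in order of first
#'   appearance), named by subject.
#'
#' @seealso [hierarchicalCluster()], [cutHierarchy()]
#' @export
setClass("HierarchyResult",
  representation(method = "character", merge = "matrix", height = "numeric",
                 order = "integer", labels = "character", cutoff = "numeric",
                 flatLabels = "integer"))

#' Per-cluster mean angle profile
#'
#' Members of a cluster are linearly resampled to a common length, then the
#' pointwise arithmetic mean and population standard deviation are taken on
#' the unwrapped headings.
#'
#' @slot cluster cluster identifier.
#' @slot mean mean angle curve, degrees.
#' @slot sd pointwise population standard deviation, degrees.
#'
#' @seealso [clusterMeanProfile()], [clusterCostMatrix()]
#' @export
setClass("ClusterProfile",
  representation(cluster = "character", mean = "numeric", sd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mean) != length(object@sd))
      msg <- c(msg, "mean and sd must have equal length")
    if (any(object@sd < 0)) msg <- c(msg, "sd must be non-negative")
    if (length(msg)) msg else TRUE
  })
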
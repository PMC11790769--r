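#' Pixel-to-centimeter calibration from two reference points
#'
#' A known real-world length (a ruler, an arena wall) is marked by two image
#' points; the isotropic scale is centimeters per pixel.
#'
#' @param pointA,pointB pixel coordinates `c(x, y)` of the two marks.
#' @param realLengthCm real distance between the marks, cm.
#' @return a [Calibration-class].
#' @examples
#' calibrate(c(0, 0), c(100, 0), 20)  # 0.2 cm/px
#' @export
calibrate <- function(pointA, pointB, realLengthCm) {
  d <- euclid(pointA, pointB)
  if (d == 0) stop("calibration points must be distinct")
  if (realLengthCm <= 0) stop("realLengthCm must be positive")
  new("Calibration", pointA = as.numeric(pointA), pointB = as.numeric(pointB),
      realLengthCm = as.numeric(realLengthCm), scale = realLengthCm / d)
}

#' Build an arena/ROI layout
#'
#' @param arenas named list of arena polygons (vertex matrices, columns x/y,
#'   pixels) or rectangles `c(x0, y0, x1, y1)`.
#' @param rois named list (by arena) of named lists of ROI polygons or
#'   rectangles. Declaration order matters: among overlapping ROIs the
#'   first-declared wins.
#' @param complementRoi label for arena points outside all drawn ROIs
#'   (e.g. `"periphery"` when only a `center` ROI is drawn); a single string
#'   applied to all arenas, a named character vector per arena, or `NA` for
#'   none.
#' @return an [ArenaLayout-class].
#' @export
arenaLayout <- function(arenas, rois = list(), complementRoi = NA_character_) {
  toPoly <- function(p) {
    if (is.numeric(p) && length(p) == 4L && is.null(dim(p)))
      rectPolygon(p[1L], p[2L], p[3L], p[4L]) else as.matrix(p)
  }
  arenas <- lapply(arenas, toPoly)
  rois <- lapply(rois, function(rr) lapply(rr, toPoly))
  if (length(complementRoi) == 1L && is.null(names(complementRoi)))
    complementRoi <- stats::setNames(rep(complementRoi, length(arenas)), names(arenas))
  new("ArenaLayout", arenas = arenas, rois = rois,
      complementRoi = complementRoi)
}

#' Total distance traveled
#'
#' Sum of Euclidean steps between consecutive samples with defined
#' positions, converted to centimeters.  Steps longer than `maxStepPx` are
#' treated as tracking glitches ("teleports"): they contribute zero distance
#' and their count is attached as attribute `teleports`.
#'
#' @param track a [Track-class].
#' @param cal a [Calibration-class].
#' @param maxStepPx teleport filter threshold, pixels (default `Inf`).
#' @return total distance in cm.
#' @export
totalDistance <- function(track, cal, maxStepPx = Inf) {
  steps <- stepLengthsPx(track, maxStepPx)
  out <- sum(steps$len) * cal@scale
  attr(out, "teleports") <- steps$teleports
  out
}

# Per-step pixel lengths of a track (teleports zeroed), with the index of
# the earlier sample of each step.  Steps touching an undefined (NA)
# position have length 0.
stepLengthsPx <- function(track, maxStepPx = Inf) {
  s <- track@samples
  n <- nrow(s)
  if (n < 2L) return(list(len = numeric(0), from = integer(0), teleports = 0L))
  dx <- diff(s$x); dy <- diff(s$y)
  len <- sqrt(dx^2 + dy^2)
  len[is.na(len)] <- 0
  tele <- len > maxStepPx
  len[tele] <- 0
  list(len = len, from = seq_len(n - 1L), teleports = sum(tele))
}

# Complement ROI label for one arena (NA when none is defined).
complementFor <- function(layout, aid) {
  cr <- layout@complementRoi
  if (!length(cr)) return(NA_character_)
  if (is.null(names(cr))) return(cr[[1L]])
  if (aid %in% names(cr)) cr[[aid]] else NA_character_
}

#' Per-frame ROI membership of a track
#'
#' Each frame is labeled by point-in-polygon membership of its centroid.
#' Boundary points belong to the explicitly drawn ROI (not the complement);
#' among overlapping drawn ROIs the first-declared wins.  Frames inside the
#' arena but outside every drawn ROI get the arena's complement label;
#' frames with no applicable label (or undefined position) are labeled
#' `"none"` with a warning.
#'
#' @param track a [Track-class].
#' @param layout an [ArenaLayout-class] containing the track's arena.
#' @return character vector, one label per frame.
#' @export
roiMembership <- function(track, layout) {
  aid <- track@arenaId
  if (!aid %in% names(layout@arenas)) stop(sprintf("arena '%s' not in layout", aid))
  s <- track@samples
  pts <- cbind(s$x, s$y)
  ok <- !is.na(s$x)
  labels <- rep(NA_character_, nrow(s))
  rois <- layout@rois[[aid]] %||% list()
  for (nm in names(rois)) {
    hit <- ok & is.na(labels)
    if (any(hit))
      labels[hit][pointInPolygon(pts[hit, , drop = FALSE], rois[[nm]])] <- nm
  }
  comp <- complementFor(layout, aid)
  inArena <- ok & is.na(labels) &
    pointInPolygon(pts, layout@arenas[[aid]])
  if (!is.na(comp)) labels[inArena] <- comp
  if (anyNA(labels)) {
    warning(sprintf("%d frame(s) outside all ROIs (labeled 'none')",
                    sum(is.na(labels))))
    labels[is.na(labels)] <- "none"
  }
  labels
}

#' Count confirmed zone transitions
#'
#' A transition is counted when the membership label changes and the new
#' label persists for at least `debounceFrames` consecutive frames;
#' unconfirmed excursions (e.g. a single frame across the light--dark
#' doorway at `debounceFrames = 2`) leave the current zone unchanged.
#'
#' @param membership character label series (see [roiMembership()]).
#' @param debounceFrames confirmation length in frames (default 1: every raw
#'   change counts).
#' @return integer transition count.
#' @export
countTransitions <- function(membership, debounceFrames = 1L) {
  n <- length(membership)
  if (n == 0L) stop("membership must be non-empty")
  cur <- membership[1L]
  count <- 0L
  i <- 2L
  while (i <= n) {
    if (membership[i] != cur) {
      j <- i
      while (j <= n && membership[j] == membership[i]) j <- j + 1L
      if (j - i >= debounceFrames) {
        count <- count + 1L
        cur <- membership[i]
      }
      i <- j
    } else i <- i + 1L
  }
  count
}

#' Behavioral metrics over an analysis window
#'
#' Computes, per ROI, the time (frames in the ROI divided by fps), the
#' distance (each step attributed to the ROI of its *earlier* frame, which
#' makes the decomposition exactly conservative), and the mean speed
#' (distance over time), plus the total distance and the number of
#' confirmed transitions.  ROIs with zero occupancy report speed 0 and
#' `defined = FALSE`.
#'
#' @param track a [Track-class].
#' @param layout an [ArenaLayout-class].
#' @param cal a [Calibration-class].
#' @param maxStepPx teleport filter (see [totalDistance()]).
#' @param debounceFrames transition confirmation length.
#' @return a [BehaviorMetrics-class].
#' @export
roiMetrics <- function(track, layout, cal, maxStepPx = Inf,
                       debounceFrames = 1L) {
  s <- track@samples
  if (nrow(s) == 0L) stop("track has no samples in the window")
  member <- roiMembership(track, layout)
  steps <- stepLengthsPx(track, maxStepPx)
  rois <- names(layout@rois[[track@arenaId]] %||% list())
  comp <- complementFor(layout, track@arenaId)
  allRois <- unique(c(rois, if (!is.na(comp)) comp,
                      intersect("none", member)))
  frameT <- 1 / track@fps
  perRoi <- do.call(rbind, lapply(allRois, function(nm) {
    timeS <- sum(member == nm) * frameT
    distCm <- sum(steps$len[member[steps$from] == nm]) * cal@scale
    data.frame(roi = nm, timeS = timeS, distanceCm = distCm,
               meanSpeedCmS = if (timeS > 0) distCm / timeS else 0,
               defined = timeS > 0)
  }))
  new("BehaviorMetrics",
      totalDistanceCm = sum(steps$len) * cal@scale,
      perRoi = perRoi,
      transitions = countTransitions(member, debounceFrames),
      window = c(s$frame[1L], s$frame[nrow(s)] + 1L) / track@fps)
}

#' Occupancy heatmap of a track
#'
#' 2-D histogram of centroid positions over the arena bounding box.  The
#' grid sums to the number of frames with a defined position.
#'
#' @param track a [Track-class].
#' @param layout an [ArenaLayout-class].
#' @param bins number of bins per axis (scalar or `c(nx, ny)`).
#' @return `ny` x `nx` count matrix (rows = y bins, top row = smallest y)
#'   with attributes `xBreaks` and `yBreaks`.
#' @export
occupancyHeatmap <- function(track, layout, bins = 20L) {
  if (length(bins) == 1L) bins <- c(bins, bins)
  stopifnot(all(bins >= 1L))
  poly <- layout@arenas[[track@arenaId]]
  xb <- seq(min(poly[, 1]), max(poly[, 1]), length.out = bins[1L] + 1L)
  yb <- seq(min(poly[, 2]), max(poly[, 2]), length.out = bins[2L] + 1L)
  s <- track@samples
  ok <- !is.na(s$x)
  ix <- pmin(pmax(findInterval(s$x[ok], xb, rightmost.closed = TRUE), 1L), bins[1L])
  iy <- pmin(pmax(findInterval(s$y[ok], yb, rightmost.closed = TRUE), 1L), bins[2L])
  grid <- matrix(0L, nrow = bins[2L], ncol = bins[1L])
  for (k in seq_along(ix)) grid[iy[k], ix[k]] <- grid[iy[k], ix[k]] + 1L
  attr(grid, "xBreaks") <- xb
  attr(grid, "yBreaks") <- yb
  grid
}
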
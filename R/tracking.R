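#' Create detection settings
#'
#' @param threshold minimum background difference, 0--255 exclusive.
#' @param minBlobAreaPx minimum connected-component area in pixels.
#' @param polarity `"darker"`, `"lighter"` or `"either"` relative to the
#'   background (a dark mouse on a light floor is `"darker"`).
#' @param morphologyRadiusPx disc radius for the morphological open/close of
#'   the foreground mask; 0 disables.
#' @param fpsOverride frames per second overriding the container metadata;
#'   `NA` defers to the video.
#' @return a [DetectionSettings-class] object.
#' @export
detectionSettings <- function(threshold = 50, minBlobAreaPx = 5L,
                              polarity = c("darker", "lighter", "either"),
                              morphologyRadiusPx = 0L, fpsOverride = NA_real_) {
  polarity <- match.arg(polarity)
  new("DetectionSettings", threshold = as.numeric(threshold),
      minBlobAreaPx = as.integer(minBlobAreaPx), polarity = polarity,
      morphologyRadiusPx = as.integer(morphologyRadiusPx),
      fpsOverride = as.numeric(fpsOverride))
}

#' Estimate the background reference frame
#'
#' Either picks one animal-free frame (`leader_frame`) — the recommended
#' practice of recording a few empty seconds before placing the animals —
#' or takes the per-pixel median over a frame range (`median_stack`), which
#' recovers the empty scene as long as the animal occupies each pixel less
#' than half the time.
#'
#' @param video h x w x n frame array (see [readVideoFrames()]) or a TIFF
#'   path.
#' @param frameRange 0-based frame indices; `leader_frame` uses the first
#'   index, `median_stack` the whole range.
#' @param method `"leader_frame"` or `"median_stack"`.
#' @return a [BackgroundModel-class].
#' @export
estimateBackground <- function(video, frameRange,
                               method = c("leader_frame", "median_stack")) {
  method <- match.arg(method)
  if (is.character(video)) video <- readVideoFrames(video)
  n <- dim(video)[3L]
  if (length(frameRange) < 1L) stop("frameRange must be non-empty")
  if (min(frameRange) < 0L || max(frameRange) > n - 1L)
    stop("frameRange out of bounds")
  img <- if (method == "leader_frame" || length(frameRange) == 1L) {
    video[, , frameRange[1L] + 1L]
  } else {
    apply(video[, , frameRange + 1L, drop = FALSE], c(1L, 2L), stats::median)
  }
  new("BackgroundModel", image = img, source = method)
}

#' Background model from an external photo
#'
#' @param image grayscale matrix (0--255 or 0--1) or RGB array, e.g. from
#'   [tiff::readTIFF()].
#' @return a [BackgroundModel-class] with source `"external_photo"`.
#' @export
backgroundFromPhoto <- function(image) {
  new("BackgroundModel", image = toGray255(image), source = "external_photo")
}

# Core detector on a pre-cropped difference image.  maskInfo is the cached
# polygonPixelMask() of the arena.  Returns c(x, y) or NULL.
detectInMask <- function(frame, bgImage, settings, maskInfo) {
  rows <- maskInfo$y0 + seq_len(nrow(maskInfo$mask)) - 1L + 1L
  cols <- maskInfo$x0 + seq_len(ncol(maskInfo$mask)) - 1L + 1L
  d <- switch(settings@polarity,
    darker = bgImage[rows, cols, drop = FALSE] - frame[rows, cols, drop = FALSE],
    lighter = frame[rows, cols, drop = FALSE] - bgImage[rows, cols, drop = FALSE],
    either = abs(frame[rows, cols, drop = FALSE] - bgImage[rows, cols, drop = FALSE]))
  fg <- (d >= settings@threshold) & maskInfo$mask
  if (!any(fg)) return(NULL)
  mode(fg) <- "numeric"
  r <- settings@morphologyRadiusPx
  if (r > 0L) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    fg <- EBImage::imageData(EBImage::closing(EBImage::opening(fg, brush), brush))
    if (!any(fg > 0)) return(NULL)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= settings@minBlobAreaPx)
  if (!length(keep)) return(NULL)
  best <- keep[which.max(sizes[keep])]
  px <- which(lab == best, arr.ind = TRUE)
  c(x = maskInfo$x0 + mean(px[, 2L]) - 1,
    y = maskInfo$y0 + mean(px[, 1L]) - 1)
}

#' Detect the animal in one frame
#'
#' Within the arena, the signed (per polarity) difference from the
#' background is thresholded, optionally cleaned by a morphological
#' open/close, and connected components at least `minBlobAreaPx` pixels
#' large are kept; the centroid of the largest surviving component is
#' returned.  The largest-component rule resolves multi-blob frames caused
#' by reflections or droppings.
#'
#' @param frame grayscale matrix, 0--255.
#' @param bg a [BackgroundModel-class]; must match the frame dimensions.
#' @param settings a [DetectionSettings-class].
#' @param arena arena polygon matrix or rectangle `c(x0, y0, x1, y1)`,
#'   pixels.
#' @return named vector `c(x, y)` (0-based pixel coordinates) or `NULL` if
#'   nothing is detected.
#' @export
detectInFrame <- function(frame, bg, settings, arena) {
  stopifnot(is(bg, "BackgroundModel"), is(settings, "DetectionSettings"))
  if (!all(dim(bg@image) == dim(frame)))
    stop("background and frame dimensions differ")
  if (is.numeric(arena) && length(arena) == 4L)
    arena <- rectPolygon(arena[1L], arena[2L], arena[3L], arena[4L])
  maskInfo <- polygonPixelMask(arena, ncol(frame), nrow(frame))
  detectInMask(frame, bg@image, settings, maskInfo)
}

#' Track all arenas over a frame window
#'
#' Runs [detectInFrame()] on every frame in `[startFrame, endFrame]`
#' (0-based, inclusive) for each arena of the layout and assembles one
#' [Track-class] per arena.  Frames without a detection carry the last
#' detected position forward (`detected = FALSE`); positions are `NA` until
#' the first detection.  Arenas are disjoint, so animal identity follows
#' from containment — there are no identity swaps.
#'
#' @param video frame array or TIFF path.
#' @param layout an [ArenaLayout-class].
#' @param settings a [DetectionSettings-class]; its `fpsOverride` takes
#'   precedence over the `fps` argument.
#' @param startFrame,endFrame analysis window, 0-based inclusive.
#' @param bg a [BackgroundModel-class]; if missing, estimated from
#'   `bgFrames` by per-pixel median.
#' @param fps frames per second of the recording (the TIFF container carries
#'   no rate metadata, so either this or `fpsOverride` must be given).
#' @param bgFrames 0-based frames used when `bg` is missing (default: the
#'   frames before `startFrame`, i.e. the animal-free leader).
#' @return named list of [Track-class] objects, one per arena.
#' @export
trackVideo <- function(video, layout, settings, startFrame, endFrame,
                       bg = NULL, fps = NA_real_, bgFrames = NULL) {
  stopifnot(is(layout, "ArenaLayout"), is(settings, "DetectionSettings"))
  if (is.character(video)) video <- readVideoFrames(video)
  n <- dim(video)[3L]
  startFrame <- as.integer(startFrame); endFrame <- as.integer(endFrame)
  if (startFrame > endFrame) stop("startFrame must be <= endFrame")
  if (startFrame < 0L || endFrame > n - 1L) stop("frame window out of bounds")
  theFps <- if (!is.na(settings@fpsOverride)) settings@fpsOverride else fps
  if (is.na(theFps))
    stop("frame rate unknown: supply fps or settings fpsOverride")
  if (is.null(bg)) {
    if (is.null(bgFrames)) {
      if (startFrame < 1L)
        stop("no leader frames before startFrame; supply bg or bgFrames")
      bgFrames <- 0:(startFrame - 1L)
    }
    bg <- estimateBackground(video, bgFrames, "median_stack")
  }
  h <- nrow(bg@image); w <- ncol(bg@image)
  masks <- lapply(layout@arenas, function(p) {
    if (is.numeric(p) && length(p) == 4L) p <- rectPolygon(p[1], p[2], p[3], p[4])
    polygonPixelMask(p, w, h)
  })
  framesIdx <- startFrame:endFrame
  out <- list()
  for (nm in names(layout@arenas)) {
    xs <- rep(NA_real_, length(framesIdx)); ys <- xs
    det <- logical(length(framesIdx))
    last <- c(NA_real_, NA_real_)
    for (k in seq_along(framesIdx)) {
      cen <- detectInMask(video[, , framesIdx[k] + 1L], bg@image, settings,
                          masks[[nm]])
      if (!is.null(cen)) {
        last <- cen; det[k] <- TRUE
      }
      xs[k] <- last[1L]; ys[k] <- last[2L]
    }
    if (!any(det))
      warning(sprintf("no detections in arena '%s' over the whole window", nm))
    out[[nm]] <- new("Track", arenaId = nm, fps = theFps,
                     samples = data.frame(frame = framesIdx, x = xs, y = ys,
                                          detected = det,
                                          interpolated = FALSE),
                     startFrame = startFrame, endFrame = endFrame)
  }
  out
}

#' Interpolate short detection gaps in a track
#'
#' Runs of at most `maxGapFrames` undetected frames flanked by detections on
#' both sides are replaced by linear interpolation between the flanking
#' positions and flagged `interpolated`; longer runs (and leading/trailing
#' gaps) keep the carry-forward positions.
#'
#' @param track a [Track-class].
#' @param maxGapFrames longest gap to interpolate.
#' @return the track with gaps filled.
#' @export
fillGaps <- function(track, maxGapFrames) {
  s <- track@samples
  det <- which(s$detected)
  if (length(det) < 2L) return(track)
  for (i in seq_len(length(det) - 1L)) {
    a <- det[i]; b <- det[i + 1L]
    gap <- b - a - 1L
    if (gap >= 1L && gap <= maxGapFrames) {
      frac <- seq_len(gap) / (gap + 1L)
      idx <- (a + 1L):(b - 1L)
      s$x[idx] <- s$x[a] + frac * (s$x[b] - s$x[a])
      s$y[idx] <- s$y[a] + frac * (s$y[b] - s$y[a])
      s$interpolated[idx] <- TRUE
    }
  }
  initialize(track, samples = s)
}
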
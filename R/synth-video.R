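#' Create a synthetic scene specification
#'
#' @param frameSize `c(width, height)` of the rendered frames, pixels.
#' @param backgroundLevel background intensity, 0--255 (default 255: the
#'   white/opaque box floor typical of open-field apparatus).
#' @param arenas named list of axis-aligned rectangles `c(x0, y0, x1, y1)`
#'   in pixels; 1 to 4 arenas, pairwise disjoint.
#' @param blobMajor,blobMinor semi-axes of the elliptical animal blob,
#'   pixels.
#' @param blobIntensity fill intensity of the blob (default 0: a dark mouse
#'   on a light floor).
#' @param noiseSigma standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed for the noise stream.
#' @return a [SceneSpec-class] object.
#' @export
sceneSpec <- function(frameSize = c(320L, 240L), backgroundLevel = 255,
                      arenas = list(A = c(10, 10, 150, 150)),
                      blobMajor = 6, blobMinor = 4, blobIntensity = 0,
                      noiseSigma = 0, seed = 1L) {
  new("SceneSpec", frameSize = as.integer(frameSize),
      backgroundLevel = as.numeric(backgroundLevel), arenas = arenas,
      blobMajor = as.numeric(blobMajor), blobMinor = as.numeric(blobMinor),
      blobIntensity = as.numeric(blobIntensity),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

# Paint a filled ellipse onto a frame matrix (rows = y, cols = x, 0-based
# pixel-center coordinates).
paintEllipse <- function(frame, cx, cy, a, b, intensity) {
  h <- nrow(frame); w <- ncol(frame)
  r0 <- max(1L, floor(cy - b) + 1L); r1 <- min(h, ceiling(cy + b) + 1L)
  c0 <- max(1L, floor(cx - a) + 1L); c1 <- min(w, ceiling(cx + a) + 1L)
  if (r0 > r1 || c0 > c1) return(frame)
  ys <- (r0:r1) - 1L; xs <- (c0:c1) - 1L
  inside <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, "+") <= 1
  sub <- frame[r0:r1, c0:c1, drop = FALSE]
  sub[inside] <- intensity
  frame[r0:r1, c0:c1] <- sub
  frame
}

#' Render a synthetic behavior video with ground truth
#'
#' Renders a static background with 1--4 arenas, then one dark (or light)
#' elliptical blob per occupied arena following its scripted path.  The clip
#' opens with an animal-free leader of `leaderS` seconds so background
#' estimation from the video itself can be exercised, mirroring the
#' recommended recording practice of leaving the apparatus empty for a few
#' seconds.  Rendering is deterministic under the scene seed (byte-identical
#' frames and files).
#'
#' @param scene a [SceneSpec-class].
#' @param paths named list of [ScriptedPath-class] objects, one per occupied
#'   arena (names must match arena names).  All paths must share one fps and
#'   duration, and the blob footprint must stay inside its arena.
#' @param file optional path of a multi-page grayscale TIFF to write.
#' @param leaderS animal-free leader duration in seconds (default 2).
#' @return list with `frames` (h x w x nFrames integer array, 0--255),
#'   `groundTruth` (data.frame frame, arena, x, y for every non-leader
#'   frame; frame is 0-based over the whole clip), `nLeaderFrames`, `fps`,
#'   and per-arena analytic `pathLength` (pixels).
#' @export
renderVideo <- function(scene, paths, file = NULL, leaderS = 2) {
  stopifnot(is(scene, "SceneSpec"), length(paths) >= 1L)
  if (is.null(names(paths)) || !all(names(paths) %in% names(scene@arenas)))
    stop("paths must be named after arenas of the scene")
  fpsAll <- vapply(paths, function(p) p@fps, numeric(1))
  durAll <- vapply(paths, function(p) p@durationS, numeric(1))
  if (length(unique(fpsAll)) != 1L || length(unique(durAll)) != 1L)
    stop("all paths must share one fps and duration")
  theFps <- fpsAll[[1L]]
  w <- scene@frameSize[1L]; h <- scene@frameSize[2L]
  a <- scene@blobMajor; b <- scene@blobMinor

  sampled <- lapply(paths, sampleScriptedPath)
  for (nm in names(sampled)) {
    ar <- scene@arenas[[nm]]
    s <- sampled[[nm]]
    if (any(s[, 1] - a < ar[1] | s[, 1] + a > ar[3] |
            s[, 2] - b < ar[2] | s[, 2] + b > ar[4]))
      stop(sprintf("path for arena '%s' leaves its arena", nm))
  }

  nAnim <- nrow(sampled[[1L]])
  nLeader <- round(leaderS * theFps)
  nTotal <- nLeader + nAnim
  bg <- matrix(scene@backgroundLevel, nrow = h, ncol = w)
  frames <- array(0L, dim = c(h, w, nTotal))

  renderOne <- function(i) {
    f <- bg
    if (i > nLeader) {
      for (nm in names(sampled)) {
        p <- sampled[[nm]][i - nLeader, ]
        f <- paintEllipse(f, p[1L], p[2L], a, b, scene@blobIntensity)
      }
    }
    f
  }
  if (scene@noiseSigma > 0) {
    withr::with_seed(scene@seed, {
      for (i in seq_len(nTotal)) {
        f <- renderOne(i) + matrix(stats::rnorm(h * w, 0, scene@noiseSigma), h, w)
        frames[, , i] <- pmin(pmax(round(f), 0), 255)
      }
    })
  } else {
    for (i in seq_len(nTotal)) frames[, , i] <- round(renderOne(i))
  }

  gt <- do.call(rbind, lapply(names(sampled), function(nm) {
    data.frame(frame = nLeader + seq_len(nAnim) - 1L, arena = nm,
               x = sampled[[nm]][, 1L], y = sampled[[nm]][, 2L])
  }))
  gt <- gt[order(gt$frame, gt$arena), ]
  rownames(gt) <- NULL

  if (!is.null(file)) writeVideoFrames(frames, file)
  list(frames = frames, groundTruth = gt, nLeaderFrames = nLeader,
       fps = theFps,
       pathLength = vapply(sampled, attr, numeric(1), "pathLength"),
       file = file)
}

#' Write frames as a multi-page grayscale TIFF
#'
#' The package's native lossless video container: one 8-bit grayscale page
#' per frame, uncompressed, so seeded renders are byte-identical on disk.
#'
#' @param frames h x w x n array of intensities in 0--255.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeVideoFrames <- function(frames, file) {
  pages <- lapply(seq_len(dim(frames)[3L]),
                  function(i) frames[, , i] / 255)
  tiff::writeTIFF(pages, file, bits.per.sample = 8L, compression = "none")
  invisible(file)
}

#' Read a multi-page TIFF video into a frame array
#'
#' RGB pages are converted to grayscale with the standard luma weights
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param file path to a (multi-page) TIFF.
#' @return h x w x n array of intensities in 0--255.
#' @export
readVideoFrames <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(pages, toGray255)
  array(unlist(mats), dim = c(nrow(mats[[1L]]), ncol(mats[[1L]]), length(mats)))
}

# Any single frame (matrix in [0,1] or [0,255], or RGB array) -> grayscale
# matrix in 0--255.
toGray255 <- function(img) {
  if (length(dim(img)) == 3L) {
    img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  }
  if (max(img) <= 1) img <- img * 255
  round(img)
}
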
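# Shared synthetic fixtures, all generated in code at test time.

FIX_FPS <- 5

fixtureArenas4 <- list(A = c(10, 10, 150, 110), B = c(170, 10, 310, 110),
                       C = c(10, 130, 150, 230), D = c(170, 130, 310, 230))

fixtureScene <- function(nArenas = 1L, noiseSigma = 0, seed = 1L) {
  arenas <- fixtureArenas4[seq_len(nArenas)]
  sceneSpec(frameSize = if (nArenas > 1L) c(320L, 240L) else c(160L, 120L),
            backgroundLevel = 255, arenas = arenas,
            blobMajor = 6, blobMinor = 4, blobIntensity = 0,
            noiseSigma = noiseSigma, seed = seed)
}

# One polyline per arena, comfortably inside it (blob margin respected).
fixturePaths <- function(nArenas = 1L, durationS = 10, fps = FIX_FPS) {
  mk <- function(rect, flip = FALSE) {
    x0 <- rect[1] + 15; x1 <- rect[3] - 15
    y0 <- rect[2] + 12; y1 <- rect[4] - 12
    wp <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
    if (flip) wp <- wp[4:1, ]
    scriptedPath(wp, durationS, fps)
  }
  arenas <- fixtureArenas4[seq_len(nArenas)]
  out <- lapply(seq_along(arenas), function(i) mk(arenas[[i]], flip = i %% 2 == 0))
  names(out) <- names(arenas)
  out
}

fixtureLayout <- function(nArenas = 1L, withCenter = FALSE) {
  arenas <- fixtureArenas4[seq_len(nArenas)]
  rois <- list()
  comp <- NA_character_
  if (withCenter) {
    rois <- lapply(arenas, function(r) {
      w <- (r[3] - r[1]) / 4; h <- (r[4] - r[2]) / 4
      list(center = c(r[1] + w, r[2] + h, r[3] - w, r[4] - h))
    })
    comp <- "periphery"
  }
  arenaLayout(arenas, rois = rois, complementRoi = comp)
}

# Two-compartment light--dark layout over one arena: lighted left half
# (drawn ROI), dark right half (complement).
fixtureLdbLayout <- function(rect = c(0, 0, 100, 50)) {
  midX <- (rect[1] + rect[3]) / 2
  arenaLayout(list(A = rect),
              rois = list(A = list(lighted = c(rect[1], rect[2], midX, rect[4]))),
              complementRoi = "dark")
}

readCsv <- function(f) utils::read.csv(f, comment.char = "#")

# Build a Track directly from a position matrix (all frames detected).
makeTrack <- function(xy, fps = FIX_FPS, arenaId = "A", startFrame = 0L) {
  n <- nrow(xy)
  new("Track", arenaId = arenaId, fps = fps,
      samples = data.frame(frame = startFrame + seq_len(n) - 1L,
                           x = xy[, 1], y = xy[, 2],
                           detected = TRUE, interpolated = FALSE),
      startFrame = startFrame, endFrame = startFrame + n - 1L)
}
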
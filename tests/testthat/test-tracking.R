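test_that("background estimation recovers the empty scene", {
  sc <- fixtureScene(1L)
  rv <- renderVideo(sc, fixturePaths(1L), leaderS = 2)
  bgL <- estimateBackground(rv$frames, 0L, "leader_frame")
  expect_true(all(bgL@image == 255))

  # median over frames where the blob occupies each pixel < 50% of the time
  bgM <- estimateBackground(rv$frames, 8:30, "median_stack")
  expect_true(all(bgM@image == 255))
  # oracle on a handful of pixels: the middle order statistic
  stack <- rv$frames[, , 9:31]
  for (rc in list(c(40, 40), c(31, 31), c(60, 100))) {
    v <- sort(stack[rc[1], rc[2], ])
    expect_equal(bgM@image[rc[1], rc[2]], v[(length(v) + 1) / 2])
  }

  # length-1 median range is the leader frame itself
  bg1 <- estimateBackground(rv$frames, 3L, "median_stack")
  expect_equal(bg1@image, estimateBackground(rv$frames, 3L, "leader_frame")@image)
  expect_error(estimateBackground(rv$frames, 10000L), "out of bounds")
})

test_that("single-frame detection hits the scripted position and ignores small blobs", {
  sc <- fixtureScene(1L)
  rv <- renderVideo(sc, fixturePaths(1L), leaderS = 2)
  bg <- estimateBackground(rv$frames, 0L, "leader_frame")
  st <- detectionSettings(threshold = 50)
  gt <- rv$groundTruth
  cen <- detectInFrame(rv$frames[, , gt$frame[1] + 1L], bg, st,
                       fixtureArenas4$A)
  expect_lt(euclidDist(cen, c(gt$x[1], gt$y[1])), 0.5)

  # a blob-free leader frame yields nothing
  expect_null(detectInFrame(rv$frames[, , 1], bg, st, fixtureArenas4$A))

  # two blobs: a 3x3 speck below minBlobAreaPx vs the real blob
  fr <- rv$frames[, , gt$frame[1] + 1L]
  fr[80:82, 60:62] <- 0   # 9-px speck at (x=59..61, y=79..81)
  st2 <- detectionSettings(threshold = 50, minBlobAreaPx = 20L)
  cen2 <- detectInFrame(fr, bg, st2, fixtureArenas4$A)
  expect_lt(euclidDist(cen2, c(gt$x[1], gt$y[1])), 0.5)
  # with a permissive area both blobs survive; the larger wins (same answer)
  st3 <- detectionSettings(threshold = 50, minBlobAreaPx = 1L)
  expect_lt(euclidDist(detectInFrame(fr, bg, st3, fixtureArenas4$A),
                       c(gt$x[1], gt$y[1])), 0.5)
  # hand-computed centroid of a lone rectangle blob
  fr2 <- matrix(255, 120, 160)
  fr2[21:24, 31:36] <- 0   # rows y=20..23, cols x=30..35
  cen3 <- detectInFrame(fr2, bg, st3, fixtureArenas4$A)
  expect_equal(unname(cen3), c(mean(30:35), mean(20:23)))
})

test_that("full tracking matches ground truth within 0.5 px, no identity swaps", {
  for (nA in c(1L, 4L)) {
    sc <- fixtureScene(nA)
    rv <- renderVideo(sc, fixturePaths(nA), leaderS = 2)
    lay <- fixtureLayout(nA)
    st <- detectionSettings(threshold = 50)
    trs <- trackVideo(rv$frames, lay, st, rv$nLeaderFrames,
                      dim(rv$frames)[3] - 1L, fps = FIX_FPS)
    expect_length(trs, nA)
    for (nm in names(trs)) {
      s <- trackSamples(trs[[nm]])
      expect_true(all(s$detected))
      gt <- rv$groundTruth[rv$groundTruth$arena == nm, ]
      err <- sqrt((s$x - gt$x)^2 + (s$y - gt$y)^2)
      expect_lt(max(err), 0.5)
    }
  }
})

test_that("tracking is deterministic and robust to noise below threshold/3", {
  sc <- fixtureScene(1L, noiseSigma = 50 / 3, seed = 21L)
  rv <- renderVideo(sc, fixturePaths(1L), leaderS = 2)
  lay <- fixtureLayout(1L)
  st <- detectionSettings(threshold = 50, minBlobAreaPx = 5L)
  run <- function() trackVideo(rv$frames, lay, st, rv$nLeaderFrames,
                               dim(rv$frames)[3] - 1L, fps = FIX_FPS)
  t1 <- run(); t2 <- run()
  expect_identical(trackSamples(t1$A), trackSamples(t2$A))
  expect_gte(mean(trackSamples(t1$A)$detected), 0.99)
  # detections stay inside the arena
  s <- trackSamples(t1$A)[trackSamples(t1$A)$detected, ]
  expect_true(all(pointInPolygon(cbind(s$x, s$y),
                                 rectPolygon(10, 10, 150, 110))))
})

test_that("boundary window and empty-arena cases behave", {
  sc <- fixtureScene(1L)
  rv <- renderVideo(sc, fixturePaths(1L), leaderS = 2)
  lay <- fixtureLayout(1L)
  st <- detectionSettings(threshold = 50)
  # start = end: a single-frame track
  tr1 <- trackVideo(rv$frames, lay, st, rv$nLeaderFrames, rv$nLeaderFrames,
                    bg = estimateBackground(rv$frames, 0L, "leader_frame"),
                    fps = FIX_FPS)
  expect_equal(nrow(trackSamples(tr1$A)), 1L)
  # a window with no animal anywhere: warning + empty track, not a crash
  expect_warning(
    tr0 <- trackVideo(rv$frames, lay, st, 0L, rv$nLeaderFrames - 1L,
                      bg = estimateBackground(rv$frames, 0L, "leader_frame"),
                      fps = FIX_FPS),
    "no detections")
  expect_false(any(trackSamples(tr0$A)$detected))
  # fps must come from somewhere
  expect_error(trackVideo(rv$frames, lay, st, 10L, 12L,
                          bg = estimateBackground(rv$frames, 0L, "leader_frame")),
               "frame rate")
})

test_that("gap filling interpolates short gaps only", {
  xy <- cbind(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9), 0)
  tr <- makeTrack(xy)
  s <- tr@samples
  s$detected[c(2, 5, 6, 7, 8)] <- FALSE
  s$x[2] <- s$x[1]; s$x[5:8] <- s$x[4]      # carry-forward as trackVideo emits
  tr <- new("Track", arenaId = "A", fps = FIX_FPS, samples = s,
            startFrame = 0L, endFrame = 9L)

  filled <- fillGaps(tr, maxGapFrames = 1L)
  fs <- trackSamples(filled)
  expect_equal(fs$x[2], 1)                   # midpoint of frames 0 and 2
  expect_true(fs$interpolated[2])
  expect_equal(fs$x[5:8], rep(3, 4))         # 4-frame gap > maxGap: untouched
  expect_false(any(fs$interpolated[5:8]))

  filled2 <- fillGaps(tr, maxGapFrames = 4L)
  expect_equal(trackSamples(filled2)$x[5:8], c(4, 5, 6, 7))

  # a gap-free track is returned unchanged
  clean <- makeTrack(xy)
  expect_identical(trackSamples(fillGaps(clean, 3L)), trackSamples(clean))
})
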
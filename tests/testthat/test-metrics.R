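test_that("calibration gives an isotropic cm/px scale", {
  expect_equal(calibrate(c(0, 0), c(100, 0), 20)@scale, 0.2)
  expect_equal(calibrate(c(0, 0), c(3, 4), 10)@scale, 2.0)
  expect_error(calibrate(c(5, 5), c(5, 5), 10), "distinct")
  expect_error(calibrate(c(0, 0), c(1, 0), -1), "positive")
})

test_that("total distance sums Euclidean steps and filters teleports", {
  cal <- calibrate(c(0, 0), c(1, 0), 1)          # scale 1 cm/px
  expect_equal(as.numeric(totalDistance(makeTrack(rbind(c(2, 2))), cal)), 0)
  expect_equal(as.numeric(totalDistance(
    makeTrack(rbind(c(0, 0), c(3, 4), c(3, 4))), cal)), 5)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  calHalf <- calibrate(c(0, 0), c(2, 0), 1)      # 0.5 cm/px
  expect_equal(as.numeric(totalDistance(makeTrack(sq), calHalf)), 20)
  # teleport filter
  tp <- totalDistance(makeTrack(rbind(c(0, 0), c(1, 0), c(500, 0))), cal,
                      maxStepPx = 50)
  expect_equal(as.numeric(tp), 1)
  expect_equal(attr(tp, "teleports"), 1L)
})

test_that("ROI membership follows the boundary and overlap tie rules", {
  lay <- arenaLayout(list(A = c(0, 0, 100, 100)),
                     rois = list(A = list(center = c(25, 25, 75, 75))),
                     complementRoi = "periphery")
  tr <- makeTrack(rbind(c(50, 50),    # strictly inside center
                        c(25, 50),    # exactly on the center boundary
                        c(10, 10)))   # outside center, inside arena
  expect_equal(roiMembership(tr, lay), c("center", "center", "periphery"))

  # first-declared ROI wins where drawn ROIs overlap
  lay2 <- arenaLayout(list(A = c(0, 0, 100, 100)),
                      rois = list(A = list(left = c(0, 0, 60, 100),
                                           right = c(40, 0, 100, 100))))
  expect_equal(roiMembership(makeTrack(rbind(c(50, 50))), lay2), "left")

  # no complement and outside all ROIs -> "none" with a warning
  lay3 <- arenaLayout(list(A = c(0, 0, 100, 100)),
                      rois = list(A = list(center = c(25, 25, 75, 75))))
  expect_warning(m3 <- roiMembership(makeTrack(rbind(c(1, 1))), lay3),
                 "outside all ROIs")
  expect_equal(m3, "none")
})

test_that("transition counting honors the debounce automaton", {
  expect_equal(countTransitions(c("L", "L", "D", "D", "L")), 2L)
  expect_equal(countTransitions(rep("L", 10)), 0L)
  expect_equal(countTransitions(c("L", "D", "L", "L"), debounceFrames = 2L), 0L)
  expect_equal(countTransitions(c("L", "D", "D", "L", "L"), debounceFrames = 2L), 2L)
  expect_error(countTransitions(character(0)), "non-empty")
})

test_that("per-ROI metrics decompose time and distance exactly", {
  lay <- arenaLayout(list(A = c(0, 0, 100, 100)),
                     rois = list(A = list(center = c(25, 25, 75, 75))),
                     complementRoi = "periphery")
  cal <- calibrate(c(0, 0), c(1, 0), 1)
  # 5 frames at 5 fps, 3 labeled center
  tr <- makeTrack(rbind(c(50, 50), c(60, 50), c(70, 50), c(80, 50), c(90, 50)))
  m <- roiMetrics(tr, lay, cal)
  expect_equal(m@perRoi$timeS[m@perRoi$roi == "center"], 0.6)
  expect_equal(sum(m@perRoi$timeS), 1)                     # 5 frames / 5 fps
  expect_equal(sum(m@perRoi$distanceCm), m@totalDistanceCm)
  # the step 70 -> 80 leaves center: attributed to center (earlier frame)
  expect_equal(m@perRoi$distanceCm[m@perRoi$roi == "center"], 30)

  # mean speed = distance / time within one ROI
  tr2 <- makeTrack(rbind(c(40, 50), c(41, 50), c(42, 50)), fps = 1)
  m2 <- roiMetrics(tr2, lay, cal)
  expect_equal(m2@perRoi$meanSpeedCmS[m2@perRoi$roi == "center"], 2 / 3)
  # unvisited ROI: zero time, speed reported 0 and flagged undefined
  perip <- m2@perRoi[m2@perRoi$roi == "periphery", ]
  expect_equal(perip$timeS, 0)
  expect_equal(perip$meanSpeedCmS, 0)
  expect_false(perip$defined)
})

test_that("conservation, scale equivariance and rotation invariance hold", {
  lay <- arenaLayout(list(A = c(0, 0, 100, 100)),
                     rois = list(A = list(center = c(25, 25, 75, 75))),
                     complementRoi = "periphery")
  withr::with_seed(5, {
    for (rep in 1:5) {
      xy <- cbind(runif(40, 1, 99), runif(40, 1, 99))
      tr <- makeTrack(xy)
      cal <- calibrate(c(0, 0), c(1, 0), 1)
      m <- roiMetrics(tr, lay, cal)
      expect_equal(sum(m@perRoi$timeS), nrow(xy) / FIX_FPS, tolerance = 1e-12)
      expect_equal(sum(m@perRoi$distanceCm), m@totalDistanceCm, tolerance = 1e-12)

      cal2 <- calibrate(c(0, 0), c(1, 0), 2)   # doubled scale
      m2 <- roiMetrics(tr, lay, cal2)
      expect_equal(m2@totalDistanceCm, 2 * m@totalDistanceCm)
      expect_equal(m2@perRoi$distanceCm, 2 * m@perRoi$distanceCm)
      expect_equal(m2@perRoi$meanSpeedCmS, 2 * m@perRoi$meanSpeedCmS)
      expect_equal(m2@perRoi$timeS, m@perRoi$timeS)
      expect_equal(m2@transitions, m@transitions)

      # rigid rotation leaves total distance unchanged
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      expect_equal(as.numeric(totalDistance(makeTrack(xy %*% R), cal)),
                   as.numeric(totalDistance(tr, cal)), tolerance = 1e-9)
    }
  })
})

test_that("occupancy heatmaps conserve counts", {
  lay <- arenaLayout(list(A = c(0, 0, 100, 100)))
  withr::with_seed(6, {
    xy <- cbind(runif(77, 0, 100), runif(77, 0, 100))
  })
  g <- occupancyHeatmap(makeTrack(xy), lay, bins = 10)
  expect_equal(sum(g), 77L)

  gStat <- occupancyHeatmap(makeTrack(rbind(c(50, 50), c(50, 50), c(50, 50))),
                            lay, bins = 8)
  expect_equal(sum(gStat > 0), 1L)
  expect_equal(sum(gStat), 3L)

  # a sweep visiting every cell center once is perfectly even
  centers <- seq(5, 95, by = 10)
  sweep <- as.matrix(expand.grid(x = centers, y = centers))
  gSweep <- occupancyHeatmap(makeTrack(sweep), lay, bins = 10)
  expect_equal(max(gSweep) / min(gSweep), 1)
})
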
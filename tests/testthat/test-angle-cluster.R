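test_that("headings follow the y-flip convention and unwrap continuously", {
  expect_equal(headingSeries(rbind(c(0, 0), c(1, 0))), 0)
  expect_equal(headingSeries(rbind(c(0, 0), c(0, -1))), 90)   # up on screen
  expect_equal(headingSeries(rbind(c(0, 0), c(-1, 0))), 180)
  expect_equal(unwrapDegrees(c(170, -170)), c(170, 190))
  # sub-threshold displacements reuse the previous heading
  h <- headingSeries(rbind(c(0, 0), c(10, 0), c(10.1, 0.1), c(10.1, -9.9)),
                     minStepPx = 1)
  expect_equal(h[1:2], c(0, 0))
  expect_equal(h[3], 90, tolerance = 1e-9)
  expect_error(headingSeries(rbind(c(0, 0), c(0.1, 0)), minStepPx = 5),
               "minStepPx")
})

test_that("re-wrapping an unwrapped series recovers the raw headings", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      traj <- matrix(cumsum(rnorm(40)), ncol = 2)
      u <- headingSeries(traj)
      d <- diff(u)
      expect_true(all(d > -180 & d <= 180))
      raw <- atan2(-diff(traj[, 2]), diff(traj[, 1])) * 180 / pi
      expect_equal(wrapDegrees(u), wrapDegrees(raw), tolerance = 1e-9)
    }
  })
})

test_that("Gaussian smoothing normalizes, fixes constants, and calms impulses", {
  for (k in c(1L, 3L, 10L))
    expect_equal(sum(gaussianKernel(k)), 1)
  expect_equal(gaussianSmooth(rep(42, 30), 3), rep(42, 30))
  # impulse response: center value is 90 * central weight
  y <- gaussianSmooth(c(0, 0, 0, 0, 90, 0, 0, 0, 0), 3)
  expect_equal(y[5], 90 * gaussianKernel(3)[4])
  expect_error(gaussianSmooth(5, 3), "at least 2")
})

test_that("total variation is non-increasing in kernel size", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      x <- rnorm(120, sd = 30)
      tvs <- c(totalVariation(x),
               totalVariation(gaussianSmooth(x, 1)),
               totalVariation(gaussianSmooth(x, 3)),
               totalVariation(gaussianSmooth(x, 10)))
      expect_true(all(diff(tvs) <= 1e-9))
    }
  })
})

test_that("constant angle series at different lengths give DTW = 10 * max(n, m)", {
  # verified by path enumeration at small sizes first
  for (nm in list(c(2, 3), c(3, 5), c(4, 4))) {
    a <- rep(0, nm[1]); b <- rep(10, nm[2])
    expect_equal(oracleDTW(a, b), 10 * max(nm))
    expect_equal(dtwDistance(a, b)$distance, 10 * max(nm))
  }
  expect_equal(dtwDistance(rep(0, 40), rep(10, 60))$distance, 600)
  # duplicated series in a matrix: zero mutual distance, symmetry
  dm <- as.matrix(angleDissimilarityMatrix(list(a = 1:5, b = 1:5, c = 6:10)))
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm, t(dm))
})

test_that("hierarchy cutoffs bracket the trivial partitions", {
  withr::with_seed(31, m <- as.matrix(stats::dist(matrix(rnorm(12), ncol = 2))))
  h <- hierarchicalCluster(m, "average", cutoffHeight = Inf)
  expect_equal(length(unique(clusterLabels(h))), 1L)
  hLow <- cutHierarchy(h, min(m[m > 0]) / 2)
  expect_equal(length(unique(clusterLabels(hLow))), 6L)
  # merge heights are monotone for the monotone linkages
  for (meth in c("ward", "complete", "average"))
    expect_true(all(diff(hierarchicalCluster(m, meth)@height) >= -1e-9))
  expect_error(hierarchicalCluster(m, "medoidish"), "arg")
})

test_that("ward separates {0,1} from {10,11} at an intermediate cutoff", {
  D <- as.matrix(stats::dist(c(0, 1, 10, 11)))
  rownames(D) <- colnames(D) <- paste0("p", 1:4)
  h <- hierarchicalCluster(D, "ward", cutoffHeight = 5)
  lab <- clusterLabels(h)
  expect_equal(unname(lab), c(1L, 1L, 2L, 2L))
})

test_that("all five linkages match the brute-force agglomerative oracle", {
  withr::with_seed(41, {
    for (rep in 1:40) {
      # arbitrary symmetric dissimilarities for the pair-recomputable linkages
      n <- 6L
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- runif(n * (n - 1) / 2, 1, 10)
      m <- m + t(m)
      for (meth in c("single", "complete", "average")) {
        ora <- oracleAgglomerate(n, oracleClusterDist(meth, D = m))
        impl <- hierarchicalCluster(m, meth)
        expect_equal(impl@height, ora$heights, tolerance = 1e-9)
        expect_equal(implPartitions(impl), ora$partitions)
      }
      # Euclidean point sets for the geometric linkages: the oracle computes
      # cluster distances from coordinates, the implementation only ever
      # sees the squared-distance matrix
      pts <- matrix(runif(2 * n, 0, 10), ncol = 2)
      D2 <- as.matrix(stats::dist(pts))^2
      for (meth in c("centroid", "ward")) {
        ora <- oracleAgglomerate(n, oracleClusterDist(meth, pts = pts))
        impl <- hierarchicalCluster(D2, meth)
        expect_equal(impl@height, ora$heights, tolerance = 1e-9)
        expect_equal(implPartitions(impl), ora$partitions)
      }
    }
  })
})

test_that("linkages agree with stats::hclust on the shared methods", {
  withr::with_seed(43, m <- as.matrix(stats::dist(matrix(rnorm(24), ncol = 2))))
  canon <- function(v) match(v, unique(unname(v)))
  n <- nrow(m)
  for (pair in list(c("single", "single"), c("complete", "complete"),
                    c("average", "average"), c("ward", "ward.D"))) {
    impl <- hierarchicalCluster(m, pair[1])
    ref <- stats::hclust(stats::as.dist(m), method = pair[2])
    expect_equal(impl@height, ref$height, tolerance = 1e-9)
    for (k in 2:5) {
      cutAt <- mean(impl@height[c(n - k, n - k + 1)])
      expect_equal(canon(clusterLabels(cutHierarchy(impl, cutAt))),
                   canon(stats::cutree(ref, k = k)))
    }
  }
})

test_that("cluster profiles average resampled members with population SD", {
  s <- list(a = rep(5, 10), b = rep(5, 10))
  p <- clusterMeanProfile(s, c(a = 1, b = 1))
  expect_equal(p[["1"]]@mean, rep(5, 10))
  expect_equal(p[["1"]]@sd, rep(0, 10))

  s2 <- list(a = rep(0, 8), b = rep(10, 8))
  p2 <- clusterMeanProfile(s2, c(a = 1, b = 1))
  expect_equal(p2[["1"]]@mean, rep(5, 8))
  expect_equal(p2[["1"]]@sd, rep(5, 8))            # population SD

  # singleton cluster: mean is the member, SD is 0; resampling to the
  # shortest member length
  s3 <- list(a = seq(0, 90, length.out = 20), b = rep(1, 10))
  p3 <- clusterMeanProfile(s3, c(a = 1, b = 2))
  expect_length(p3[["1"]]@mean, 10L)
  expect_equal(p3[["1"]]@mean, seq(0, 90, length.out = 10), tolerance = 1e-9)
  expect_equal(p3[["1"]]@sd, rep(0, 10))
})

test_that("cumulative cost matrices report between-cluster distance", {
  pA <- new("ClusterProfile", cluster = "1", mean = rep(0, 6), sd = rep(0, 6))
  pB <- new("ClusterProfile", cluster = "2", mean = rep(10, 6), sd = rep(0, 6))
  cm <- clusterCostMatrix(pA, pB)
  expect_equal(cm$distance, 60)                    # 10 per step on the diagonal
  expect_equal(oracleDTW(rep(0, 4), rep(10, 4)), 40)
  expect_equal(dim(cm$costMatrix), c(6L, 6L))
  expect_equal(clusterCostMatrix(pA, pA)$distance, 0)
})

test_that("three planted angle archetypes are recovered exactly at zero noise", {
  skip_if_not_installed("mclust")
  pop <- simulatePopulation(angleArchetypes(), nPerCluster = 5, length = 100,
                            noiseSigma = 0, seed = 7, kind = "angle1d")
  dm <- angleDissimilarityMatrix(pop$series)
  h <- hierarchicalCluster(dm, "ward", cutoffHeight = 1000)
  expect_equal(length(unique(clusterLabels(h))), 3L)
  expect_equal(mclust::adjustedRandIndex(clusterLabels(h), pop$labels), 1)
})
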
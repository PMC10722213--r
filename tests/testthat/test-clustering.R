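test_that("the penalized distance takes its analytic values", {
  # all terms vanish
  expect_equal(fkDistance(c(1, 2, 3), c(1, 2, 3), 1.5, 1.5, 1.5), 0)
  # worked example: ||x-c|| = 5, dFD = 1, FD-to-mean gap 0.5
  d <- fkDistance(c(0, 0, 0), c(3, 4, 0), fdX = 2, fdC = 1, meanFDCi = 1.5,
                  beta = 0.1, gamma = 0.5)
  expect_equal(d, sqrt(25.225), tolerance = 1e-12)
  expect_equal(d, 5.0224, tolerance = 1e-4)
  # reduction to Euclidean at beta = gamma = 0
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(3); cc <- rnorm(3)
    expect_equal(fkDistance(x, cc, runif(1), runif(1), runif(1), 0, 0),
                 sqrt(sum((x - cc)^2)))
  }
  expect_error(fkDistance(1, 2, 1, 1, 1, beta = -1), "beta")
})

test_that("K-means++ seeding is deterministic and spans all points at k = N", {
  set.seed(2)
  pts <- matrix(rnorm(24), 8, 3)
  fd <- runif(8)
  cfg <- clusterConfig(seed = 99)
  i1 <- kmeansppInit(pts, fd, 8, cfg)
  expect_setequal(i1$index, 1:8)
  i2 <- kmeansppInit(pts, fd, 3, cfg)
  i3 <- kmeansppInit(pts, fd, 3, cfg)
  expect_identical(i2$index, i3$index)
  expect_error(kmeansppInit(pts, fd, 9, cfg), "exceeds")
})

test_that("seeding probabilities are proportional to squared distance", {
  # 5-point 1D instance; FD constant so the penalized metric is Euclidean
  pts <- matrix(c(0, 1, 3, 7, 12), 5, 1)
  fd <- rep(1, 5)
  nDraw <- 40000
  draws <- matrix(0L, nDraw, 2)
  for (s in seq_len(nDraw)) {
    init <- kmeansppInit(pts, fd, 2, clusterConfig(seed = s))
    draws[s, ] <- init$index[1:2]
  }
  # exact joint distribution over (first, second)
  pj <- matrix(0, 5, 5)
  for (i in 1:5) {
    d2 <- (pts[, 1] - pts[i, 1])^2
    pj[i, ] <- (1 / 5) * d2 / sum(d2)
  }
  obs <- table(factor(draws[, 1], 1:5), factor(draws[, 2], 1:5))
  keep <- pj > 0
  chi2 <- sum((obs[keep] - nDraw * pj[keep])^2 / (nDraw * pj[keep]))
  dfree <- sum(keep) - 1
  expect_gt(pchisq(chi2, dfree, lower.tail = FALSE), 1e-3)
})

test_that("a single cluster converges to the coordinate mean", {
  set.seed(3)
  pts <- matrix(rnorm(60), 20, 3)
  st <- fkmeansFit(pts, runif(20), 1, clusterConfig(seed = 1))
  expect_equal(st@centroids[1, ], colMeans(pts), tolerance = 1e-9)
  expect_true(all(st@assignments == 1L))
  expect_lte(st@iterations, clusterConfig()$maxIter)
})

test_that("at beta = gamma = 0 the fit matches a reference K-means++", {
  set.seed(4)
  for (trial in 1:3) {
    n <- 150
    pts <- rbind(matrix(rnorm(2 * 50), 50, 2),
                 matrix(rnorm(2 * 50, 6), 50, 2),
                 matrix(rnorm(2 * 50, c(0, 9)), 50, 2))
    fd <- runif(n, 0, 3)
    seed <- 100 + trial
    cfg <- clusterConfig(beta = 0, gamma = 0, seed = seed)
    st <- fkmeansFit(pts, fd, 3, cfg)
    ref <- oracleKmeans(pts, 3, seed)
    expect_identical(as.integer(st@assignments), as.integer(ref))
  }
})

test_that("well-separated blobs with distinct FD are recovered exactly", {
  set.seed(5)
  a <- matrix(rnorm(40 * 3, 0, 0.5), 40, 3)
  b <- matrix(rnorm(40 * 3, 20, 0.5), 40, 3)
  pts <- rbind(a, b)
  fd <- c(rnorm(40, 2.5, 0.05), rnorm(40, 1, 0.05))
  st <- fkmeansFit(pts, fd, 2, clusterConfig(seed = 6))
  lab <- st@assignments
  expect_true(length(unique(lab[1:40])) == 1 &&
                length(unique(lab[41:80])) == 1 &&
                lab[1] != lab[41])
  # every cluster nonempty and statistics recomputable
  expect_equal(st@clusterFDMean[lab[1]], mean(fd[1:40]))
  expect_equal(st@clusterFDVar[lab[41]], var(fd[41:80]))
})

test_that("the stopping rule fires on the printed inequalities", {
  # mean change 0.12 >= tau1 = 0.1
  s1 <- stopCheck(c(1.50, 0.3), c(1.62, 0.3))
  expect_true(s1$stop)
  expect_match(s1$reason, "mean")
  # identical statistics: continue
  expect_false(stopCheck(c(1.5, 0.3), c(1.5, 0.3))$stop)
  # variance change 0.06 >= tau2 = 0.05 with equal means
  s3 <- stopCheck(c(1.5, 0.30), c(1.5, 0.36))
  expect_true(s3$stop)
  expect_match(s3$reason, "var")
  # exact threshold equality triggers
  expect_true(stopCheck(c(1.0, 0.1), c(1.1, 0.1))$stop)
  # stabilize mode inverts the decision
  expect_false(stopCheck(c(1.5, 0.3), c(1.62, 0.3), mode = "stabilize")$stop)
  expect_true(stopCheck(c(1.5, 0.3), c(1.5, 0.3), mode = "stabilize")$stop)
})

test_that("a level stops at the first comparison when statistics jump", {
  # two nearby groups with FD 1 and 2 plus one remote group with FD 0:
  # k=2 merges the nearby pair (fibrosis mean 1.5), k=3 isolates the
  # FD-2 group (mean 2), so the mean-FD jump stops the sweep at
  # k = k_min + 1
  set.seed(7)
  pts <- rbind(matrix(rnorm(30 * 3, c(0, 0, 0), 0.3), 30, 3),
               matrix(rnorm(30 * 3, c(12, 0, 0), 0.3), 30, 3),
               matrix(rnorm(30 * 3, c(60, 0, 0), 0.3), 30, 3))
  fd <- rep(c(1, 2, 0), each = 30) + rnorm(90, 0, 0.01)
  cfg <- clusterConfig(seed = 8, coordScale = 1)
  res <- runLevel(pts, fd, c(2, 10), cfg, levelIndex = 1)
  expect_equal(res$selectedK, 3)
  expect_match(res$stopReason, "mean|var")
})

test_that("a level exhausts its range when statistics never move", {
  # one tight FD plateau: every clustering has indistinguishable cluster
  # means, the fibrosis region heals to the full set, and no stop fires
  set.seed(8)
  pts <- matrix(runif(80 * 3, 0, 20), 80, 3)
  fd <- rnorm(80, 2, 0.005)
  res <- runLevel(pts, fd, c(2, 5), clusterConfig(seed = 9), levelIndex = 2)
  expect_equal(res$selectedK, 5)
  expect_match(res$stopReason, "exhausted")
  expect_true(all(res$members))
  # fewer points than k_min: input returned unchanged with a warning
  expect_warning(r2 <- runLevel(pts[1, , drop = FALSE], fd[1], c(2, 5),
                                clusterConfig()), "unchanged")
  expect_true(all(r2$members))
})

test_that("hierarchical segmentation is deterministic and bounded", {
  spec <- phantomSpec(shape = c(48, 48, 16), poolRadius = c(11, 9, 4.5),
                      wallThickness = 2, nPVBranches = 0, seed = 11)
  ph <- generatePhantom(spec)
  geo <- plainLA(c(48, 48, 16), c(11, 9, 4.5), 2)
  fdm <- fdMap(ph$volume, 7, region = geo$wall)
  s1 <- segmentFibrosis(ph$volume, geo$wall, fdm, clusterConfig(seed = 2))
  s2 <- segmentFibrosis(ph$volume, geo$wall, fdm, clusterConfig(seed = 2))
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$history, s2$history)
  # output is a subset of the clipped wall, three levels recorded
  expect_true(all(geo$wall[s1$mask]))
  expect_length(s1$levels, 3)
  expect_error(segmentFibrosis(ph$volume, array(FALSE, c(48, 48, 16)), fdm),
               "empty")
})

test_that("baselines behave on constructed inputs", {
  # two-intensity slice: exact bipartition
  a <- array(1, c(10, 10, 1)); a[6:10, , 1] <- 9
  m <- array(TRUE, c(10, 10, 1))
  bk <- baselineKmeans2D(newVolume(a), m, k = 2, seed = 1)
  expect_identical(bk[, , 1], a[, , 1] == 9)
  expect_identical(bk, baselineKmeans2D(newVolume(a), m, k = 2, seed = 1))
  # region growing: uniform region bounded by a strong edge
  b <- array(0, c(12, 12, 3)); b[4:9, 4:9, 2] <- 5
  rg <- baselineRegionGrow(newVolume(b), c(6, 6, 2), tol = 1)
  expect_identical(rg, b == 5)
  # tol = 0 grows only through equal intensities
  b2 <- b; b2[5, 5, 2] <- 5.4
  rg0 <- baselineRegionGrow(newVolume(b2), c(6, 6, 2), tol = 0)
  expect_false(rg0[5, 5, 2])
  expect_error(baselineRegionGrow(newVolume(b), c(50, 1, 1), 1), "outside")
})
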
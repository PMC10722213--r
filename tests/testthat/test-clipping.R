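test_that("region normalization and binarization follow the z-score rule", {
  # region of {0, 10}: population mean 5, sd 5 -> normalized {-1, 1}
  a <- array(0, c(4, 4, 1))
  a[, 1:2, 1] <- 0; a[, 3:4, 1] <- 10
  reg <- array(TRUE, c(4, 4, 1))
  b <- normalizeAndBinarize(newVolume(a), reg, 0.2)
  expect_identical(b[, , 1], a[, , 1] == 10)
  # threshold boundary: normalized value exactly 0.2 binarizes to 1;
  # the probe voxel sits outside the region so mu = 5, sd = 5 exactly
  a2 <- array(0, c(5, 4, 1))
  a2[1:4, 1:2, 1] <- 0; a2[1:4, 3:4, 1] <- 10
  a2[5, 1, 1] <- 6                    # (6 - 5) / 5 == 0.2
  reg2 <- array(FALSE, c(5, 4, 1)); reg2[1:4, , 1] <- TRUE
  b2 <- normalizeAndBinarize(newVolume(a2), reg2, 0.2)
  expect_true(b2[5, 1, 1])
  # constant region is degenerate
  expect_error(normalizeAndBinarize(newVolume(array(3, c(4, 4, 1))), reg),
               "degenerate")
})

test_that("disc dilation is extensive and produces the expected disc", {
  m <- array(FALSE, c(15, 15, 1))
  m[8, 8, 1] <- TRUE
  d3 <- dilateRoi(m, 3)
  # single voxel dilates to the disc of radius 3 in its slice
  expected <- outer(1:15, 1:15, function(x, y) (x - 8)^2 + (y - 8)^2 <= 3^2)
  expect_true(all(d3[, , 1][expected]))
  expect_false(any(d3[, , 1][!outer(1:15, 1:15, function(x, y)
    (x - 8)^2 + (y - 8)^2 <= 4^2)]))
  # extensivity for random masks and radii
  set.seed(1)
  for (i in 1:3) {
    rm <- array(runif(12 * 12 * 2) < 0.1, c(12, 12, 2))
    if (!any(rm)) next
    expect_true(all(dilateRoi(rm, sample(1:5, 1))[rm]))
  }
  expect_error(dilateRoi(array(FALSE, c(4, 4, 1))), "empty")
})

test_that("exact distance maps match the brute-force oracle", {
  set.seed(3)
  edge <- array(FALSE, c(20, 20, 1))
  edge[5, 5, 1] <- TRUE
  d <- distanceMap(array(TRUE, c(20, 20, 1)), edge, "exact")
  expect_equal(d$data[5, 5, 1], 0)
  expect_equal(d$data[5, 9, 1], 4)          # axis-aligned distance
  edge2 <- array(runif(20 * 20) < 0.05, c(20, 20, 1))
  if (!any(edge2)) edge2[7, 7, 1] <- TRUE
  dx <- distanceMap(array(TRUE, c(20, 20, 1)), edge2, "exact")
  expect_equal(dx$data[, , 1], oracleSliceDistance(edge2[, , 1]),
               tolerance = 1e-6)
  expect_error(distanceMap(array(TRUE, c(5, 5, 1)),
                           array(FALSE, c(4, 4, 1))), "mismatch")
})

test_that("chamfer distances stay within the stated error bound", {
  set.seed(9)
  for (i in 1:3) {
    edge <- array(runif(64 * 64) < 0.02, c(64, 64, 1))
    if (!any(edge)) edge[32, 32, 1] <- TRUE
    ex <- distanceMap(array(TRUE, c(64, 64, 1)), edge, "exact")$data
    ch <- distanceMap(array(TRUE, c(64, 64, 1)), edge, "chamfer")$data
    pos <- ex > 0
    expect_lte(max(abs(ch[pos] - ex[pos]) / ex[pos]), 0.08)
  }
})

test_that("seed selection finds distance peaks and respects d_min", {
  # all-zero distance map: no seeds
  z <- array(0, c(16, 16, 1))
  expect_equal(nrow(selectCandidates(z, array(TRUE, c(16, 16, 1)), 3)), 0)
  # two distant blobs: one seed at each distance peak
  dom <- array(FALSE, c(40, 20, 1))
  dom[3:13, 3:13, 1] <- TRUE
  dom[28:38, 8:18, 1] <- TRUE
  edge <- fkmeans:::maskBoundary2d(dom)
  dm <- distanceMap(dom, edge, "exact")
  # distance measured from blob boundaries: peaks at blob centres
  seeds <- selectCandidates(dm, dom & !edge, dMin = 2, nmsRadius = 8)
  expect_equal(nrow(seeds), 2)
  centers <- seeds[order(seeds[, 1]), ]
  expect_equal(unname(centers[1, 1:2]), c(8, 8), tolerance = 1)
  expect_equal(unname(centers[2, 1:2]), c(33, 13), tolerance = 1)
  # d_min beyond the maximum distance: empty
  expect_equal(nrow(selectCandidates(dm, dom, dMin = 50)), 0)
})

test_that("Voronoi partitions match brute-force nearest-seed labelling", {
  # one seed: a single cell covering the domain
  dom <- array(TRUE, c(8, 8, 3))
  p1 <- voronoiPartition(matrix(c(4, 4, 2), 1), dom)
  expect_true(all(p1@cellOf[dom] == 1L))
  expect_equal(nrow(p1@adjacency), 0)
  # bisector with tie-break to the lowest seed index
  dom2 <- array(TRUE, c(11, 3, 3))
  seeds2 <- rbind(c(1, 1, 1), c(11, 1, 1))
  p2 <- voronoiPartition(seeds2, dom2)
  expect_true(all(p2@cellOf[1:5, , ] == 1L))
  expect_true(all(p2@cellOf[6, , ] == 1L))   # equidistant -> lowest index
  expect_true(all(p2@cellOf[7:11, , ] == 2L))
  expect_equal(p2@adjacency, matrix(c(1L, 2L), 1))
  # random 20-seed instance against the brute-force oracle
  set.seed(12)
  dom3 <- array(runif(18 * 15 * 6) < 0.7, c(18, 15, 6))
  seeds3 <- cbind(sample(1:18, 20, TRUE), sample(1:15, 20, TRUE),
                  sample(1:6, 20, TRUE))
  seeds3 <- unique(seeds3)
  p3 <- voronoiPartition(seeds3, dom3)
  expect_identical(p3@cellOf, oracleVoronoi(seeds3, dom3))
  # adjacency is symmetric-free and without self pairs
  expect_true(all(p3@adjacency[, 1] < p3@adjacency[, 2]))
  expect_error(voronoiPartition(matrix(numeric(0), 0, 3), dom3), "seeds")
})

test_that("cell features separate snake-like from blob-like cells", {
  # constructed domain: a winding tube and a compact blob, one seed each
  dm <- c(70, 40, 9)
  dom <- array(FALSE, dm)
  for (x in 5:60) {
    yc <- 20 + 8 * sin(2 * pi * x / 28)
    dom[x, round(yc) + (-1:1), 4:6] <- TRUE
  }
  blob <- array(FALSE, dm)
  for (x in 55:67) for (y in 28:39) for (z in 3:7)
    if ((x - 61)^2 + (y - 33)^2 + (z - 5)^2 <= 30) blob[x, y, z] <- TRUE
  dom2 <- dom | blob
  seeds <- rbind(c(20, 20, 5), c(61, 33, 5))
  part <- voronoiPartition(seeds, dom2)
  vol <- array(50, dm)
  fdm <- fdMap(vol, 7)
  feats <- cellFeatures(part, fdm, dom2, minCellVoxels = 20)
  f <- feats@features
  expect_true(all(f$featured))
  expect_gt(f$tortuosity[1], f$tortuosity[2])
  # constant intensity: zero FD everywhere
  expect_equal(f$fdMean, c(0, 0))
  # sub-threshold cells are unfeatured
  feats2 <- cellFeatures(part, fdm, dom2, minCellVoxels = 1e6)
  expect_false(any(feats2@features$featured))
})

test_that("truncation flags exactly at the feature-difference thresholds", {
  dom <- array(TRUE, c(10, 5, 3))
  seeds <- rbind(c(3, 3, 2), c(8, 3, 2))
  part <- voronoiPartition(seeds, dom)
  mkFeats <- function(fd, tort) {
    new("CellFeatures", features = data.frame(
      cell = 1:2, nVoxels = c(75, 75), fdMean = fd, tortuosity = tort,
      avgWidth = c(3, 3), featured = TRUE))
  }
  la <- dom
  # both differences at their thresholds: flagged (>= comparison)
  tr <- truncateCells(part, mkFeats(c(1.0, 1.7), c(1.0, 2.0)), la)
  expect_equal(tr$flagged, 2L)            # higher tortuosity cell removed
  expect_equal(sum(tr$clipped), sum(la) - sum(part@cellOf == 2L))
  # FD difference just below threshold: conjunctive rule does not fire
  tr2 <- truncateCells(part, mkFeats(c(1.0, 1.69), c(1.0, 2.0)), la)
  expect_length(tr2$flagged, 0)
  expect_identical(tr2$clipped, la)
  # identical features: nothing flagged
  tr3 <- truncateCells(part, mkFeats(c(1.2, 1.2), c(1.1, 1.1)), la)
  expect_length(tr3$flagged, 0)
  # disjunctive rule fires on either difference
  tr4 <- truncateCells(part, mkFeats(c(1.0, 1.69), c(1.0, 2.0)), la,
                       rule = "or")
  expect_equal(tr4$flagged, 2L)
  # unfeatured cells never trigger truncation
  fu <- mkFeats(c(1.0, 1.8), c(1.0, 2.1))
  fu@features$featured[2] <- FALSE
  expect_length(truncateCells(part, fu, la)$flagged, 0)
})

test_that("truncation is monotone in its thresholds", {
  set.seed(21)
  dom <- array(TRUE, c(24, 12, 3))
  seeds <- cbind(sample(1:24, 6), sample(1:12, 6), sample(1:3, 6, TRUE))
  seeds <- unique(seeds)
  part <- voronoiPartition(seeds, dom)
  n <- nrow(seeds)
  feats <- new("CellFeatures", features = data.frame(
    cell = seq_len(n), nVoxels = rep(100L, n),
    fdMean = runif(n, 0, 3), tortuosity = runif(n, 1, 3),
    avgWidth = rep(3, n), featured = TRUE))
  la <- dom
  grid <- expand.grid(dFD = c(0.2, 0.5, 0.9), dT = c(0.3, 0.8, 1.4))
  counts <- matrix(NA_integer_, 3, 3)
  for (i in seq_len(nrow(grid))) {
    fl <- truncateCells(part, feats, la, grid$dFD[i], grid$dT[i])$flagged
    counts[match(grid$dFD[i], c(0.2, 0.5, 0.9)),
           match(grid$dT[i], c(0.3, 0.8, 1.4))] <- length(fl)
  }
  # raising either threshold never flags more cells
  expect_true(all(apply(counts, 2, diff) <= 0))
  expect_true(all(apply(counts, 1, diff) <= 0))
})

test_that("the clipping pipeline is deterministic and only removes wall", {
  spec <- phantomSpec(seed = 4)
  ph <- generatePhantom(spec)
  fdm <- fdMap(ph$volume, 7)
  c1 <- clipPipeline(ph$volume, ph$mask, clipConfig(), fdmap = fdm)
  c2 <- clipPipeline(ph$volume, ph$mask, clipConfig(), fdmap = fdm)
  expect_identical(c1$clipped, c2$clipped)
  la <- maskLabel(ph$mask, c("la", "fibrosis"))
  expect_true(all(la[c1$clipped]))         # clipped is a subset of the wall
  expect_gte(diceScore(c1$clipped, la), 0.80)
})

test_that("clipping a structure-free LA is the identity", {
  geo <- plainLA()
  vol <- array(49, c(48, 48, 16))
  vol[geo$pool] <- 50.5
  vol[geo$wall] <- 52.5
  set.seed(2)
  vol <- vol + array(rnorm(length(vol), 0, 0.25), dim(vol))
  res <- clipPipeline(newVolume(vol), geo$la, clipConfig())
  expect_identical(res$clipped, geo$la)
  expect_length(res$flagged, 0)
})
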
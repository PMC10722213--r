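mkMask <- function(d, coords) {
  m <- array(FALSE, d)
  if (length(coords)) m[coords] <- TRUE
  m
}

test_that("Dice takes its analytic values and is symmetric", {
  d <- c(6, 6, 3)
  a <- array(FALSE, d); a[1:2, 1:5, 1] <- TRUE          # 10 voxels
  b <- array(FALSE, d); b[2:3, 1:5, 1] <- TRUE          # 10, overlap 5
  expect_equal(diceScore(a, b), 0.5)
  expect_equal(diceScore(a, a), 1)
  dis <- array(FALSE, d); dis[6, 6, 3] <- TRUE
  expect_equal(diceScore(a, dis), 0)
  expect_equal(diceScore(a, b), diceScore(b, a))
  expect_equal(diceScore(array(FALSE, d), array(FALSE, d)), 1)
  expect_error(diceScore(a, array(FALSE, c(2, 2, 2))), "mismatch")
})

test_that("precision and recall follow the confusion counts", {
  d <- c(8, 8, 2)
  truth <- array(FALSE, d); truth[1:3, 1:4, 1] <- TRUE   # 12 voxels
  expect_equal(unname(precisionRecall(truth, truth)), c(1, 1))
  half <- array(FALSE, d); half[1:3, 1:2, 1] <- TRUE     # subset, half
  expect_equal(unname(precisionRecall(half, truth)), c(1, 0.5))
  # constructed counts: TP = 8, FP = 2, FN = 4
  truth2 <- array(FALSE, d); truth2[1:2, 1:6, 1] <- TRUE          # 12
  pred2 <- array(FALSE, d); pred2[1:2, 1:4, 1] <- TRUE            # TP 8
  pred2[5, 1:2, 1] <- TRUE                                        # FP 2
  pr <- precisionRecall(pred2, truth2)
  expect_equal(unname(pr["precision"]), 0.8)
  expect_equal(unname(pr["recall"]), 8 / 12, tolerance = 1e-12)
  # swapping arguments swaps the roles
  pr2 <- precisionRecall(truth2, pred2)
  expect_equal(unname(pr2["precision"]), unname(pr["recall"]))
  expect_warning(precisionRecall(array(FALSE, d), truth), "empty")
})

test_that("surface distances are exact on constructed masks", {
  d <- c(10, 10, 6)
  cube <- array(FALSE, d); cube[3:5, 3:5, 2:4] <- TRUE
  sd0 <- surfaceDistances(cube, cube)
  expect_equal(unname(sd0), c(0, 0, 0, 0))
  shifted <- array(FALSE, d); shifted[4:6, 3:5, 2:4] <- TRUE
  sd1 <- surfaceDistances(shifted, cube, spacing = c(1, 1, 1))
  expect_equal(unname(sd1["hd"]), 1)
  # metrics scale linearly with spacing
  sd2 <- surfaceDistances(shifted, cube, spacing = c(2, 2, 2))
  expect_equal(unname(sd2), 2 * unname(sd1))
  expect_error(surfaceDistances(array(FALSE, d), cube), "empty")
})

test_that("surface distances match the brute-force oracle on small masks", {
  set.seed(31)
  for (i in 1:4) {
    d <- c(9, 8, 7)
    a <- array(runif(prod(d)) < 0.25, d)
    b <- array(runif(prod(d)) < 0.25, d)
    if (!any(a)) a[5, 4, 3] <- TRUE
    if (!any(b)) b[2, 2, 2] <- TRUE
    sp <- c(1, 1.5, 2)
    got <- surfaceDistances(a, b, sp)
    want <- oracleSurfaceDistances(a, b, sp)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("HD95 never exceeds HD and ASSD never exceeds MSSD", {
  set.seed(32)
  for (i in 1:30) {
    d <- c(7, 7, 5)
    a <- array(runif(prod(d)) < 0.3, d)
    b <- array(runif(prod(d)) < 0.3, d)
    if (!any(a)) a[1, 1, 1] <- TRUE
    if (!any(b)) b[7, 7, 5] <- TRUE
    sdv <- surfaceDistances(a, b)
    expect_lte(sdv["hd95"], sdv["hd"])
    expect_lte(sdv["assd"], sdv["mssd"])
  }
})

test_that("the full report combines all metrics", {
  d <- c(8, 8, 4)
  a <- array(FALSE, d); a[2:5, 2:5, 2] <- TRUE
  b <- array(FALSE, d); b[3:6, 2:5, 2] <- TRUE
  rep <- evaluateSegmentation(a, b, spacing = c(1, 1, 1))
  expect_s4_class(rep, "SegmentationReport")
  expect_equal(rep@dice, diceScore(a, b))
  expect_true(rep@hd95 <= rep@hd && rep@assd <= rep@mssd)
  expect_true(rep@dice >= 0 && rep@dice <= 1)
})

test_that("ICC(2,1) matches the analysis-of-variance oracle", {
  a <- c(9, 6, 8, 7)
  b <- c(2, 1, 4, 1)
  expect_equal(icc21(a, b), oracleICC21(a, b), tolerance = 1e-12)
  set.seed(33)
  for (i in 1:5) {
    x <- rnorm(8); y <- x + rnorm(8, 0, 0.3)
    expect_equal(icc21(x, y), oracleICC21(x, y), tolerance = 1e-10)
  }
  # identical non-constant ratings: perfect agreement
  expect_equal(icc21(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # anti-correlated ratings: negative ICC
  expect_lt(icc21(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1)), 0)
  expect_error(icc21(1:2, 1:2), "at least 3")
  expect_error(icc21(rep(1, 4), rep(1, 4)), "degenerate")
})
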
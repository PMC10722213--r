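#' Dice overlap between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; two empty masks score 1 by convention.
#'
#' @param pred,truth binary masks on the same grid.
#' @return Fraction in [0, 1].
#' @export
diceScore <- function(pred, truth) {
  pred <- pred != 0; truth <- truth != 0
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred & truth) / s
}

#' Precision and recall of a predicted mask
#'
#' @inheritParams diceScore
#' @return named numeric \code{c(precision, recall)}. An empty prediction
#'   has precision 0 (with a warning); an empty truth has recall 1 when
#'   the prediction is also empty, otherwise 0 precision contributions
#'   follow from the counts.
#' @export
precisionRecall <- function(pred, truth) {
  pred <- pred != 0; truth <- truth != 0
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp + fp == 0) {
    warning("empty prediction: precision defined as 0")
    prec <- 0
  } else prec <- tp / (tp + fp)
  rec <- if (tp + fn == 0) 1 else tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' Symmetric surface distances between two masks
#'
#' Boundary voxels (foreground with a face-adjacent background neighbour,
#' counting out-of-volume as background) are extracted from both masks;
#' directed minimum distances are computed in physical units both ways.
#' ASSD is the mean over the pooled directed sets, MSSD and HD the
#' maximum, and HD95 the 95th percentile of the pooled set.
#'
#' @inheritParams diceScore
#' @param spacing per-axis voxel size in mm.
#' @return named numeric \code{c(assd, mssd, hd, hd95)}.
#' @export
surfaceDistances <- function(pred, truth, spacing = c(1, 1, 1)) {
  pred <- pred != 0; truth <- truth != 0
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (!any(pred) || !any(truth))
    stop("surface distances undefined for an empty mask")
  bp <- voxelCoords(maskBoundary(pred)) * 1.0
  bt <- voxelCoords(maskBoundary(truth)) * 1.0
  dPT <- .directedMinDistances(bp, bt, as.numeric(spacing))
  dTP <- .directedMinDistances(bt, bp, as.numeric(spacing))
  pool <- c(dPT, dTP)
  c(assd = mean(pool), mssd = max(pool), hd = max(pool),
    hd95 = as.numeric(quantile(pool, 0.95)))
}

#' Full segmentation report
#'
#' @inheritParams surfaceDistances
#' @return A \linkS4class{SegmentationReport}.
#' @export
evaluateSegmentation <- function(pred, truth, spacing = c(1, 1, 1)) {
  pred <- pred != 0; truth <- truth != 0
  pr <- suppressWarnings(precisionRecall(pred, truth))
  sdists <- if (any(pred) && any(truth))
    surfaceDistances(pred, truth, spacing)
  else c(assd = NA_real_, mssd = NA_real_, hd = NA_real_, hd95 = NA_real_)
  new("SegmentationReport", dice = diceScore(pred, truth),
      precision = unname(pr["precision"]), recall = unname(pr["recall"]),
      assd = unname(sdists["assd"]), mssd = unname(sdists["mssd"]),
      hd = unname(sdists["hd"]), hd95 = unname(sdists["hd95"]),
      nPred = sum(pred), nTruth = sum(truth))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two raters, from the classical mean squares:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n} (MS_C - MS_E)}}
#' with n cases and k = 2 raters.
#'
#' @param ratingsA,ratingsB numeric vectors of per-case measurements from
#'   the two raters (equal length >= 3).
#' @return ICC estimate (can be negative for anti-correlated ratings).
#' @export
icc21 <- function(ratingsA, ratingsB) {
  n <- length(ratingsA)
  if (length(ratingsB) != n) stop("rating vectors differ in length")
  if (n < 3) stop("need at least 3 cases")
  x <- cbind(ratingsA, ratingsB)
  k <- 2
  grand <- mean(x)
  rowM <- rowMeans(x)
  colM <- colMeans(x)
  ssR <- k * sum((rowM - grand)^2)
  ssC <- n * sum((colM - grand)^2)
  ssTot <- sum((x - grand)^2)
  ssE <- ssTot - ssR - ssC
  msR <- ssR / (n - 1)
  msC <- ssC / (k - 1)
  msE <- ssE / ((n - 1) * (k - 1))
  den <- msR + (k - 1) * msE + k * (msC - msE) / n
  if (!is.finite(den) || den == 0)
    stop("degenerate ratings: zero variance across cases and raters")
  (msR - msE) / den
}
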
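#' Configuration for hierarchical fractal-penalized K-means
#'
#' @param beta weight of the point-vs-centroid FD penalty (default 0.1).
#' @param gamma weight of the point-vs-cluster-mean FD penalty (default 0.5).
#' @param tau1 stopping threshold on the change of the fibrosis region's
#'   mean FD between successive cluster counts (default 0.1).
#' @param tau2 stopping threshold on the change of its FD variance
#'   (default 0.05).
#' @param levelKRanges list of (k_min, k_max) per hierarchy level
#'   (default \code{list(c(2,30), c(2,5), c(2,3))}).
#' @param maxIter maximum Lloyd iterations per fit (default 100).
#' @param convTol convergence tolerance on the maximum centroid
#'   displacement, in feature-space units (default 1e-6).
#' @param seed RNG seed controlling every K-means++ initialization.
#' @param coordScale multiplier applied to voxel coordinates before
#'   clustering (default 0.005). The FD penalties operate on FD units of
#'   order 1; unscaled voxel coordinates on a ~100-voxel grid would make
#'   the spatial term dominate the metric by four orders of magnitude, so
#'   coordinates are shrunk until both terms are commensurate.
#' @param stopMode "literal": a change >= tau stops the sweep (the printed
#'   inequalities); "stabilize": a change below tau stops it.
#' @param fibrosisRegion "union": the fibrosis region at each k is the
#'   union of clusters whose mean FD lies within tau1 of the maximum
#'   cluster mean (clusters whose means are not significantly different,
#'   in the sense of the stopping metric, are not distinguished);
#'   "single": strictly the maximum-mean cluster.
#' @return A validated list of options.
#' @export
clusterConfig <- function(beta = 0.1, gamma = 0.5, tau1 = 0.1, tau2 = 0.05,
                          levelKRanges = list(c(2, 30), c(2, 5), c(2, 3)),
                          maxIter = 100, convTol = 1e-6, seed = 1,
                          coordScale = 0.005,
                          stopMode = c("literal", "stabilize"),
                          fibrosisRegion = c("union", "single")) {
  stopifnot(beta >= 0, gamma >= 0, tau1 > 0, tau2 > 0,
            length(levelKRanges) == 3, maxIter >= 1, coordScale > 0)
  for (kr in levelKRanges)
    stopifnot(length(kr) == 2, kr[1] >= 1, kr[2] >= kr[1])
  list(beta = beta, gamma = gamma, tau1 = tau1, tau2 = tau2,
       levelKRanges = levelKRanges, maxIter = maxIter, convTol = convTol,
       seed = as.integer(seed), coordScale = coordScale,
       stopMode = match.arg(stopMode),
       fibrosisRegion = match.arg(fibrosisRegion))
}

#' Fractal-penalized point-to-centroid distance
#'
#' \deqn{d(x,c) = \sqrt{\|x-c\|^2 + \beta\,(FD(x)-FD(c))^2 +
#'   \gamma\,(FD(x) - \overline{FD}(c_i))^2}}
#'
#' @param x,c numeric coordinate vectors of the point and centroid.
#' @param fdX,fdC fractal dimension of the point and of the centroid.
#' @param meanFDCi mean FD of the centroid's cluster members (previous
#'   iteration).
#' @param beta,gamma penalty weights.
#' @return Nonnegative distance; reduces to the Euclidean distance at
#'   \code{beta = gamma = 0}.
#' @export
fkDistance <- function(x, c, fdX, fdC, meanFDCi, beta = 0.1, gamma = 0.5) {
  stopifnot(beta >= 0, gamma >= 0)
  sqrt(sum((x - c)^2) + beta * (fdX - fdC)^2 + gamma * (fdX - meanFDCi)^2)
}

# Squared fk distances from all points to one centroid (vectorized).
fkDist2 <- function(points, fd, cen, fdC, meanFDCi, beta, gamma) {
  rowSums(sweep(points, 2, cen)^2) + beta * (fd - fdC)^2 +
    gamma * (fd - meanFDCi)^2
}

#' K-means++ initialization under the fractal-penalized metric
#'
#' The first centroid is drawn uniformly; each further centroid is drawn
#' with probability proportional to the squared penalized distance to the
#' nearest already-chosen centroid. Because no clusters exist during
#' seeding, the cluster-mean FD of a chosen centroid is taken as the
#' centroid's own FD (the gamma term collapses onto the beta term).
#'
#' @param points numeric matrix (N x d) in feature space.
#' @param fd per-point FD values.
#' @param k number of centroids (<= N).
#' @param config a \code{\link{clusterConfig}}; \code{config$seed} makes
#'   the draw deterministic.
#' @return list with \code{centroids} (k x d), \code{fd} (k) and
#'   \code{index} (row indices of the chosen points).
#' @export
kmeansppInit <- function(points, fd, k, config = clusterConfig()) {
  n <- nrow(points)
  if (k > n) stop("k exceeds the number of points")
  withSeed(config$seed, kmeansppInitImpl(points, fd, k, config))
}

kmeansppInitImpl <- function(points, fd, k, config) {
  n <- nrow(points)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- fkDist2(points, fd, points[idx[1], ], fd[idx[1]], fd[idx[1]],
                config$beta, config$gamma)
  if (k > 1) for (j in 2:k) {
    tot <- sum(d2)
    idx[j] <- if (tot > 0) sample.int(n, 1, prob = d2 / tot)
              else sample.int(n, 1)
    nd <- fkDist2(points, fd, points[idx[j], ], fd[idx[j]], fd[idx[j]],
                  config$beta, config$gamma)
    d2 <- pmin(d2, nd)
  }
  list(centroids = points[idx, , drop = FALSE], fd = fd[idx], index = idx)
}

#' Fit fractal-penalized K-means for a fixed k
#'
#' Lloyd iterations under the penalized metric: points are assigned to the
#' nearest centroid, centroid positions are recomputed as the mean of
#' their members, the FD of a (generally off-lattice) centroid is the FD
#' of its nearest data point, and the cluster-mean FD entering the gamma
#' term is taken from the previous iteration's assignments. Clusters that
#' empty are re-seeded at the point currently farthest from its centroid
#' (distinct points when several clusters empty at once). Iteration stops
#' when the largest centroid displacement falls below \code{convTol} or
#' after \code{maxIter} iterations.
#'
#' @inheritParams kmeansppInit
#' @return A \linkS4class{ClusterState}.
#' @export
fkmeansFit <- function(points, fd, k, config = clusterConfig()) {
  if (!nrow(points)) stop("empty input")
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(points)) stop("k exceeds the number of points")
  init <- kmeansppInit(points, fd, k, config)
  fkmeansLloyd(points, fd, k, init, config)
}

fkmeansLloyd <- function(points, fd, k, init, config) {
  n <- nrow(points)
  cen <- init$centroids
  cfd <- init$fd
  mfd <- cfd                      # no assignments yet: gamma uses FD(c)
  asg <- rep(1L, n)
  beta <- config$beta; gamma <- config$gamma
  iters <- 0L
  for (it in seq_len(config$maxIter)) {
    iters <- it
    D <- matrix(0, n, k)
    for (j in seq_len(k))
      D[, j] <- fkDist2(points, fd, cen[j, ], cfd[j], mfd[j], beta, gamma)
    asg <- max.col(-D, ties.method = "first")
    newcen <- cen
    used <- integer(0)
    for (j in seq_len(k)) {
      m <- which(asg == j)
      if (!length(m)) {             # re-seed at the farthest point
        dd <- D[cbind(seq_len(n), asg)]
        if (length(used)) dd[used] <- -Inf
        far <- which.max(dd)
        asg[far] <- j
        m <- far
        used <- c(used, far)
      }
      newcen[j, ] <- colMeans(points[m, , drop = FALSE])
    }
    for (j in seq_len(k))
      cfd[j] <- fd[which.min(rowSums(sweep(points, 2, newcen[j, ])^2))]
    mfd <- vapply(seq_len(k), function(j) {
      x <- fd[asg == j]
      if (length(x)) mean(x) else cfd[j]
    }, numeric(1))
    move <- max(rowSums((newcen - cen)^2))
    cen <- newcen
    if (move < config$convTol^2) break
  }
  vfd <- vapply(seq_len(k), function(j) {
    x <- fd[asg == j]
    if (length(x) > 1) var(x) else 0
  }, numeric(1))
  new("ClusterState", points = points, fd = fd, assignments = as.integer(asg),
      centroids = cen, centroidFD = cfd, clusterFDMean = mfd,
      clusterFDVar = vfd, iterations = iters)
}

#' Stopping decision between two fibrosis-region statistics
#'
#' Implements the two stopping metrics on the (mean, variance) of the FD
#' of the fibrosis region at successive cluster counts: in the literal
#' mode the sweep stops when \eqn{|mean_i - mean_{i-1}| \ge \tau_1} or
#' \eqn{|var_i - var_{i-1}| \ge \tau_2}; in the stabilize mode it stops
#' when both changes fall below their thresholds.
#'
#' @param prev,curr numeric vectors \code{c(meanFD, varFD)}.
#' @param tau1,tau2 thresholds.
#' @param mode "literal" or "stabilize".
#' @return list(stop = logical, reason = character).
#' @export
stopCheck <- function(prev, curr, tau1 = 0.1, tau2 = 0.05,
                      mode = c("literal", "stabilize")) {
  mode <- match.arg(mode)
  dMean <- abs(curr[1] - prev[1])
  dVar <- abs(curr[2] - prev[2])
  if (mode == "literal") {
    stop <- (dMean >= tau1) || (dVar >= tau2)
    reason <- if (dMean >= tau1) "mean-FD change >= tau1"
              else if (dVar >= tau2) "var-FD change >= tau2"
              else "continue"
  } else {
    stop <- (dMean < tau1) && (dVar < tau2)
    reason <- if (stop) "statistics stabilized below tau1/tau2" else "continue"
  }
  list(stop = stop, reason = reason)
}

# Indices of the clusters forming the fibrosis region of a fit. Clusters
# below a minimum size cannot anchor the region (a lone extreme-FD voxel
# is not a fibrosis estimate), but small clusters whose mean FD ties with
# the anchor are still absorbed in union mode.
fibrosisClusters <- function(state, config, minAnchor = 10L) {
  m <- state@clusterFDMean
  sizes <- tabulate(state@assignments, nbins = length(m))
  eligible <- sizes >= min(minAnchor, max(sizes))
  top <- which(eligible)[which.max(m[eligible])]
  if (config$fibrosisRegion == "union")
    which(m > m[top] - config$tau1)
  else top
}

#' Run one level of the clustering hierarchy
#'
#' Sweeps the cluster count upward through the level's range. After each
#' fit the fibrosis region is identified (see
#' \code{\link{clusterConfig}}'s \code{fibrosisRegion}) and its FD mean
#' and variance are compared with the previous count's values via
#' \code{\link{stopCheck}}; the sweep ends at the k where the stop fires
#' (or when the range is exhausted), and that state's fibrosis-region
#' points feed the next level. The first k of a level is never compared.
#' With fewer points than k_min the level returns its input unchanged,
#' with a warning.
#'
#' @param points numeric matrix of voxel coordinates (unscaled).
#' @param fd per-point FD values.
#' @param kRange integer(2): (k_min, k_max).
#' @param config a \code{\link{clusterConfig}}.
#' @param levelIndex 1-based level number (seeds the per-k fits).
#' @return list with \code{state} (\linkS4class{ClusterState} or NULL when
#'   skipped), \code{selectedK}, \code{members} (logical vector over input
#'   points: the fibrosis region), \code{history} (data.frame of per-k
#'   statistics) and \code{stopReason}.
#' @export
runLevel <- function(points, fd, kRange, config = clusterConfig(),
                     levelIndex = 1) {
  n <- nrow(points)
  if (n < kRange[1]) {
    warning("fewer points than k_min; level returns its input unchanged")
    return(list(state = NULL, selectedK = NA_integer_,
                members = rep(TRUE, n), history = NULL,
                stopReason = "insufficient points"))
  }
  scaled <- points * config$coordScale
  prev <- NULL
  sel <- NULL
  hist <- NULL
  reason <- "k range exhausted"
  for (k in kRange[1]:min(kRange[2], n)) {
    cfgK <- config
    cfgK$seed <- config$seed + 7919L * as.integer(levelIndex) + as.integer(k)
    st <- fkmeansFit(scaled, fd, k, cfgK)
    reg <- fibrosisClusters(st, config)
    mem <- st@assignments %in% reg
    mu <- mean(fd[mem])
    v <- if (sum(mem) > 1) var(fd[mem]) else 0
    hist <- rbind(hist, data.frame(level = levelIndex, k = k, meanFD = mu,
                                   varFD = v, n = sum(mem)))
    sel <- list(state = st, selectedK = k, members = mem)
    if (!is.null(prev)) {
      sc <- stopCheck(prev, c(mu, v), config$tau1, config$tau2,
                      config$stopMode)
      if (sc$stop) { reason <- sc$reason; break }
    }
    prev <- c(mu, v)
  }
  c(sel, list(history = hist, stopReason = reason))
}

#' Hierarchical fibrosis segmentation of the clipped LA wall
#'
#' Runs three clustering levels, each on the previous level's fibrosis
#' region, and returns the final region mapped back to a voxel mask. The
#' per-level, per-k FD statistics and stop reasons are recorded in the
#' \code{history} attribute of the result.
#'
#' @param volume a \linkS4class{Volume} (used to compute the FD map when
#'   \code{fdmap} is NULL).
#' @param clippedLA logical 3D array: the clipped LA wall voxels to
#'   cluster.
#' @param fdmap optional \linkS4class{FDMap}; computed from \code{volume}
#'   over \code{clippedLA} when missing.
#' @param config a \code{\link{clusterConfig}}.
#' @return A list with \code{mask} (logical 3D array of fibrosis voxels),
#'   \code{levels} (per-level voxel masks), \code{history} (data.frame)
#'   and \code{stopReasons}.
#' @export
segmentFibrosis <- function(volume, clippedLA, fdmap = NULL,
                            config = clusterConfig()) {
  clippedLA <- clippedLA != 0
  if (!any(clippedLA)) stop("empty clipped LA mask")
  if (is.null(fdmap)) fdmap <- fdMap(volume, region = clippedLA)
  coords <- voxelCoords(clippedLA)
  fd <- fdmap@data[coords]
  ok <- is.finite(fd)
  coords <- coords[ok, , drop = FALSE]
  fd <- fd[ok]
  idx <- seq_len(nrow(coords))
  levels <- list()
  hist <- NULL
  reasons <- character(0)
  for (lev in seq_along(config$levelKRanges)) {
    res <- runLevel(coords[idx, , drop = FALSE] * 1.0, fd[idx],
                    config$levelKRanges[[lev]], config, lev)
    idx <- idx[res$members]
    hist <- rbind(hist, res$history)
    reasons <- c(reasons, res$stopReason)
    m <- array(FALSE, dim(clippedLA))
    m[coords[idx, , drop = FALSE]] <- TRUE
    levels[[lev]] <- m
  }
  list(mask = levels[[length(levels)]], levels = levels, history = hist,
       stopReasons = reasons)
}
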
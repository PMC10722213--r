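#' Configuration for the Voronoi clipping pipeline
#'
#' @param dilationRadius radius (voxels) of the per-slice disc dilation
#'   defining the periatrial search region (default 20).
#' @param binThreshold threshold on the z-normalized intensity; voxels with
#'   normalized intensity >= this value binarize to 1 (default 0.2).
#' @param deltaFD,deltaTort truncation thresholds on the absolute
#'   difference of fractal dimension (default 0.7) and tortuosity
#'   (default 1.0) between adjacent Voronoi cells.
#' @param dMin minimum distance-map value (voxels) for a cell seed to be a
#'   structure candidate (default 3).
#' @param nmsRadius non-maximum-suppression radius between seeds (default 5).
#' @param candidateNmsRadius wider suppression radius applied among
#'   structure candidates (seeds with distance >= dMin) so that each
#'   distant structure is covered by a single cell (default 15).
#' @param minCellVoxels cells smaller than this are unfeatured and never
#'   truncated (default 20).
#' @param distanceMode "exact" per-slice Euclidean distance (default) or
#'   "chamfer" two-pass 3x3 propagation with weights 1 and sqrt(2).
#' @param rule "and" (default) requires both feature differences to exceed
#'   their thresholds; "or" flags on either.
#' @param scaleMax maximum scaling factor R for the FD map (default 7).
#' @return A validated list of options.
#' @export
clipConfig <- function(dilationRadius = 20, binThreshold = 0.2,
                       deltaFD = 0.7, deltaTort = 1.0, dMin = 3,
                       nmsRadius = 5, candidateNmsRadius = 15,
                       minCellVoxels = 20,
                       distanceMode = c("exact", "chamfer"),
                       rule = c("and", "or"), scaleMax = 7) {
  stopifnot(dilationRadius >= 1, dMin > 0, nmsRadius >= 1, minCellVoxels >= 1)
  list(dilationRadius = dilationRadius, binThreshold = binThreshold,
       deltaFD = deltaFD, deltaTort = deltaTort, dMin = dMin,
       nmsRadius = nmsRadius, candidateNmsRadius = candidateNmsRadius,
       minCellVoxels = minCellVoxels,
       distanceMode = match.arg(distanceMode), rule = match.arg(rule),
       scaleMax = scaleMax)
}

#' Normalize within a region and binarize
#'
#' Intensities are z-scored using the mean and standard deviation of the
#' voxels inside \code{laMask} only, then thresholded: normalized values
#' greater than or equal to \code{threshold} map to 1.
#'
#' @param volume a \linkS4class{Volume}.
#' @param laMask logical 3D array (the LA region the statistics come from).
#' @param threshold binarization threshold on the normalized scale.
#' @return logical 3D array.
#' @export
normalizeAndBinarize <- function(volume, laMask, threshold = 0.2) {
  a <- if (is(volume, "Volume")) volume@data else volume
  laMask <- laMask != 0
  if (!any(laMask)) stop("empty LA mask")
  v <- a[laMask]
  mu <- mean(v)
  sg <- sqrt(mean((v - mu)^2))        # population sd of the region
  if (!is.finite(sg) || sg == 0)
    stop("degenerate input: zero intensity variance inside the LA region")
  (a - mu) / sg >= threshold
}

#' Per-slice disc dilation of a mask
#'
#' @param laMask logical 3D array (or \linkS4class{LabelMask}).
#' @param radius disc radius in voxels (default 20).
#' @return logical 3D array containing the input (dilation is extensive).
#' @export
dilateRoi <- function(laMask, radius = 20) {
  m <- if (is(laMask, "LabelMask")) laMask@data != 0 else laMask != 0
  if (!any(m)) stop("empty mask")
  stopifnot(radius >= 1)
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  out <- array(FALSE, dim(m))
  for (z in seq_len(dim(m)[3])) {
    sl <- m[, , z]
    if (any(sl))
      out[, , z] <- EBImage::dilate(EBImage::Image(sl * 1), brush) > 0.5
  }
  out | m
}

#' Per-slice distance map to the LA wall edge
#'
#' For every voxel, the 2D distance (within its slice) to the nearest wall
#' edge voxel. The default mode is the exact Euclidean distance transform;
#' chamfer mode propagates a 3x3 kernel with axis weight 1 and diagonal
#' weight sqrt(2) in two passes, matching the exact map to within the
#' chamfer error bound (about 8\%).
#'
#' @param binaryVol logical 3D array (clipping domain; distances are
#'   reported on its full grid).
#' @param wallEdge logical 3D array of wall-edge voxels.
#' @param mode "exact" or "chamfer".
#' @return A list with \code{data} (3D numeric array of distances, 0 on the
#'   edge, \code{Inf} in slices without edge voxels) and \code{wallEdge}.
#' @export
distanceMap <- function(binaryVol, wallEdge, mode = c("exact", "chamfer")) {
  mode <- match.arg(mode)
  if (!identical(dim(binaryVol), dim(wallEdge))) stop("shape mismatch")
  wallEdge <- wallEdge != 0
  d <- array(Inf, dim(binaryVol))
  for (z in seq_len(dim(binaryVol)[3])) {
    ed <- wallEdge[, , z]
    if (!any(ed)) next
    d[, , z] <- if (mode == "exact") {
      # distance of every pixel to the nearest edge pixel
      EBImage::distmap(EBImage::Image(1 - ed))@.Data
    } else {
      .chamferDistance(ed)
    }
  }
  list(data = d, wallEdge = wallEdge, mode = mode)
}

# Boundary of a binary mask: foreground voxels with a face-adjacent
# background neighbour (out-of-volume counts as background).
maskBoundary <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  shift <- function(m, ax, s) {
    out <- array(FALSE, d)            # out-of-volume neighbours stay FALSE
    idx <- lapply(d, seq_len)
    src <- idx
    if (s == 1) { idx[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { idx[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  inner <- mask
  for (ax in 1:3) for (s in c(1, -1)) inner <- inner & shift(mask, ax, s)
  mask & !inner
}

# 2D per-slice boundary (used for the wall edge of the clipping pipeline,
# which operates slice-wise).
maskBoundary2d <- function(mask) {
  mask <- mask != 0
  out <- array(FALSE, dim(mask))
  for (z in seq_len(dim(mask)[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    er <- sl
    n <- nrow(sl); m <- ncol(sl)
    inner <- sl
    inner[2:n, ] <- inner[2:n, ] & sl[1:(n - 1), ]
    inner[1:(n - 1), ] <- inner[1:(n - 1), ] & sl[2:n, ]
    inner[, 2:m] <- inner[, 2:m] & sl[, 1:(m - 1)]
    inner[, 1:(m - 1)] <- inner[, 1:(m - 1)] & sl[, 2:m]
    inner[1, ] <- FALSE; inner[n, ] <- FALSE
    inner[, 1] <- FALSE; inner[, m] <- FALSE
    out[, , z] <- sl & !inner
  }
  out
}

#' Select Voronoi seed candidates from a distance map
#'
#' Local maxima of the per-slice distance map with distance at least
#' \code{dMin}, thinned by greedy 3D non-maximum suppression (descending
#' distance, minimum pairwise separation \code{nmsRadius}).
#'
#' @param dmap result of \code{\link{distanceMap}} (or a 3D numeric array).
#' @param domain logical 3D array restricting the search (e.g. binarized
#'   volume within the dilated ROI).
#' @param dMin minimum distance value.
#' @param nmsRadius minimum seed separation in voxels.
#' @return Integer matrix (n x 3) of seed coordinates, possibly 0 rows.
#' @export
selectCandidates <- function(dmap, domain, dMin = 3, nmsRadius = 5) {
  d <- if (is.list(dmap)) dmap$data else dmap
  stopifnot(dMin > 0)
  cand <- localMaxima2d(d, domain)
  cand <- cand[d[cand] >= dMin & is.finite(d[cand]), , drop = FALSE]
  nonMaxSuppress(cand, d, nmsRadius)
}

# All local maxima (>=) of the distance map within each slice, restricted
# to the domain and to strictly positive distances.
localMaxima2d <- function(d, domain) {
  res <- NULL
  for (z in seq_len(dim(d)[3])) {
    dom <- domain[, , z]
    if (!any(dom)) next
    sl <- d[, , z]
    sl[!dom] <- -Inf                  # maxima of the field *within* the domain
    n <- nrow(sl); m <- ncol(sl)
    pad <- matrix(-Inf, n + 2, m + 2)
    pad[2:(n + 1), 2:(m + 1)] <- sl
    isMax <- matrix(TRUE, n, m)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      isMax <- isMax & (sl >= pad[(2:(n + 1)) + dx, (2:(m + 1)) + dy])
    }
    sel <- which(isMax & dom & sl > 0 & is.finite(sl), arr.ind = TRUE)
    if (nrow(sel))
      res <- rbind(res, cbind(sel, z))
  }
  if (is.null(res)) res <- matrix(integer(0), 0, 3)
  colnames(res) <- c("x", "y", "z")
  res
}

nonMaxSuppress <- function(cand, d, radius) {
  if (!nrow(cand)) return(cand)
  vals <- d[cand]
  ord <- order(-vals, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    dd <- sqrt(rowSums(sweep(prev, 2, cand[i, ])^2))
    keep[i] <- all(dd >= radius)
  }
  cand[keep, , drop = FALSE]
}

#' Voronoi partition of a voxel domain
#'
#' Assigns every domain voxel to its nearest seed (Euclidean distance in
#' physical units; ties broken by the lowest seed index) and records the
#' face-adjacency of the resulting cells.
#'
#' @param seeds integer matrix (n x 3) of seed voxel coordinates.
#' @param domain logical 3D array.
#' @param spacing per-axis voxel size (default isotropic).
#' @return A \linkS4class{VoronoiPartition}.
#' @export
voronoiPartition <- function(seeds, domain, spacing = c(1, 1, 1)) {
  if (is.null(seeds) || nrow(seeds) == 0)
    stop("empty partition: no seeds (treat clipping as a no-op)")
  vox <- voxelCoords(domain != 0)
  cellOf <- array(0L, dim(domain))
  if (nrow(vox)) {
    ss <- sweep(seeds, 2, spacing, "*")
    ss2 <- rowSums(ss^2)
    best <- integer(nrow(vox))
    # chunked nearest-seed search keeps the distance matrix small
    chunk <- 4096L
    for (start in seq(1L, nrow(vox), by = chunk)) {
      ii <- start:min(start + chunk - 1L, nrow(vox))
      vs <- sweep(vox[ii, , drop = FALSE], 2, spacing, "*")
      d2 <- outer(rowSums(vs^2), rep(1, nrow(ss))) - 2 * vs %*% t(ss) +
        outer(rep(1, length(ii)), ss2)
      # max.col on the negated matrix with "first" ties -> lowest seed index
      best[ii] <- max.col(-d2, ties.method = "first")
    }
    cellOf[vox] <- best
  }
  adj <- cellAdjacency(cellOf)
  new("VoronoiPartition", seeds = as.matrix(seeds), cellOf = cellOf,
      adjacency = adj)
}

cellAdjacency <- function(cellOf) {
  d <- dim(cellOf)
  pairs <- NULL
  grab <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])) else NULL
  }
  pairs <- rbind(
    grab(cellOf[-d[1], , , drop = FALSE], cellOf[-1, , , drop = FALSE]),
    grab(cellOf[, -d[2], , drop = FALSE], cellOf[, -1, , drop = FALSE]),
    grab(cellOf[, , -d[3], drop = FALSE], cellOf[, , -1, drop = FALSE]))
  if (is.null(pairs) || !nrow(pairs)) return(matrix(integer(0), 0, 2))
  unique(pairs)
}

#' Per-cell fractal-dimension and tortuosity features
#'
#' For every Voronoi cell, the mean FD over the cell's foreground voxels
#' and the tortuosity and average width of the cell's largest foreground
#' component. Cells with fewer foreground voxels than \code{minCellVoxels}
#' are flagged unfeatured (NA features) and can never trigger truncation;
#' the same applies when the tortuosity of a cell is degenerate (e.g. a
#' closed-loop component).
#'
#' @param partition a \linkS4class{VoronoiPartition}.
#' @param fdmap an \linkS4class{FDMap} on the same grid.
#' @param binaryVol logical 3D array of foreground voxels.
#' @param minBranchLen passed to \code{\link{tortuosity}}.
#' @param minCellVoxels minimum foreground size of a featured cell.
#' @return A \linkS4class{CellFeatures}.
#' @export
cellFeatures <- function(partition, fdmap, binaryVol, minBranchLen = 4,
                         minCellVoxels = 20) {
  if (!identical(dim(partition@cellOf), dim(fdmap@data)))
    stop("FD map grid mismatch")
  nCell <- nrow(partition@seeds)
  fg <- binaryVol != 0
  feats <- data.frame(cell = seq_len(nCell), nVoxels = 0L,
                      fdMean = NA_real_, tortuosity = NA_real_,
                      avgWidth = NA_real_, featured = FALSE)
  for (j in seq_len(nCell)) {
    sel <- partition@cellOf == j & fg
    n <- sum(sel)
    feats$nVoxels[j] <- n
    if (n < minCellVoxels) next
    fdv <- fdmap@data[sel]
    feats$fdMean[j] <- mean(fdv[is.finite(fdv)])
    tr <- tryCatch(tortuosity(sel, minBranchLen = minBranchLen),
                   error = function(e) NULL)
    if (!is.null(tr)) {
      feats$tortuosity[j] <- tr@tortuosity
      feats$avgWidth[j] <- tr@avgWidth
      feats$featured[j] <- is.finite(feats$fdMean[j])
    }
  }
  new("CellFeatures", features = feats)
}

#' Truncate structure-like Voronoi cells from the LA wall
#'
#' For every adjacent pair of featured cells whose absolute feature
#' differences reach both thresholds (\code{rule = "and"}; either with
#' \code{rule = "or"}), the member cell marked as anatomical structure is
#' flagged: the cell with the greater tortuosity (PV-like), or, if the
#' tortuosities tie within 0.1, the cell with the greater FD (MV-like).
#' Wall voxels belonging to flagged cells are removed. Only cells whose
#' seed lies at distance >= \code{dMin} from the wall edge (structure
#' candidates) can be flagged.
#'
#' @param partition a \linkS4class{VoronoiPartition}.
#' @param feats a \linkS4class{CellFeatures}.
#' @param laMask logical 3D array: the LA wall mask being clipped.
#' @param deltaFD,deltaTort truncation thresholds (defaults 0.7 and 1.0).
#' @param rule "and" or "or".
#' @param candidate logical per-cell vector; non-candidates are never
#'   flagged (default: all cells eligible).
#' @return A list with \code{clipped} (logical 3D array, a subset of
#'   \code{laMask}) and \code{flagged} (integer cell indices removed).
#' @export
truncateCells <- function(partition, feats, laMask, deltaFD = 0.7,
                          deltaTort = 1.0, rule = c("and", "or"),
                          candidate = NULL) {
  rule <- match.arg(rule)
  laMask <- laMask != 0
  f <- feats@features
  nCell <- nrow(f)
  if (is.null(candidate)) candidate <- rep(TRUE, nCell)
  flagged <- logical(nCell)
  adj <- partition@adjacency
  for (r in seq_len(nrow(adj))) {
    i <- adj[r, 1]; j <- adj[r, 2]
    if (!f$featured[i] || !f$featured[j]) next
    dFD <- abs(f$fdMean[i] - f$fdMean[j])
    dTort <- abs(f$tortuosity[i] - f$tortuosity[j])
    hit <- if (rule == "and") (dFD >= deltaFD && dTort >= deltaTort)
           else (dFD >= deltaFD || dTort >= deltaTort)
    if (!hit) next
    pick <- if (dTort > 0.1) {
      if (f$tortuosity[i] > f$tortuosity[j]) i else j
    } else {
      if (f$fdMean[i] >= f$fdMean[j]) i else j
    }
    if (candidate[pick]) flagged[pick] <- TRUE
  }
  clipped <- laMask
  if (any(flagged))
    clipped[partition@cellOf %in% which(flagged)] <- FALSE
  list(clipped = clipped, flagged = which(flagged))
}

#' Full Voronoi clipping pipeline
#'
#' Chains per-slice disc dilation, region normalization and binarization,
#' per-slice distance mapping from the LA wall edge, seed selection,
#' Voronoi partitioning, per-cell feature extraction and truncation,
#' producing the clipped LA wall (Clipped_LA). When no seeds are found the
#' pipeline degrades to the identity on the wall mask.
#'
#' @param volume a \linkS4class{Volume}.
#' @param laMask \linkS4class{LabelMask} or logical array: the LA (blood
#'   pool + wall) segmentation. If a LabelMask is given, labels \code{la}
#'   and \code{fibrosis} form the region.
#' @param config a \code{\link{clipConfig}} list.
#' @param fdmap optional precomputed \linkS4class{FDMap}.
#' @return A list with \code{clipped} (logical 3D array, subset of the LA
#'   mask), \code{partition}, \code{features}, \code{seeds},
#'   \code{flagged}, \code{binary} and \code{dmap}.
#' @export
clipPipeline <- function(volume, laMask, config = clipConfig(),
                         fdmap = NULL) {
  la <- if (is(laMask, "LabelMask"))
    maskLabel(laMask, c("la", "fibrosis")) else laMask != 0
  if (!any(la)) stop("empty LA mask")
  checkSameGrid(volume, if (is(laMask, "LabelMask")) laMask else
    newLabelMask(array(0L, dim(la))))
  roi <- dilateRoi(la, config$dilationRadius)
  binary <- normalizeAndBinarize(volume, la, config$binThreshold) & roi
  wallEdge <- maskBoundary2d(la)
  dmap <- distanceMap(binary, wallEdge, config$distanceMode)
  # structure candidates (distance >= dMin) are thinned with a wide radius
  # so each distant structure gets one cell; all remaining positive maxima
  # become ordinary wall cells that serve as feature references and are
  # never truncated
  cands <- selectCandidates(dmap, binary, config$dMin,
                            config$candidateNmsRadius)
  refs <- nonMaxSuppress(localMaxima2d(dmap$data, binary), dmap$data,
                         config$nmsRadius)
  refs <- refs[dmap$data[refs] < config$dMin, , drop = FALSE]
  if (nrow(cands) && nrow(refs)) {
    # drop references too close to a candidate
    dd <- .minDistanceToSet(refs * 1.0, cands * 1.0)
    refs <- refs[dd >= config$nmsRadius, , drop = FALSE]
  }
  allSeeds <- rbind(cands, refs)
  if (nrow(allSeeds) == 0)
    return(list(clipped = la, partition = NULL, features = NULL,
                seeds = allSeeds, flagged = integer(0), binary = binary,
                dmap = dmap))
  candidate <- dmap$data[allSeeds] >= config$dMin
  part <- voronoiPartition(allSeeds, binary | la)
  if (is.null(fdmap))
    fdmap <- fdMap(volume, R = config$scaleMax, region = binary | la)
  feats <- cellFeatures(part, fdmap, binary,
                        minCellVoxels = config$minCellVoxels)
  tr <- truncateCells(part, feats, la, config$deltaFD, config$deltaTort,
                      config$rule, candidate)
  list(clipped = tr$clipped, partition = part, features = feats,
       seeds = allSeeds, flagged = tr$flagged, binary = binary, dmap = dmap)
}
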
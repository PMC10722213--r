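#' Skeleton tortuosity and width of a binary shape
#'
#' Measures how winding a shape is as the ratio \eqn{L/D} of its spine
#' (centerline) arc length to the straight-line distance between the spine
#' endpoints. 2D masks are skeletonized by Zhang-Suen thinning, short
#' branches are pruned, and the spine is the weighted longest geodesic of
#' the skeleton graph. 3D masks use a centerline extracted as the
#' minimum-cost path between the two graph-farthest voxels, penalized away
#' from the boundary so that it follows the ridge of the distance
#' transform. In both cases the spine is smoothed by snapping to local mask
#' centroids, extended to the shape boundary at both ends, and measured as
#' a dense polyline. Analysis is restricted to the largest connected
#' component.
#'
#' @param mask logical 2D matrix or 3D array (nonzero = shape).
#' @param minBranchLen skeleton branches shorter than this many voxels are
#'   pruned (default 4).
#' @param spacing physical voxel size (isotropic measurements assume the
#'   default of 1; lengths are scaled by the mean spacing otherwise).
#' @return A \linkS4class{TortuosityResult}.
#' @export
tortuosity <- function(mask, minBranchLen = 4, spacing = 1) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  nd <- length(dim(mask))
  res <- if (nd == 2L) tortuosity2d(mask, minBranchLen)
         else if (nd == 3L) tortuosity3d(mask)
         else stop("mask must be 2D or 3D")
  s <- mean(spacing)
  new("TortuosityResult",
      tortuosity = res$L / res$D,
      spineLength = res$L * s,
      endpointDistance = res$D * s,
      avgWidth = res$width * s,
      nBranches = res$nBranches)
}

## ---- shared helpers ----

# Undirected voxel-adjacency graph (8-/26-connectivity) over a coordinate
# matrix; edge weights are Euclidean step lengths.
voxelGraph <- function(coords) {
  d <- ncol(coords)
  key <- apply(coords, 1, paste, collapse = ",")
  idx <- seq_len(nrow(coords))
  names(idx) <- key
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  froms <- integer(0); tos <- integer(0); ws <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    nk <- apply(nb, 1, paste, collapse = ",")
    j <- idx[nk]
    hit <- !is.na(j) & idx < j          # each edge once
    if (any(hit)) {
      froms <- c(froms, idx[hit]); tos <- c(tos, j[hit])
      ws <- c(ws, rep(sqrt(sum(offs[r, ]^2)), sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  if (length(froms))
    g <- igraph::add_edges(g, rbind(froms, tos), weight = ws)
  g
}

largestComponent <- function(g, coords) {
  cmp <- igraph::components(g)
  keep <- which(cmp$membership == which.max(cmp$csize))
  list(g = igraph::induced_subgraph(g, keep),
       coords = coords[keep, , drop = FALSE])
}

# Length of a polyline through the given points.
polylineLength <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2)))
}

# Snap each path point to the centroid of mask voxels within `rad`,
# suppressing lattice zigzag so the polyline length is unbiased.
smoothToCentroids <- function(pts, coords, rad) {
  out <- pts
  r2 <- rad^2
  for (i in seq_len(nrow(pts))) {
    d2 <- rowSums(sweep(coords, 2, pts[i, ])^2)
    sel <- d2 <= r2
    if (sum(sel) >= 3) out[i, ] <- colMeans(coords[sel, , drop = FALSE])
  }
  out
}

# Extend a spine end along its local direction until it leaves the mask;
# recovers the cap length that thinning erodes.
extendSpineEnd <- function(pts, inMask, fromEnd, maxStep = 50) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  if (fromEnd) { p <- pts[n, ]; q <- pts[max(1, n - 3), ] }
  else { p <- pts[1, ]; q <- pts[min(n, 4), ] }
  dir <- p - q
  nd <- sqrt(sum(dir^2))
  if (nd < 1e-9) return(pts)
  dir <- dir / nd
  last <- p
  for (s in seq(0.5, maxStep, by = 0.5)) {
    cand <- round(p + s * dir)
    if (!inMask(cand)) break
    last <- p + s * dir
  }
  if (fromEnd) rbind(pts, last) else rbind(last, pts)
}

maskLookup <- function(coords) {
  env <- new.env(hash = TRUE, size = nrow(coords) * 2L)
  keys <- apply(coords, 1, paste, collapse = ",")
  for (k in keys) assign(k, TRUE, envir = env)
  function(p) {
    if (any(p < 1)) return(FALSE)
    exists(paste(round(p), collapse = ","), envir = env)
  }
}

## ---- 2D: thinning + skeleton graph ----

# Iteratively remove leaf branches shorter than minBranchLen voxels.
pruneSkeleton <- function(g, coords, minBranchLen) {
  repeat {
    deg <- igraph::degree(g)
    leaves <- which(deg == 1)
    if (!length(leaves) || igraph::vcount(g) <= minBranchLen + 1) break
    drop <- integer(0)
    for (lv in leaves) {
      path <- lv; cur <- lv; prev <- -1L
      repeat {
        nbs <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nbs) != 1L || deg[nbs] > 2L) break
        prev <- cur; cur <- nbs; path <- c(path, cur)
        if (length(path) > minBranchLen) break
      }
      if (length(path) <= minBranchLen) drop <- c(drop, path[-length(path)])
    }
    drop <- unique(drop)
    if (!length(drop) || length(drop) >= igraph::vcount(g) - 1) break
    keep <- setdiff(seq_len(igraph::vcount(g)), drop)
    g <- igraph::induced_subgraph(g, keep)
    coords <- coords[keep, , drop = FALSE]
  }
  list(g = g, coords = coords)
}

tortuosity2d <- function(mask, minBranchLen) {
  skel <- .thinSkeleton(mask)
  coords <- which(skel, arr.ind = TRUE)
  if (nrow(coords) < 2) {
    # shape thins to a point: treat as degenerate straight stub
    mc <- which(mask, arr.ind = TRUE)
    return(list(L = 1, D = 1, width = 2 * mean(boundaryDistance(mc)) - 1,
                nBranches = 0L))
  }
  lc <- largestComponent(voxelGraph(coords), coords)
  g <- lc$g; coords <- lc$coords
  pr <- pruneSkeleton(g, coords, minBranchLen)
  g <- pr$g; coords <- pr$coords
  deg <- igraph::degree(g)
  if (igraph::vcount(g) > 3 && !any(deg == 1) &&
      igraph::ecount(g) >= igraph::vcount(g))
    stop("degenerate shape: closed-loop skeleton (endpoint distance 0)")
  dia <- igraph::get_diameter(g, weights = igraph::E(g)$weight)
  pts <- coords[as.integer(dia), , drop = FALSE]
  mcoords <- which(mask, arr.ind = TRUE)
  pts <- smoothToCentroids(pts, mcoords, 2.2)
  inMask <- maskLookup(mcoords)
  pts <- extendSpineEnd(pts, inMask, TRUE)
  pts <- extendSpineEnd(pts, inMask, FALSE)
  L <- polylineLength(pts)
  D <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (D < 1e-9) stop("degenerate shape: coincident spine endpoints")
  dt <- boundaryDistance(coords, mcoords)
  list(L = L, D = D, width = mean(2 * dt - 1), nBranches = sum(deg == 1))
}

## ---- 3D: distance-ridge centerline ----

# Euclidean distance from each of `pts` to the nearest voxel *outside* the
# mask, approximated as 1 + distance to the nearest boundary mask voxel.
boundaryDistance <- function(pts, coords = pts) {
  inMask <- maskLookup(coords)
  d <- ncol(coords)
  isBnd <- vapply(seq_len(nrow(coords)), function(i) {
    p <- coords[i, ]
    for (ax in seq_len(d)) for (s in c(-1, 1)) {
      q <- p; q[ax] <- q[ax] + s
      if (!inMask(q)) return(TRUE)
    }
    FALSE
  }, logical(1))
  bc <- coords[isBnd, , drop = FALSE]
  if (!nrow(bc)) return(rep(1 + max(dim(coords)), nrow(pts)))
  .minDistanceToSet(pts * 1.0, bc * 1.0) + 1
}

tortuosity3d <- function(mask, ridgeLambda = 8) {
  coords <- which(mask, arr.ind = TRUE)
  lc <- largestComponent(voxelGraph(coords), coords)
  g <- lc$g; coords <- lc$coords
  if (nrow(coords) < 3)
    return(list(L = 1, D = 1, width = 1, nBranches = 0L))
  dt <- boundaryDistance(coords)
  # endpoints by double BFS, recentred to the local distance-ridge maximum
  d1 <- igraph::distances(g, v = 1, weights = NA)[1, ]
  A <- which.max(d1)
  dA <- igraph::distances(g, v = A, weights = NA)[1, ]
  B <- which.max(dA)
  recenter <- function(v) {
    dd <- igraph::distances(g, v = v, weights = NA)[1, ]
    cand <- which(dd <= dt[v] + 1)
    cand[which.max(dt[cand])]
  }
  A <- recenter(A); B <- recenter(B)
  el <- igraph::as_edgelist(g, names = FALSE)
  wl <- igraph::E(g)$weight
  dtmax <- max(dt)
  pen <- wl * (1 + ridgeLambda *
                 ((dtmax - dt[el[, 1]]) + (dtmax - dt[el[, 2]])) / 2)
  sp <- igraph::shortest_paths(g, from = A, to = B, weights = pen)$vpath[[1]]
  pts <- coords[as.integer(sp), , drop = FALSE]
  pts <- smoothToCentroids(pts, coords, 1.5)
  inMask <- maskLookup(coords)
  pts <- extendSpineEnd(pts, inMask, TRUE)
  pts <- extendSpineEnd(pts, inMask, FALSE)
  L <- polylineLength(pts)
  D <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (D < 1e-9) stop("degenerate shape: coincident spine endpoints")
  spineDT <- boundaryDistance(round(pts), coords)
  list(L = L, D = D, width = mean(2 * spineDT - 1),
       nBranches = max(0L, sum(igraph::degree(g) == 1)))
}
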
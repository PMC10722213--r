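#' 2D K-means intensity baseline
#'
#' Per-slice standard K-means on intensity only; the fibrosis estimate in
#' each slice is the cluster with the highest mean intensity. Slices with
#' fewer foreground voxels than \code{k} are skipped.
#'
#' @param volume a \linkS4class{Volume}.
#' @param clippedLA logical 3D array restricting the clustering.
#' @param k number of intensity clusters (default 2).
#' @param seed RNG seed for the K-means starts.
#' @return logical 3D array of estimated fibrosis voxels.
#' @export
baselineKmeans2D <- function(volume, clippedLA, k = 2, seed = 1) {
  stopifnot(k >= 2)
  a <- if (is(volume, "Volume")) volume@data else volume
  clippedLA <- clippedLA != 0
  out <- array(FALSE, dim(a))
  withSeed(seed, {
    for (z in seq_len(dim(a)[3])) {
      sel <- which(clippedLA[, , z])
      if (length(sel) <= k) next
      vals <- a[, , z][sel]
      if (length(unique(vals)) < k) next
      km <- stats::kmeans(vals, centers = k, nstart = 3)
      top <- which.max(km$centers)
      sl <- matrix(FALSE, dim(a)[1], dim(a)[2])
      sl[sel[km$cluster == top]] <- TRUE
      out[, , z] <- sl
    }
  })
  out
}

#' 3D region-growing baseline
#'
#' Classic seeded growth: starting from \code{seedPoint}, 26-connected
#' neighbours are accepted while their intensity lies within \code{tol} of
#' the running region mean. Growth order is deterministic (FIFO).
#'
#' @param volume a \linkS4class{Volume}.
#' @param seedPoint integer(3) voxel coordinate inside the volume.
#' @param tol intensity tolerance.
#' @param within optional logical 3D array restricting growth.
#' @return logical 3D array of the grown region.
#' @export
baselineRegionGrow <- function(volume, seedPoint, tol, within = NULL) {
  a <- if (is(volume, "Volume")) volume@data else volume
  d <- dim(a)
  seedPoint <- as.integer(seedPoint)
  if (any(seedPoint < 1) || any(seedPoint > d))
    stop("seed point outside the volume")
  if (!is.null(within) && !within[seedPoint[1], seedPoint[2], seedPoint[3]])
    stop("seed point outside the growth region")
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  lin <- function(p) p[1] + d[1] * (p[2] - 1L + d[2] * (p[3] - 1L))
  inMask <- array(FALSE, d)
  inMask[seedPoint[1], seedPoint[2], seedPoint[3]] <- TRUE
  queue <- matrix(seedPoint, 1, 3)
  total <- a[seedPoint[1], seedPoint[2], seedPoint[3]]
  count <- 1
  while (nrow(queue)) {
    p <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    nxt <- NULL
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      if (inMask[q[1], q[2], q[3]]) next
      if (!is.null(within) && !within[q[1], q[2], q[3]]) next
      if (abs(a[q[1], q[2], q[3]] - total / count) <= tol) {
        inMask[q[1], q[2], q[3]] <- TRUE
        total <- total + a[q[1], q[2], q[3]]
        count <- count + 1
        nxt <- rbind(nxt, q)
      }
    }
    if (!is.null(nxt)) queue <- rbind(queue, nxt)
  }
  inMask
}
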
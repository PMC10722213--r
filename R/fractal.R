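#' Differential box count of one window
#'
#' The number of boxes of scale \code{r} needed to cover the intensity
#' surface over a pixel neighbourhood:
#' \deqn{N_r = \frac{R^2}{r^2}\left(\frac{M_r - m_r}{r}\right) + 1}
#' where \eqn{M_r} and \eqn{m_r} are the window maximum and minimum and
#' \eqn{R} is the maximum scaling factor.
#'
#' @param window 2D numeric matrix: the r-neighbourhood of a pixel.
#' @param r scale, with \code{2 < r < R}.
#' @param R maximum scaling factor.
#' @return Box count (numeric >= 1).
#' @export
boxCount <- function(window, r, R) {
  if (!(r > 2 && r < R)) stop("scale must satisfy 2 < r < R")
  rng <- max(window) - min(window)
  (R^2 / r^2) * (rng / r) + 1
}

# Scales used for an FD fit: all integers strictly between 2 and R.
fdScales <- function(R) {
  if (R < 4) stop("R must be >= 4 so that at least one scale 2 < r < R exists")
  seq.int(3L, as.integer(R) - 1L)
}

# Ordinary least-squares slope of y on x.
olsSlope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc * xc)
}

#' Fractal dimension at one pixel of a slice
#'
#' Estimated as the least-squares regression slope of \eqn{\log N_r}
#' against \eqn{\log(1/r)} over all integer scales \code{2 < r < R}.
#' Windows are axis-aligned squares of side \code{r} centred at the pixel
#' (even \code{r} extends one pixel toward the positive axes), clipped at
#' the image boundary.
#'
#' @param slice 2D numeric matrix.
#' @param x,y pixel coordinates (1-based).
#' @param R maximum scaling factor (default 7).
#' @return FD value (dimensionless; 0 for a locally constant image).
#' @export
fdAt <- function(slice, x, y, R = 7) {
  rs <- fdScales(R)
  logNr <- vapply(rs, function(r) {
    lo <- (r - 1) %/% 2; hi <- r %/% 2
    xs <- max(1, x - lo):min(nrow(slice), x + hi)
    ys <- max(1, y - lo):min(ncol(slice), y + hi)
    log(boxCount(slice[xs, ys, drop = FALSE], r, R))
  }, numeric(1))
  olsSlope(log(1 / rs), logNr)
}

#' Per-voxel fractal dimension map
#'
#' Computes the differential box-counting FD at every voxel, slice by slice
#' along the z axis. Voxels outside \code{region} carry the sentinel value
#' \code{NA}.
#'
#' @param volume a \linkS4class{Volume} (or 3D array).
#' @param R maximum scaling factor; default 7.
#' @param region optional logical 3D array restricting the computation.
#' @return An \linkS4class{FDMap}.
#' @export
fdMap <- function(volume, R = 7, region = NULL) {
  a <- if (is(volume, "Volume")) volume@data else volume
  if (!is.null(region) && !identical(dim(region), dim(a)))
    stop("region shape mismatch")
  rs <- fdScales(R)
  lx <- log(1 / rs)
  lxc <- lx - mean(lx)
  den <- sum(lxc^2)
  fd <- array(NA_real_, dim(a))
  for (z in seq_len(dim(a)[3])) {
    sl <- a[, , z]
    acc <- matrix(0, nrow(sl), ncol(sl))
    for (i in seq_along(rs)) {
      rng <- .rangeFilter(sl, rs[i])
      acc <- acc + lxc[i] * log((R^2 / rs[i]^2) * (rng / rs[i]) + 1)
    }
    fd[, , z] <- acc / den
  }
  if (!is.null(region)) fd[!region] <- NA_real_
  new("FDMap", data = fd, scaleMax = as.numeric(R), rSet = rs,
      boundary = "clip", sentinel = NA_real_)
}

#' Export an FD map as a Volume
#'
#' @param fdmap an \linkS4class{FDMap}.
#' @param spacing,origin grid metadata for the output volume.
#' @param fill replacement for sentinel (out-of-region) voxels.
#' @return A \linkS4class{Volume} of FD values.
#' @export
fdMapAsVolume <- function(fdmap, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          fill = 0) {
  a <- fdmap@data
  a[!is.finite(a)] <- fill
  newVolume(a, spacing, origin)
}
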
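#' @import methods
#' @importFrom stats var sd rnorm runif quantile setNames aggregate
#' @importFrom utils head tail write.csv
#' @useDynLib fkmeans, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default label table for atrial structure masks
#'
#' Integer codes used throughout the package for the anatomical labels of a
#' \linkS4class{LabelMask}: background, left atrium (blood pool + wall),
#' pulmonary veins, mitral valve, left atrial appendage and fibrotic wall.
#'
#' @export
laLabels <- c(background = 0L, la = 1L, pv = 2L, mv = 3L, laa = 4L,
              fibrosis = 5L)

#' Volume: a 3D scalar image with grid metadata
#'
#' Container for a 3D intensity volume together with its voxel spacing (mm)
#' and the physical coordinate of voxel (1,1,1). All per-slice 2D operations
#' in the package iterate over the third (slice) axis.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), per-axis voxel size in mm (all > 0).
#' @slot origin numeric(3), physical coordinate of the first voxel.
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("Volume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (any(!is.finite(object@data)))
    return("data contains NaN/Inf values")
  TRUE
})

#' LabelMask: a 3D integer label image sharing a Volume's grid
#'
#' @slot data 3D integer array of label codes.
#' @slot labelMap named integer vector mapping label names to codes; every
#'   nonzero value present in \code{data} must appear here.
#' @slot spacing,origin grid metadata as in \linkS4class{Volume}.
#' @export
setClass("LabelMask",
  representation(data = "array", labelMap = "integer", spacing = "numeric",
                 origin = "numeric"),
  prototype(labelMap = laLabels, spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("LabelMask", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values")
  if (is.null(names(object@labelMap)) || any(names(object@labelMap) == ""))
    return("labelMap must be a named integer vector")
  vals <- unique(as.integer(object@data))
  unknown <- setdiff(vals[vals != 0L], object@labelMap)
  if (length(unknown))
    return(paste("labels not in labelMap:", paste(unknown, collapse = ", ")))
  TRUE
})

#' FDMap: per-voxel differential box-counting fractal dimension
#'
#' @slot data 3D numeric array of FD values; voxels outside the requested
#'   region carry the sentinel value recorded in \code{sentinel}.
#' @slot scaleMax maximum scaling factor R (voxels).
#' @slot rSet integer scales used, each strictly between 2 and R.
#' @slot boundary boundary policy used at image edges ("clip" or "reflect").
#' @slot sentinel value marking out-of-region voxels.
#' @export
setClass("FDMap",
  representation(data = "array", scaleMax = "numeric", rSet = "integer",
                 boundary = "character", sentinel = "numeric"),
  prototype(boundary = "clip", sentinel = NA_real_))

setValidity("FDMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  r <- object@rSet
  if (!length(r)) return("rSet must be nonempty")
  if (is.unsorted(r, strictly = TRUE)) return("rSet must be strictly increasing")
  if (any(r <= 2) || any(r >= object@scaleMax))
    return("all scales must satisfy 2 < r < R")
  TRUE
})

#' VoronoiPartition: nearest-seed assignment of a voxel domain
#'
#' @slot seeds integer matrix (n x 3) of seed voxel coordinates.
#' @slot cellOf 3D integer array; 0 for background, otherwise the index of
#'   the nearest seed (ties to the lowest seed index).
#' @slot adjacency 2-column integer matrix of seed-index pairs whose cells
#'   share a voxel face (each unordered pair listed once, i < j).
#' @export
setClass("VoronoiPartition",
  representation(seeds = "matrix", cellOf = "array", adjacency = "matrix"))

setValidity("VoronoiPartition", function(object) {
  if (ncol(object@seeds) != 3L) return("seeds must be an n x 3 matrix")
  if (length(dim(object@cellOf)) != 3L) return("cellOf must be a 3D array")
  adj <- object@adjacency
  if (nrow(adj) && ncol(adj) != 2L) return("adjacency must have 2 columns")
  if (nrow(adj) && any(adj[, 1] == adj[, 2])) return("self-adjacency present")
  TRUE
})

#' CellFeatures: shape and texture descriptors per Voronoi cell
#'
#' One row per cell; cells smaller than the configured minimum are flagged
#' unfeatured and carry NA features (they can never trigger truncation).
#'
#' @slot features data.frame with columns \code{cell}, \code{nVoxels},
#'   \code{fdMean}, \code{tortuosity}, \code{avgWidth}, \code{featured}.
#' @export
setClass("CellFeatures", representation(features = "data.frame"))

#' TortuosityResult: spine-based tortuosity of a binary shape
#'
#' @slot tortuosity ratio of spine length to endpoint distance (>= 1 up to
#'   discretization).
#' @slot spineLength arc length L of the longest spine path (physical units).
#' @slot endpointDistance straight-line distance D between spine endpoints.
#' @slot avgWidth mean shape width sampled along the spine.
#' @slot nBranches number of branches of the pruned skeleton.
#' @export
setClass("TortuosityResult",
  representation(tortuosity = "numeric", spineLength = "numeric",
                 endpointDistance = "numeric", avgWidth = "numeric",
                 nBranches = "integer"))

#' ClusterState: converged state of one fractal-penalized K-means fit
#'
#' @slot points numeric matrix (N x 3) of voxel coordinates in feature space
#'   (after coordinate scaling).
#' @slot fd per-point fractal dimension.
#' @slot assignments integer cluster index per point.
#' @slot centroids k x 3 centroid positions.
#' @slot centroidFD FD value attached to each centroid (FD of the nearest
#'   data point).
#' @slot clusterFDMean,clusterFDVar per-cluster FD statistics.
#' @slot iterations Lloyd iterations run.
#' @export
setClass("ClusterState",
  representation(points = "matrix", fd = "numeric", assignments = "integer",
                 centroids = "matrix", centroidFD = "numeric",
                 clusterFDMean = "numeric", clusterFDVar = "numeric",
                 iterations = "integer"))

setValidity("ClusterState", function(object) {
  n <- nrow(object@points)
  if (length(object@assignments) != n) return("one assignment per point required")
  k <- nrow(object@centroids)
  if (any(object@assignments < 1L) || any(object@assignments > k))
    return("assignments out of range")
  if (!all(seq_len(k) %in% object@assignments))
    return("empty cluster after convergence")
  TRUE
})

#' SegmentationReport: the full mask-comparison metric suite
#'
#' @slot dice,precision,recall overlap fractions in [0, 1].
#' @slot assd,mssd,hd,hd95 surface distances in physical units (mm).
#' @slot nPred,nTruth foreground voxel counts of the two masks.
#' @export
setClass("SegmentationReport",
  representation(dice = "numeric", precision = "numeric", recall = "numeric",
                 assd = "numeric", mssd = "numeric", hd = "numeric",
                 hd95 = "numeric", nPred = "integer", nTruth = "integer"))

#' PhantomSpec: parameters of the synthetic left-atrium phantom
#'
#' See \code{\link{phantomSpec}} for the constructor and the meaning and
#' defaults of each slot.
#'
#' @slot shape integer(3) grid size in voxels.
#' @slot poolRadius numeric(3) ellipsoid semi-axes of the blood pool (voxels).
#' @slot wallThickness wall thickness in voxels (integer >= 1).
#' @slot nPVBranches number of pulmonary-vein tubes.
#' @slot pvTortuosity target centerline tortuosity of each tube (>= 1).
#' @slot fibrosisFraction fraction of wall voxels planted as fibrosis, in (0,1).
#' @slot textureAmplitude intensity amplitude of the fibrosis texture.
#' @slot noiseSigma standard deviation of the global Gaussian noise.
#' @slot spacing voxel spacing passed to the generated volume.
#' @slot seed RNG seed; the generator owns one private RNG stream.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", poolRadius = "numeric",
                 wallThickness = "integer", nPVBranches = "integer",
                 pvTortuosity = "numeric", fibrosisFraction = "numeric",
                 textureAmplitude = "numeric", noiseSigma = "numeric",
                 spacing = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 8L))
    return("shape must be three dimensions >= 8")
  if (length(object@poolRadius) != 3L || any(object@poolRadius <= 0))
    return("poolRadius must be three positive semi-axes")
  if (object@wallThickness < 1L) return("wallThickness must be >= 1")
  if (object@nPVBranches < 0L) return("nPVBranches must be >= 0")
  if (object@pvTortuosity < 1) return("pvTortuosity must be >= 1")
  if (object@fibrosisFraction <= 0 || object@fibrosisFraction >= 1)
    return("fibrosisFraction must be in (0, 1)")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  # the pool plus wall plus a PV excursion must fit inside the grid
  margin <- object@shape / 2 - (object@poolRadius + object@wallThickness)
  if (any(margin < 1))
    return("pool plus wall does not fit inside the grid")
  TRUE
})

## ---- show methods ----

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume %d x %d x %d, spacing (%s) mm, intensity [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = ", "),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  tab <- table(factor(object@data, levels = object@labelMap,
                      labels = names(object@labelMap)))
  cat(sprintf("LabelMask %d x %d x %d\n", d[1], d[2], d[3]))
  print(tab)
})

setMethod("show", "FDMap", function(object) {
  v <- object@data[is.finite(object@data)]
  cat(sprintf("FDMap (R = %g, r = {%s}, boundary = %s): %d voxels, FD [%.2f, %.2f]\n",
              object@scaleMax, paste(object@rSet, collapse = ","),
              object@boundary, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "VoronoiPartition", function(object) {
  cat(sprintf("VoronoiPartition: %d seeds, %d assigned voxels, %d adjacent pairs\n",
              nrow(object@seeds), sum(object@cellOf > 0), nrow(object@adjacency)))
})

setMethod("show", "CellFeatures", function(object) {
  cat(sprintf("CellFeatures for %d cells (%d featured)\n",
              nrow(object@features), sum(object@features$featured)))
  print(head(object@features, 10))
})

setMethod("show", "TortuosityResult", function(object) {
  cat(sprintf("Tortuosity %.3f (L = %.2f, D = %.2f), avg width %.2f, %d branches\n",
              object@tortuosity, object@spineLength, object@endpointDistance,
              object@avgWidth, object@nBranches))
})

setMethod("show", "ClusterState", function(object) {
  cat(sprintf("ClusterState: %d points, %d clusters, %d iterations\n",
              nrow(object@points), nrow(object@centroids), object@iterations))
  cat("cluster FD means:", paste(round(object@clusterFDMean, 3), collapse = " "), "\n")
})

setMethod("show", "SegmentationReport", function(object) {
  cat(sprintf(
    "SegmentationReport: Dice %.3f  precision %.3f  recall %.3f\n",
    object@dice, object@precision, object@recall))
  cat(sprintf("  ASSD %.3f  MSSD %.3f  HD %.3f  HD95 %.3f (physical units)\n",
              object@assd, object@mssd, object@hd, object@hd95))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s, pool (%s), wall %d, %d PVs (tortuosity >= %.2f)\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@poolRadius), collapse = ", "),
              object@wallThickness, object@nPVBranches, object@pvTortuosity))
  cat(sprintf("  fibrosis %.0f%% of wall, texture amplitude %g, noise sd %g, seed %d\n",
              100 * object@fibrosisFraction, object@textureAmplitude,
              object@noiseSigma, object@seed))
})

## ---- accessors ----

#' Grid accessors
#'
#' @param x a \linkS4class{Volume}, \linkS4class{LabelMask} or
#'   \linkS4class{FDMap}.
#' @return \code{voxelData} returns the raw array, \code{voxelSpacing} the
#'   per-axis spacing, \code{voxelOrigin} the physical origin and
#'   \code{labelMap} the label table of a mask.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname voxelData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname voxelData
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname voxelData
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname voxelData
setMethod("voxelData", "Volume", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "LabelMask", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "FDMap", function(x) x@data)
#' @rdname voxelData
setMethod("voxelSpacing", "Volume", function(x) x@spacing)
#' @rdname voxelData
setMethod("voxelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname voxelData
setMethod("voxelOrigin", "Volume", function(x) x@origin)
#' @rdname voxelData
setMethod("voxelOrigin", "LabelMask", function(x) x@origin)
#' @rdname voxelData
setMethod("labelMap", "LabelMask", function(x) x@labelMap)

#' Construct a Volume
#'
#' @param data 3D numeric array.
#' @param spacing per-axis voxel size in mm.
#' @param origin physical coordinate of the first voxel.
#' @return A \linkS4class{Volume}.
#' @export
newVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume", data = array(as.numeric(data), dim(data)),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Construct a LabelMask
#'
#' @param data 3D integer array of label codes.
#' @param labelMap named integer vector of label codes; defaults to
#'   \code{\link{laLabels}}.
#' @param spacing,origin grid metadata.
#' @return A \linkS4class{LabelMask}.
#' @export
newLabelMask <- function(data, labelMap = laLabels, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  storage.mode(labelMap) <- "integer"
  new("LabelMask", data = array(as.integer(data), dim(data)),
      labelMap = labelMap, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Extract a named label as a logical mask
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param labels character names (or integer codes) of the labels to select.
#' @return logical 3D array.
#' @export
maskLabel <- function(mask, labels) {
  codes <- if (is.character(labels)) mask@labelMap[labels] else as.integer(labels)
  if (any(is.na(codes))) stop("unknown label name")
  array(mask@data %in% codes, dim(mask@data))
}
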
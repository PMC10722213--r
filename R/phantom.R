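#' Specify a synthetic left-atrium phantom
#'
#' The phantom emulates the anatomy the segmentation pipeline expects: an
#' ellipsoidal blood pool wrapped in a thin wall, snake-like pulmonary-vein
#' tubes attached to the outside of the wall, smooth mitral-valve and
#' appendage bulges contiguous with the pool, and a contiguous patch of
#' wall voxels carrying high-spatial-frequency texture (fibrosis).
#' Intensity contrasts between compartments are deliberately mild (about
#' 2-3 intensity units on a background of ~50) so that the box-counting
#' fractal dimension responds to the planted texture rather than to
#' compartment edges; the fibrosis texture is two-level (thresholded
#' band-pass noise), which gives it a near-constant local intensity range
#' and hence a tight FD plateau well above the smooth wall.
#'
#' @param shape grid size in voxels (default 96 x 96 x 24).
#' @param poolRadius ellipsoid semi-axes of the blood pool in voxels.
#' @param wallThickness wall thickness in voxels.
#' @param nPVBranches number of pulmonary-vein tubes (default 3).
#' @param pvTortuosity target centerline tortuosity of each tube; the
#'   generator builds helical tubes with ~20\% analytic margin so that the
#'   measured tortuosity meets the target despite discretization.
#' @param fibrosisFraction fraction of wall voxels planted as fibrosis.
#' @param textureAmplitude amplitude of the two-level fibrosis texture.
#' @param noiseSigma standard deviation of global Gaussian noise.
#' @param spacing voxel spacing of the generated volume.
#' @param seed RNG seed for the phantom's private random stream.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(96, 96, 24),
                        poolRadius = c(24, 19, 7),
                        wallThickness = 3,
                        nPVBranches = 3,
                        pvTortuosity = 2.0,
                        fibrosisFraction = 0.2,
                        textureAmplitude = 10,
                        noiseSigma = 0.25,
                        spacing = c(1, 1, 1),
                        seed = 1) {
  new("PhantomSpec", shape = as.integer(shape),
      poolRadius = as.numeric(poolRadius),
      wallThickness = as.integer(wallThickness),
      nPVBranches = as.integer(nPVBranches),
      pvTortuosity = as.numeric(pvTortuosity),
      fibrosisFraction = as.numeric(fibrosisFraction),
      textureAmplitude = as.numeric(textureAmplitude),
      noiseSigma = as.numeric(noiseSigma),
      spacing = as.numeric(spacing),
      seed = as.integer(seed))
}

# Compartment intensities; mild contrasts by design (see phantomSpec).
phantomIntensities <- c(background = 49, pool = 50.5, wall = 52.5,
                        structure = 52.5)

#' Generate a phantom volume and its ground-truth label mask
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with elements \code{volume} (\linkS4class{Volume}) and
#'   \code{mask} (\linkS4class{LabelMask} with labels background/la/pv/mv/
#'   laa/fibrosis; \code{la} covers pool + healthy wall, fibrosis voxels
#'   are wall voxels relabelled \code{fibrosis}).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withSeed(spec@seed, generatePhantomImpl(spec))
}

generatePhantomImpl <- function(spec) {
  dm <- spec@shape
  ctr <- (dm + 1) / 2
  ax <- spec@poolRadius
  wt <- spec@wallThickness
  ints <- phantomIntensities

  ix <- array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm)
  iy <- array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm)
  iz <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  rho <- function(a) sqrt(((ix - ctr[1]) / a[1])^2 + ((iy - ctr[2]) / a[2])^2 +
                          ((iz - ctr[3]) / a[3])^2)
  pool <- rho(ax) <= 1
  wall <- rho(ax + wt) <= 1 & !pool

  lab <- array(0L, dm)
  lab[pool] <- laLabels[["la"]]
  lab[wall] <- laLabels[["la"]]

  # fibrosis: the contiguous angular cap of wall voxels around +y covering
  # the requested fraction (exact count by construction)
  wv <- which(wall, arr.ind = TRUE)
  dirs <- sweep(sweep(wv, 2, ctr), 2, ax + wt / 2, "/")
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ang <- acos(pmin(pmax(dirs[, 2], -1), 1))
  nf <- round(spec@fibrosisFraction * nrow(wv))
  fib <- array(FALSE, dm)
  fib[wv[order(ang)[seq_len(nf)], , drop = FALSE]] <- TRUE
  lab[fib] <- laLabels[["fibrosis"]]

  # pulmonary veins: helical tubes attached to the outer wall, axes spread
  # around the xy plane away from the fibrotic cap at +y
  structureMask <- function() array(FALSE, dm)
  pv <- structureMask()
  if (spec@nPVBranches > 0) {
    angles <- (190 + 150 * (seq_len(spec@nPVBranches) - 1) /
                 max(1, spec@nPVBranches - 1)) * pi / 180
    for (i in seq_len(spec@nPVBranches)) {
      d3 <- c(cos(angles[i]), sin(angles[i]), 0.1)
      d3 <- d3 / sqrt(sum(d3^2))
      pv <- pv | helixTube(dm, ctr, ax + wt, d3, spec@pvTortuosity)
    }
    pv <- pv & lab == 0L
    lab[pv] <- laLabels[["pv"]]
  }

  # mitral valve: smooth bulge outside the wall at the -x pole
  mv <- bulge(dm, rho, ix, iy, iz, ctr, ax, wt, dir = c(-1, 0, 0),
              semi = c(6, 7, 5), push = 2)
  mv <- mv & lab == 0L
  lab[mv] <- laLabels[["mv"]]

  # appendage: smaller smooth lobe
  laa <- bulge(dm, rho, ix, iy, iz, ctr, ax, wt,
               dir = c(0.55, -0.78, 0.3), semi = c(4, 5, 3), push = 1.5)
  laa <- laa & lab == 0L
  lab[laa] <- laLabels[["laa"]]

  vol <- array(ints[["background"]], dm)
  vol[pool] <- ints[["pool"]]
  vol[wall] <- ints[["wall"]]
  vol[pv | mv | laa] <- ints[["structure"]]

  # two-level (thresholded band-pass) fibrosis texture
  if (nf > 0) {
    wn <- array(rnorm(prod(dm)), dm)
    tex <- gaussBlur(wn, 0.5) - gaussBlur(wn, 1.2)
    vol[fib] <- ints[["wall"]] + spec@textureAmplitude * sign(tex[fib])
  }
  if (spec@noiseSigma > 0)
    vol <- vol + array(rnorm(prod(dm), 0, spec@noiseSigma), dm)

  list(volume = newVolume(vol, spec@spacing),
       mask = newLabelMask(lab, laLabels, spec@spacing))
}

# Voxels within `tubeRadius` of a helical centerline starting on the outer
# wall surface along direction `d3`. The helix is built with an integer
# number of turns so its analytic tortuosity has the closed form
# sqrt(1 + (2*pi*turns*A/H)^2); A is solved for the target with a 10%
# margin to absorb the low bias of discrete centerline measurement.
helixTube <- function(dm, ctr, axOuter, d3, targetTort,
                      height = 11, turns = 1, tubeRadius = 1.8) {
  s <- 1 / sqrt(sum((d3 / axOuter)^2))        # ellipsoid surface distance
  p0 <- ctr + (s - 0.5) * d3
  design <- targetTort * 1.2
  A <- height * sqrt(design^2 - 1) / (2 * pi * turns)
  e1 <- c(-d3[2], d3[1], 0)
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d3[2] * e1[3] - d3[3] * e1[2],
          d3[3] * e1[1] - d3[1] * e1[3],
          d3[1] * e1[2] - d3[2] * e1[1])
  tt <- seq(0, 1, length.out = 300)
  phase <- 2 * pi * turns * tt
  cl <- t(p0 + outer(d3, height * tt) +
            outer(e1, A * (cos(phase) - 1)) + outer(e2, A * sin(phase)))
  out <- array(FALSE, dm)
  r2 <- tubeRadius^2
  for (i in seq_len(nrow(cl))) {
    p <- cl[i, ]
    xs <- max(1, floor(p[1] - tubeRadius)):min(dm[1], ceiling(p[1] + tubeRadius))
    ys <- max(1, floor(p[2] - tubeRadius)):min(dm[2], ceiling(p[2] + tubeRadius))
    zs <- max(1, floor(p[3] - tubeRadius)):min(dm[3], ceiling(p[3] + tubeRadius))
    for (x in xs) for (y in ys) for (z in zs)
      if ((x - p[1])^2 + (y - p[2])^2 + (z - p[3])^2 <= r2)
        out[x, y, z] <- TRUE
  }
  out
}

# Smooth ellipsoidal bulge contiguous with the pool, planted just outside
# the outer wall surface along `dir`.
bulge <- function(dm, rho, ix, iy, iz, ctr, ax, wt, dir, semi, push) {
  dir <- dir / sqrt(sum(dir^2))
  s <- 1 / sqrt(sum((dir / (ax + wt))^2))
  c0 <- ctr + (s + push) * dir
  b <- sqrt(((ix - c0[1]) / semi[1])^2 + ((iy - c0[2]) / semi[2])^2 +
            ((iz - c0[3]) / semi[3])^2) <= 1
  b & rho(ax + wt) > 1
}

#' Write a canonical suite of phantom fixtures
#'
#' Generates a small deterministic set of phantoms (two grid sizes, two
#' fibrosis fractions, fixed seeds), writes each volume and mask as NIfTI,
#' and records a JSON manifest with an md5 checksum per file. Re-running
#' restores any deleted file and reproduces identical checksums.
#'
#' @param outDir output directory (created if needed).
#' @return The manifest as a data.frame, invisibly; also written to
#'   \code{manifest.json}.
#' @export
fixtureSuite <- function(outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0) stop("directory not writable: ", outDir)
  cases <- expand.grid(size = c("small", "large"),
                       fibrosis = c(0.15, 0.25), stringsAsFactors = FALSE)
  files <- character(0)
  for (i in seq_len(nrow(cases))) {
    shape <- if (cases$size[i] == "small") c(48, 48, 16) else c(96, 96, 24)
    poolR <- if (cases$size[i] == "small") c(11, 9, 4.5) else c(24, 19, 7)
    nPV <- if (cases$size[i] == "small") 0L else 3L
    wt <- if (cases$size[i] == "small") 2L else 3L
    spec <- phantomSpec(shape = shape, poolRadius = poolR, wallThickness = wt,
                        nPVBranches = nPV,
                        fibrosisFraction = cases$fibrosis[i],
                        seed = 100 + i)
    ph <- generatePhantom(spec)
    base <- sprintf("phantom_%s_f%02d", cases$size[i],
                    round(100 * cases$fibrosis[i]))
    vf <- file.path(outDir, paste0(base, "_vol.nii"))
    mf <- file.path(outDir, paste0(base, "_mask.nii"))
    writeVolume(ph$volume, vf)
    writeLabelMask(ph$mask, mf)
    files <- c(files, vf, mf, paste0(mf, ".labels.json"))
  }
  manifest <- data.frame(file = basename(files),
                         md5 = vapply(files, function(f)
                           as.character(tools::md5sum(f)), character(1)),
                         row.names = NULL)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
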
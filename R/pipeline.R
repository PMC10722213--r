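#' Run the full clipping + clustering + evaluation pipeline
#'
#' Either generates a phantom (when \code{config$phantom} is given) or
#' reads the input volume and LA mask from disk, clips the anatomical
#' structures (unless a precomputed clipped mask is supplied via
#' \code{config$clippedPath} or \code{config$skipClip} is TRUE, the
#' "manual clipping" regime), segments fibrosis, evaluates against ground
#' truth when available, and writes masks, a JSON report and a provenance
#' file into \code{outDir}.
#'
#' @param config a list with entries: either \code{phantom} (a
#'   \linkS4class{PhantomSpec}) or \code{volumePath} + \code{laPath};
#'   optional \code{truthPath}, \code{clippedPath}, \code{skipClip},
#'   \code{clip} (a \code{\link{clipConfig}}), \code{cluster} (a
#'   \code{\link{clusterConfig}}), \code{fdR} (scaling factor for the FD
#'   map, default 7) and \code{seed}.
#' @param outDir output directory.
#' @return A list with \code{fibrosis}, \code{clipped}, \code{report}
#'   (NULL without truth), \code{history} and the output paths, invisibly.
#' @export
runFull <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  clipCfg <- if (!is.null(config$clip)) config$clip else clipConfig()
  clusCfg <- if (!is.null(config$cluster)) config$cluster else clusterConfig()
  clusCfg$seed <- seed
  fdR <- if (!is.null(config$fdR)) config$fdR else 7

  truth <- NULL
  if (!is.null(config$phantom)) {
    spec <- config$phantom
    spec@seed <- seed
    ph <- generatePhantom(spec)
    volume <- ph$volume
    laMask <- ph$mask
    truth <- maskLabel(ph$mask, "fibrosis")
  } else {
    if (is.null(config$volumePath) || is.null(config$laPath))
      stop("config needs either a phantom spec or volumePath + laPath")
    volume <- readVolume(config$volumePath)
    laMask <- readLabelMask(config$laPath)
    if (!is.null(config$truthPath))
      truth <- voxelData(readLabelMask(config$truthPath)) != 0
  }

  la <- if (is(laMask, "LabelMask")) maskLabel(laMask, c("la", "fibrosis"))
        else laMask != 0
  # reduce the LA region (pool + wall) to its wall shell
  depth <- if (!is.null(config$wallDepth)) config$wallDepth
           else if (!is.null(config$phantom)) config$phantom@wallThickness
           else 3L
  wall <- la & !erodeK(la, depth)

  if (!is.null(config$clippedPath)) {
    clipped <- voxelData(readLabelMask(config$clippedPath)) != 0
  } else if (isTRUE(config$skipClip)) {
    clipped <- wall
  } else {
    clip <- clipPipeline(volume, laMask, clipCfg)
    clipped <- clip$clipped & wall
  }

  fdm <- fdMap(volume, R = fdR, region = clipped)
  seg <- segmentFibrosis(volume, clipped, fdm, clusCfg)

  report <- NULL
  if (!is.null(truth))
    report <- evaluateSegmentation(seg$mask, truth, voxelSpacing(volume))

  sp <- voxelSpacing(volume)
  fibPath <- file.path(outDir, "fibrosis.nii")
  clipPath <- file.path(outDir, "clipped.nii")
  writeLabelMask(newLabelMask(array(as.integer(seg$mask), dim(seg$mask)),
                              c(background = 0L, fibrosis = 1L), sp), fibPath)
  writeLabelMask(newLabelMask(array(as.integer(clipped), dim(clipped)),
                              c(background = 0L, la = 1L), sp), clipPath)
  if (!is.null(report)) {
    jsonlite::write_json(list(
      dice = report@dice, precision = report@precision,
      recall = report@recall, assd = report@assd, mssd = report@mssd,
      hd = report@hd, hd95 = report@hd95), file.path(outDir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  prov <- list(seed = seed,
               clip = clipCfg, cluster = clusCfg, fdR = fdR,
               packageVersion = as.character(utils::packageVersion("fkmeans")),
               rVersion = R.version.string,
               history = seg$history, stopReasons = seg$stopReasons)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(fibrosis = seg$mask, clipped = clipped, report = report,
                 history = seg$history, paths = c(fibrosis = fibPath,
                                                  clipped = clipPath)))
}

erodeK <- function(mask, k) {
  for (i in seq_len(k)) mask <- erodeOnce(mask)
  mask
}

# One face-connected erosion; used to reduce the LA region to its wall
# shell (interior pool voxels have all six neighbours inside).
erodeOnce <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  inner <- mask
  shift <- function(m, ax, s) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len); src <- idx
    if (s == 1) { idx[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { idx[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (s in c(1, -1)) inner <- inner & shift(mask, ax, s)
  inner
}

#' Dice score over a parameter grid
#'
#' Re-runs the fibrosis segmentation of a phantom for every combination of
#' the stopping thresholds and the FD scaling factor and records the Dice
#' score against the planted fibrosis (ground-truth clipping regime).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param tau1,tau2,R numeric vectors defining the grid.
#' @param config base \code{\link{clusterConfig}}.
#' @param csvPath optional path for a CSV copy of the results.
#' @return data.frame with columns tau1, tau2, R, dice.
#' @export
parameterSweep <- function(spec, tau1 = 0.1, tau2 = 0.05, R = 7,
                           config = clusterConfig(), csvPath = NULL) {
  grid <- expand.grid(tau1 = tau1, tau2 = tau2, R = R)
  if (!nrow(grid)) stop("empty parameter grid")
  ph <- generatePhantom(spec)
  truth <- maskLabel(ph$mask, "fibrosis")
  la <- maskLabel(ph$mask, c("la", "fibrosis"))
  wall <- la & !erodeK(la, spec@wallThickness)
  dice <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$tau1 <- grid$tau1[i]
    cfg$tau2 <- grid$tau2[i]
    fdm <- fdMap(ph$volume, R = grid$R[i], region = wall)
    seg <- segmentFibrosis(ph$volume, wall, fdm, cfg)
    dice[i] <- diceScore(seg$mask, truth)
  }
  out <- cbind(grid, dice = dice)
  if (!is.null(csvPath)) write.csv(out, csvPath, row.names = FALSE)
  out
}
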
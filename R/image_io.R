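#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (\code{.nii}, \code{.nii.gz}) via \pkg{RNifti} and
#' MetaImage (\code{.mha}, \code{.mhd} + \code{.raw}). Intensities are
#' promoted to double; spacing is taken from the stored affine/header and
#' the origin from its translation column.
#'
#' @param path file path.
#' @return A \linkS4class{Volume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- fileFormat(path)
  raw <- switch(ext,
    nifti = readNiftiRaw(path),
    meta  = readMetaImage(path),
    stop("unsupported format (expect .nii/.nii.gz/.mha/.mhd): ", path))
  if (any(!is.finite(raw$data)))
    stop("volume contains NaN/Inf values: ", path)
  newVolume(raw$data, raw$spacing, raw$origin)
}

#' Write a 3D volume
#'
#' @param volume a \linkS4class{Volume}.
#' @param path destination; format chosen by extension as in
#'   \code{\link{readVolume}}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume"))
  switch(fileFormat(path),
    nifti = writeNiftiRaw(volume@data, volume@spacing, volume@origin, path),
    meta  = writeMetaImage(volume@data, volume@spacing, volume@origin, path,
                           type = "MET_DOUBLE"),
    stop("unsupported format: ", path))
  invisible(path)
}

#' Read a label mask (with its JSON label-map sidecar if present)
#'
#' The label map is stored next to the image as \code{<path>.labels.json}
#' (a \code{name: integer} object). Without a sidecar the default
#' \code{\link{laLabels}} table is used.
#'
#' @param path file path of the mask image.
#' @return A \linkS4class{LabelMask} with bit-exact integer data.
#' @export
readLabelMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(fileFormat(path),
    nifti = readNiftiRaw(path),
    meta  = readMetaImage(path),
    stop("unsupported format: ", path))
  if (any(!is.finite(raw$data))) stop("mask contains NaN/Inf values: ", path)
  if (max(abs(raw$data - round(raw$data))) > 0)
    stop("mask contains non-integer values: ", path)
  side <- paste0(path, ".labels.json")
  lm <- if (file.exists(side)) {
    v <- jsonlite::read_json(side, simplifyVector = TRUE)
    setNames(as.integer(v), names(v))
  } else laLabels
  newLabelMask(round(raw$data), lm, raw$spacing, raw$origin)
}

#' Write a label mask and its label-map sidecar
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path destination path (format by extension).
#' @return \code{path}, invisibly.
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  validObject(mask)
  switch(fileFormat(path),
    nifti = writeNiftiRaw(mask@data, mask@spacing, mask@origin, path),
    meta  = writeMetaImage(mask@data, mask@spacing, mask@origin, path,
                           type = "MET_INT"),
    stop("unsupported format: ", path))
  jsonlite::write_json(as.list(mask@labelMap), paste0(path, ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

## ---- internals ----

fileFormat <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("meta")
  "unknown"
}

readNiftiRaw <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  a <- as.array(img)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3L) stop("expected a 3D volume: ", path)
  m <- try(RNifti::xform(img), silent = TRUE)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  if (!inherits(m, "try-error") && is.matrix(m) && all(dim(m) == c(4, 4))) {
    sp <- sqrt(colSums(m[1:3, 1:3]^2))
    if (all(sp > 0)) spacing <- sp
    origin <- m[1:3, 4]
  }
  list(data = array(as.double(a), dim(a)), spacing = abs(spacing),
       origin = origin)
}

writeNiftiRaw <- function(data, spacing, origin, path) {
  img <- RNifti::asNifti(array(as.double(data), dim(data)))
  m <- diag(4)
  diag(m)[1:3] <- spacing
  m[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
}

metaTypes <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
metaSizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

# Minimal MetaImage (ITK .mha/.mhd) reader: ASCII header, uncompressed
# little-endian raw data, either appended (ElementDataFile = LOCAL) or in a
# companion .raw file.
readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list(); dataFile <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("unreadable MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { dataFile <- val; break }
  }
  need <- c("NDims", "DimSize", "ElementType")
  if (!all(need %in% names(hdr)))
    stop("MetaImage header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (as.integer(hdr$NDims) != 3L) stop("expected NDims = 3: ", path)
  if (identical(hdr[["CompressedData"]], "True"))
    stop("compressed MetaImage not supported: ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  if (!type %in% names(metaTypes)) stop("unsupported ElementType: ", type)
  n <- prod(dims)
  if (identical(dataFile, "LOCAL")) {
    vals <- readBin(con, what = metaTypes[[type]], n = n,
                    size = metaSizes[[type]], endian = "little",
                    signed = !(type %in% c("MET_UCHAR", "MET_USHORT")))
  } else {
    rawPath <- file.path(dirname(path), dataFile)
    if (!file.exists(rawPath)) stop("MetaImage data file not found: ", rawPath)
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, what = metaTypes[[type]], n = n,
                    size = metaSizes[[type]], endian = "little",
                    signed = !(type %in% c("MET_UCHAR", "MET_USHORT")))
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path)
  list(data = array(as.double(vals), dims), spacing = spacing, origin = origin)
}

writeMetaImage <- function(data, spacing, origin, path, type = "MET_DOUBLE") {
  dims <- dim(data)
  local <- grepl("\\.mha$", tolower(path))
  dataFile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(format(spacing, trim = TRUE), collapse = " ")),
    paste("Offset =", paste(format(origin, trim = TRUE), collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", dataFile))
  vals <- as.vector(data)
  writeBinVals <- function(con) {
    if (metaTypes[[type]] == "integer")
      writeBin(as.integer(round(vals)), con, size = metaSizes[[type]],
               endian = "little")
    else
      writeBin(as.double(vals), con, size = metaSizes[[type]],
               endian = "little")
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write: ", path))
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (local) {
    writeBinVals(con)
  } else {
    rcon <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBinVals(rcon)
  }
  invisible(path)
}
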
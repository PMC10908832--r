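## NIfTI-1 I/O: read/write volumes, split into slices, reassemble.
## All heavy lifting is delegated to RNifti; the calibration fields are
## patched in-place after writing because RNifti recomputes them from the
## data (the codec needs them to carry the *original* volume's range).

#' Read a 3-D NIfTI-1 volume
#'
#' Opens a \code{.nii} or \code{.nii.gz} file as a \code{\link{VolumeImage}}.
#' Only 3-D volumes are supported; 4-D acquisitions with singleton trailing
#' dimensions are squeezed, genuine 4-D files are rejected. Float-typed
#' inputs are accepted with a warning (the codec expects integer samples).
#'
#' @param path Path to a NIfTI-1 file.
#' @return A \code{VolumeImage}; header fields (affine, voxel spacing,
#'   cal_min/cal_max, descrip) are preserved verbatim.
#' @seealso \code{\link{writeVolume}}, \code{\link{planSlices}}
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  hdr <- RNifti::niftiHeader(path)
  nd <- hdr$dim[1]
  dims <- hdr$dim[seq(2, 1 + nd)]
  if (nd > 3) {
    if (all(dims[-(1:3)] == 1L))
      dims <- dims[1:3]
    else
      stop("only 3-D volumes supported (file is ", nd, "-D)")
  }
  if (nd < 3)
    stop("only 3-D volumes supported (file is ", nd, "-D)")
  dtype <- .DTYPE_TABLE$name[match(hdr$datatype, .DTYPE_TABLE$code)]
  if (is.na(dtype))
    stop("unsupported NIfTI datatype code ", hdr$datatype)
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim = dims)
  if (!dtypeInfo(dtype)$integer)
    warning("float-typed volume: the codec expects integer samples")
  header <- list(affine  = matrix(RNifti::xform(img), 4, 4),
                 pixdim  = as.numeric(RNifti::pixdim(img))[1:3],
                 cal_min = hdr$cal_min,
                 cal_max = hdr$cal_max,
                 descrip = hdr$descrip,
                 sidecar = .readSidecar(path, hdr$descrip))
  VolumeImage(dat, dtype, header)
}

#' Write a VolumeImage as NIfTI-1
#'
#' Writes \code{.nii} or gzip-compressed \code{.nii.gz} according to the
#' file extension, storing samples in the volume's own dtype and
#' preserving affine, voxel spacing, cal_min/cal_max and descrip. If the
#' volume carries codec metadata that does not fit the 80-character
#' descrip field, a JSON sidecar \code{<path>.json} is written.
#'
#' @param vol A \code{VolumeImage}.
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path) {
  validObject(vol)
  info <- dtypeInfo(vol@dtype)
  dat <- vol@data
  if (info$integer && info$max <= .Machine$integer.max)
    storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol@header$pixdim
  RNifti::sform(img) <- structure(vol@header$affine, code = 2L)
  img$descrip <- vol@header$descrip
  RNifti::writeNifti(img, path, datatype = vol@dtype)
  .pokeCalibration(path, vol@header$cal_min, vol@header$cal_max)
  if (!is.null(vol@header$sidecar))
    jsonlite::write_json(vol@header$sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Overwrite cal_max (byte offset 124) and cal_min (offset 128) of a
## written NIfTI-1 file; handles gzip containers and byte order.
.pokeCalibration <- function(path, cal_min, cal_max) {
  gz <- grepl("\\.gz$", path)
  con <- if (gz) gzfile(path, "rb") else file(path, "rb")
  raw <- raw()
  repeat {
    chunk <- readBin(con, "raw", n = 4194304L)
    if (!length(chunk)) break
    raw <- c(raw, chunk)
  }
  close(con)
  endian <- if (identical(readBin(raw[1:4], "integer", endian = "little"),
                          348L)) "little" else "big"
  raw[125:132] <- writeBin(c(cal_max, cal_min), raw(), size = 4,
                           endian = endian)
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  writeBin(raw, con)
  close(con)
  invisible(NULL)
}

.readSidecar <- function(path, descrip) {
  sc <- paste0(path, ".json")
  if (grepl("sidecar=1", descrip, fixed = TRUE) && file.exists(sc))
    jsonlite::read_json(sc, simplifyVector = TRUE)
  else
    NULL
}

#' Split a volume into ordered slice images
#'
#' Returns the \code{S} planes of the volume along the third array axis,
#' in ascending (0-based) index order. \code{assembleVolume} is its exact
#' inverse.
#'
#' @param vol A \code{VolumeImage}.
#' @return A list of \code{m x n} numeric matrices.
#' @examples
#' v <- VolumeImage(array(1:8, dim = c(2, 2, 2)), "uint16")
#' length(planSlices(v))  # 2
#' @export
planSlices <- function(vol) {
  S <- numSlices(vol)
  lapply(seq_len(S), function(k) vol@data[, , k])
}

#' Assemble slice images into a volume
#'
#' Stacks equal-shape slices along the third axis. The header is copied
#' as given; the slice-axis extent follows the slice count.
#'
#' @param slices Non-empty list of \code{m x n} numeric matrices.
#' @param dtype Sample-type name of the result.
#' @param header Optional header list (as in \code{\link{VolumeImage}}).
#' @return A \code{VolumeImage} with \code{S = length(slices)}.
#' @export
assembleVolume <- function(slices, dtype = "uint16", header = NULL) {
  if (!length(slices))
    stop("empty slice sequence")
  shp <- dim(slices[[1L]])
  ok <- vapply(slices, function(s)
    is.matrix(s) && identical(dim(s), shp), logical(1))
  if (!all(ok))
    stop("slices differ in shape")
  arr <- array(unlist(slices, use.names = FALSE),
               dim = c(shp, length(slices)))
  VolumeImage(arr, dtype, header)
}
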
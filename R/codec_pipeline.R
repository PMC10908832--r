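## Volume-level downsampling/upsampling: pair consecutive slices, embed
## the odd slice into the even one, record codec parameters in the
## header so upsampling is blind.

.encodeMeta <- function(meta) {
  sprintf("QH1 S=%d beta=%d range=%s parity=%d lo=%s hi=%s",
          meta$S, meta$beta, meta$range, meta$parity,
          format(meta$lo, digits = 10, scientific = FALSE),
          format(meta$hi, digits = 10, scientific = FALSE))
}

.parseMeta <- function(descrip) {
  if (!grepl("^QH1 ", descrip))
    return(NULL)
  if (grepl("sidecar=1", descrip, fixed = TRUE))
    return("sidecar")
  grab <- function(key, conv = as.numeric) {
    m <- regmatches(descrip,
                    regexpr(paste0(key, "=[^ ]+"), descrip))
    if (!length(m)) return(NULL)
    conv(sub(paste0(key, "="), "", m))
  }
  list(S = grab("S", as.integer), beta = grab("beta", as.integer),
       range = grab("range", identity), parity = grab("parity", as.integer),
       lo = grab("lo"), hi = grab("hi"))
}

#' Halve a volume's slice count by quantization hiding
#'
#' Slices are paired (0,1), (2,3), ...; each pair is replaced by one
#' stego slice in which the odd (message) slice is embedded into the
#' even (cover) slice's DCT detail coefficients
#' (\code{\link{embedSlice}}). An odd trailing slice passes through
#' unchanged and is flagged. The output header records the codec
#' parameters (beta, range mode, original slice count, parity) in the
#' descrip field, the volume-wide intensity extrema in
#' cal_min/cal_max, and doubles the slice-axis voxel spacing so the file
#' stays geometrically sensible.
#'
#' @param vol A \code{VolumeImage} with integer samples, \code{S >= 2}
#'   and in-plane dimensions \code{>= 4}.
#' @param cfg A \code{\link{codecConfig}}.
#' @return A \code{VolumeImage} with \code{floor(S/2) + (S mod 2)} slices.
#' @seealso \code{\link{upsampleVolume}}
#' @export
downsampleVolume <- function(vol, cfg = codecConfig()) {
  validObject(vol)
  validObject(cfg)
  if (!dtypeInfo(vol@dtype)$integer)
    stop("float-typed volume: convert to an integer dtype first")
  dat <- vol@data
  if (cfg@sliceAxis != 3L)
    dat <- aperm(dat, .axisPerm(cfg@sliceAxis))
  d <- dim(dat)
  if (d[3L] < 2L)
    stop("need at least 2 slices")
  if (d[1L] < 4L || d[2L] < 4L)
    stop("in-plane dimensions must be at least 4x4")
  S <- d[3L]
  parity <- S %% 2L
  vr <- range(dat)
  rng <- if (cfg@rangeMode == "volume") vr else NULL
  nPairs <- S %/% 2L
  out <- array(0, dim = c(d[1L], d[2L], nPairs + parity))
  for (k in seq_len(nPairs))
    out[, , k] <- embedSlice(dat[, , 2L * k - 1L], dat[, , 2L * k],
                             beta = cfg@beta, range = rng,
                             dtype = vol@dtype, clampEps = cfg@clampEps)
  if (parity)
    out[, , nPairs + 1L] <- dat[, , S]
  if (cfg@sliceAxis != 3L)
    out <- aperm(out, order(.axisPerm(cfg@sliceAxis)))
  meta <- list(S = S, beta = as.integer(cfg@beta), range = cfg@rangeMode,
               parity = parity, lo = vr[1], hi = vr[2])
  header <- vol@header
  desc <- .encodeMeta(meta)
  if (nchar(desc) > 79L) {
    header$descrip <- "QH1 sidecar=1"
    header$sidecar <- meta
  } else {
    header$descrip <- desc
    header$sidecar <- NULL
  }
  header$cal_min <- vr[1]
  header$cal_max <- vr[2]
  header$pixdim[cfg@sliceAxis] <- header$pixdim[cfg@sliceAxis] * 2
  VolumeImage(out, vol@dtype, header)
}

.axisPerm <- function(axis) switch(axis, c(3L, 2L, 1L), c(1L, 3L, 2L),
                                   c(1L, 2L, 3L))

#' Reconstruct the full volume from a stego volume
#'
#' The inverse of \code{\link{downsampleVolume}}: each stego slice k
#' yields output slice 2k (the stego slice itself, standing in for the
#' original even slice) and output slice 2k+1, blindly extracted with
#' \code{\link{extractSlice}}. Codec parameters are read from the header
#' metadata written at downsampling; \code{cfg} overrides them when the
#' metadata is absent.
#'
#' @param stegoVol A \code{VolumeImage} produced by
#'   \code{downsampleVolume} (possibly after a write/read roundtrip).
#' @param cfg Optional \code{\link{codecConfig}} used when the header
#'   carries no codec metadata (beta is then mandatory).
#' @return A \code{VolumeImage} with the original slice count.
#' @export
upsampleVolume <- function(stegoVol, cfg = NULL) {
  validObject(stegoVol)
  meta <- .parseMeta(stegoVol@header$descrip)
  if (identical(meta, "sidecar"))
    meta <- stegoVol@header$sidecar
  sliceAxis <- if (is.null(cfg)) 3L else cfg@sliceAxis
  if (is.null(meta)) {
    if (is.null(cfg))
      stop("no codec metadata in header and no config supplied")
    meta <- list(S = NULL, beta = as.integer(cfg@beta),
                 range = cfg@rangeMode, parity = 0L,
                 lo = stegoVol@header$cal_min, hi = stegoVol@header$cal_max)
  }
  dat <- stegoVol@data
  if (sliceAxis != 3L)
    dat <- aperm(dat, .axisPerm(sliceAxis))
  Sp <- dim(dat)[3L]
  parity <- meta$parity %||% 0L
  nPairs <- Sp - parity
  S <- meta$S %||% (2L * nPairs + parity)
  rng <- if (identical(meta$range, "volume")) c(meta$lo, meta$hi) else NULL
  padding <- if (is.null(cfg)) "zero" else cfg@medianPadding
  out <- array(0, dim = c(dim(dat)[1:2], S))
  for (k in seq_len(nPairs)) {
    out[, , 2L * k - 1L] <- dat[, , k]
    out[, , 2L * k] <- extractSlice(dat[, , k], beta = meta$beta,
                                    range = rng, dtype = stegoVol@dtype,
                                    medianPadding = padding)
  }
  if (parity)
    out[, , S] <- dat[, , Sp]
  if (sliceAxis != 3L)
    out <- aperm(out, order(.axisPerm(sliceAxis)))
  header <- stegoVol@header
  header$descrip <- ""
  header$sidecar <- NULL
  header$pixdim[sliceAxis] <- header$pixdim[sliceAxis] / 2
  VolumeImage(out, stegoVol@dtype, header)
}

#' Report on-disk and raw-data sizes of an original/stego file pair
#'
#' @param originalPath,stegoPath Paths to the two NIfTI files.
#' @param gzip Also report gzip-recompressed byte sizes.
#' @return A list with on-disk sizes, raw voxel-data sizes (from the
#'   header geometry and bit depth), their ratio
#'   \code{stego / original}, and optionally gzip sizes.
#' @export
sizeReport <- function(originalPath, stegoPath, gzip = FALSE) {
  for (p in c(originalPath, stegoPath))
    if (!file.exists(p))
      stop("file not found: ", p)
  rawBytes <- function(path) {
    h <- RNifti::niftiHeader(path)
    nd <- h$dim[1]
    prod(h$dim[seq(2, 1 + nd)]) * h$bitpix / 8
  }
  gzBytes <- function(path) {
    if (grepl("\\.gz$", path))
      return(file.size(path))
    length(memCompress(readBin(path, "raw", n = file.size(path)), "gzip"))
  }
  rep <- list(
    original_disk_bytes = file.size(originalPath),
    stego_disk_bytes    = file.size(stegoPath),
    original_raw_bytes  = rawBytes(originalPath),
    stego_raw_bytes     = rawBytes(stegoPath))
  rep$raw_ratio <- rep$stego_raw_bytes / rep$original_raw_bytes
  rep$disk_ratio <- rep$stego_disk_bytes / rep$original_disk_bytes
  if (gzip) {
    rep$original_gzip_bytes <- gzBytes(originalPath)
    rep$stego_gzip_bytes <- gzBytes(stegoPath)
    rep$gzip_ratio <- rep$stego_gzip_bytes / rep$original_gzip_bytes
  }
  rep
}
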
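#' @import methods
NULL

## Sample-type lookup shared by I/O, codec and metrics.  Codes are the
## NIfTI-1 datatype codes.
.DTYPE_TABLE <- data.frame(
  name    = c("uint8", "int8", "int16", "uint16", "int32", "uint32",
              "float32", "float64"),
  code    = c(2L, 256L, 4L, 512L, 8L, 768L, 16L, 64L),
  bits    = c(8L, 8L, 16L, 16L, 32L, 32L, 32L, 64L),
  integer = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
  min     = c(0, -128, -32768, 0, -2147483648, 0, -Inf, -Inf),
  max     = c(255, 127, 32767, 65535, 2147483647, 4294967295, Inf, Inf),
  stringsAsFactors = FALSE)

#' Describe an integer or float sample type
#'
#' Returns the bit width, representable range and NIfTI-1 datatype code for
#' a sample-type name such as \code{"uint16"}.
#'
#' @param dtype Sample-type name: one of \code{"uint8"}, \code{"int8"},
#'   \code{"int16"}, \code{"uint16"}, \code{"int32"}, \code{"uint32"},
#'   \code{"float32"}, \code{"float64"}.
#' @return A list with elements \code{name}, \code{code}, \code{bits},
#'   \code{integer}, \code{min}, \code{max}.
#' @examples
#' dtypeInfo("uint16")$max  # 65535
#' @export
dtypeInfo <- function(dtype) {
  i <- match(dtype, .DTYPE_TABLE$name)
  if (is.na(i))
    stop("unknown sample type '", dtype, "'")
  as.list(.DTYPE_TABLE[i, ])
}

.defaultHeader <- function() {
  list(affine   = diag(4),
       pixdim   = c(1, 1, 1),
       cal_min  = 0,
       cal_max  = 0,
       descrip  = "",
       sidecar  = NULL)
}

#' VolumeImage: a 3-D voxel grid with sample type and header metadata
#'
#' The central container of the package: an \code{m x n x S} intensity
#' grid (stored as a double array, integer-valued for integer sample
#' types), the sample-type descriptor, and the NIfTI header fields the
#' codec uses (affine, voxel spacing, calibration range, description).
#'
#' @slot data 3-D numeric array, \code{m x n x S}.
#' @slot dtype Sample-type name (see \code{\link{dtypeInfo}}).
#' @slot header List with \code{affine} (4x4), \code{pixdim} (length 3),
#'   \code{cal_min}, \code{cal_max}, \code{descrip}, and optionally
#'   \code{sidecar} (codec metadata that did not fit in \code{descrip}).
#' @aliases VolumeImage
#' @exportClass VolumeImage
setClass("VolumeImage",
         representation(data = "array", dtype = "character",
                        header = "list"))

setValidity("VolumeImage", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3-D array")
  info <- tryCatch(dtypeInfo(object@dtype), error = function(e) NULL)
  if (is.null(info)) {
    msgs <- c(msgs, "unknown dtype")
  } else if (length(object@data)) {
    r <- range(object@data)
    if (r[1] < info$min || r[2] > info$max)
      msgs <- c(msgs, sprintf("samples outside the %s range [%g, %g]",
                              object@dtype, info$min, info$max))
    if (info$integer && any(object@data != round(object@data)))
      msgs <- c(msgs, "non-integral samples under an integer dtype")
  }
  h <- object@header
  if (!all(c("affine", "pixdim", "cal_min", "cal_max", "descrip") %in%
           names(h)))
    msgs <- c(msgs, "incomplete header")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VolumeImage
#'
#' @param data 3-D numeric array.
#' @param dtype Sample-type name; defaults to \code{"uint16"}.
#' @param header Optional header list; missing fields are filled with
#'   defaults (identity affine, unit spacing, calibration set to the data
#'   range, empty description).
#' @return A \code{VolumeImage}.
#' @examples
#' v <- VolumeImage(array(0:7, dim = c(2, 2, 2)), "uint16")
#' numSlices(v)
#' @export
VolumeImage <- function(data, dtype = "uint16", header = NULL) {
  storage.mode(data) <- "double"
  h <- .defaultHeader()
  if (!is.null(header))
    h[names(header)] <- header
  if (is.null(header$cal_min) && is.null(header$cal_max) && length(data)) {
    h$cal_min <- min(data)
    h$cal_max <- max(data)
  }
  new("VolumeImage", data = data, dtype = dtype, header = h)
}

#' @describeIn VolumeImage-accessors The voxel array.
#' @export
volData <- function(vol) vol@data

#' @describeIn VolumeImage-accessors The sample-type name.
#' @export
volDtype <- function(vol) vol@dtype

#' @describeIn VolumeImage-accessors The header list.
#' @export
volHeader <- function(vol) vol@header

#' Accessors for VolumeImage
#'
#' @param vol A \code{VolumeImage}.
#' @name VolumeImage-accessors
#' @return \code{volData}: the array; \code{volDtype}: the type name;
#'   \code{volHeader}: the header list; \code{numSlices}: the slice count
#'   along the third array axis; \code{volRange}: \code{c(vmin, vmax)},
#'   the volume-wide intensity extrema.
NULL

#' @describeIn VolumeImage-accessors Number of slices (third axis).
#' @export
numSlices <- function(vol) dim(vol@data)[3L]

#' @describeIn VolumeImage-accessors Volume-wide \code{c(vmin, vmax)}.
#' @export
volRange <- function(vol) range(vol@data)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  r <- volRange(object)
  cat(sprintf("VolumeImage: %d x %d x %d  <%s>\n", d[1], d[2], d[3],
              object@dtype))
  cat(sprintf("  intensity range [%g, %g]; voxel spacing %s\n",
              r[1], r[2], paste(signif(object@header$pixdim, 4),
                                collapse = " x ")))
  if (nzchar(object@header$descrip))
    cat("  descrip: ", object@header$descrip, "\n", sep = "")
})

#' CodecConfig: parameters of the slice-embedding codec
#'
#' @slot beta Number of quantization intervals partitioning the DCT detail
#'   coefficient magnitude range; larger beta gives finer intervals (less
#'   stego distortion, noisier blind extraction after integer storage).
#' @slot rangeMode \code{"volume"} (normalize every slice with the
#'   volume-wide extrema, recorded in the header so extraction stays
#'   blind) or \code{"per-slice"} (each slice's own extrema).
#' @slot sliceAxis Array axis (1..3) along which slices run; default 3.
#' @slot medianPadding Border handling of the 3x3 median post-filter:
#'   \code{"zero"} or \code{"replicate"}.
#' @slot clampEps Normalized message values are clamped to
#'   \code{1 - clampEps} before embedding so a full-scale pixel cannot
#'   land on the next interval boundary.
#' @exportClass CodecConfig
setClass("CodecConfig",
         representation(beta = "numeric", rangeMode = "character",
                        sliceAxis = "integer", medianPadding = "character",
                        clampEps = "numeric"))

setValidity("CodecConfig", function(object) {
  msgs <- character()
  if (object@beta < 2 || object@beta > 1e6 ||
      object@beta != round(object@beta))
    msgs <- c(msgs, "beta must be an integer in [2, 1e6]")
  if (!object@rangeMode %in% c("volume", "per-slice"))
    msgs <- c(msgs, "rangeMode must be 'volume' or 'per-slice'")
  if (!object@sliceAxis %in% 1:3)
    msgs <- c(msgs, "sliceAxis must be 1, 2 or 3")
  if (!object@medianPadding %in% c("zero", "replicate"))
    msgs <- c(msgs, "medianPadding must be 'zero' or 'replicate'")
  if (object@clampEps <= 0 || object@clampEps > 2^-10)
    msgs <- c(msgs, "clampEps must be in (0, 2^-10]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CodecConfig
#'
#' @param beta Quantization interval count (default 500).
#' @param rangeMode \code{"volume"} or \code{"per-slice"}.
#' @param sliceAxis Slice axis, 1..3 (default 3).
#' @param medianPadding \code{"zero"} or \code{"replicate"}.
#' @param clampEps Message clamp (default \code{2^-12}).
#' @return A \code{CodecConfig}.
#' @examples
#' codecConfig(beta = 500)
#' @export
codecConfig <- function(beta = 500, rangeMode = c("volume", "per-slice"),
                        sliceAxis = 3L, medianPadding = c("zero", "replicate"),
                        clampEps = 2^-12) {
  new("CodecConfig", beta = beta, rangeMode = match.arg(rangeMode),
      sliceAxis = as.integer(sliceAxis),
      medianPadding = match.arg(medianPadding), clampEps = clampEps)
}

setMethod("show", "CodecConfig", function(object) {
  cat(sprintf(
    "CodecConfig: beta=%d, rangeMode=%s, sliceAxis=%d, medianPadding=%s\n",
    object@beta, object@rangeMode, object@sliceAxis, object@medianPadding))
})

#' QualityReport: per-slice and per-volume image-quality metrics
#'
#' @slot perSlice data.frame with columns \code{metric}, \code{beta},
#'   \code{slice_index} (0-based), \code{value}.
#' @slot volume data.frame of per-volume aggregates: the mean over slices
#'   (\code{aggregation == "slice-mean"}) and single whole-volume values
#'   (\code{aggregation == "pooled"}).
#' @slot fiveNumber data.frame of five-number summaries (min, q1, median,
#'   q3, max) of the per-slice values, one row per metric.
#' @exportClass QualityReport
setClass("QualityReport",
         representation(perSlice = "data.frame", volume = "data.frame",
                        fiveNumber = "data.frame"))

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport over", length(unique(object@perSlice$slice_index)),
      "slices\n")
  print(object@volume, row.names = FALSE)
})

#' @describeIn QualityReport-accessors Per-slice metric table.
#' @export
perSliceMetrics <- function(report) report@perSlice

#' @describeIn QualityReport-accessors Per-volume aggregate table.
#' @export
volumeMetrics <- function(report) report@volume

#' Accessors for QualityReport
#'
#' @param report A \code{QualityReport}.
#' @name QualityReport-accessors
NULL

#' @describeIn QualityReport-accessors Five-number summaries per metric.
#' @export
fiveNumberSummaries <- function(report) report@fiveNumber

`%||%` <- function(a, b) if (is.null(a)) b else a
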
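## Quantization hiding: embed a message slice's normalized pixels into
## the DCT detail coefficients of a cover slice, and the blind inverse.
## Each detail coefficient keeps its quantization interval index i
## (|c| in [2i/beta, 2(i+1)/beta)); the position *within* the interval
## encodes the message value, so extraction needs only beta.

#' Linearly normalize a slice to [0, 1]
#'
#' \code{(x - lo) / (hi - lo)}, then clipped to [0, 1]. A degenerate
#' range (\code{hi == lo}) yields all zeros with the attribute
#' \code{constant = TRUE}; the codec skips embedding in that case.
#'
#' @param x Numeric matrix.
#' @param lo,hi Normalization range, \code{hi >= lo}.
#' @return Numeric matrix in [0, 1], with attribute \code{constant}.
#' @export
normalizeSlice <- function(x, lo, hi) {
  stopifnot(hi >= lo)
  if (hi == lo) {
    out <- array(0, dim = dim(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (x - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  attr(out, "constant") <- FALSE
  out
}

#' Map a normalized slice back to the intensity domain
#'
#' \code{round(x * (hi - lo) + lo)}, clamped to the representable range
#' of \code{dtype} (no rounding for float dtypes).
#'
#' @param x Numeric matrix (nominally in [0, 1]).
#' @param lo,hi Source range used at normalization.
#' @param dtype Target sample type (see \code{\link{dtypeInfo}}).
#' @return Numeric matrix of \code{dtype}-representable values.
#' @export
denormalizeSlice <- function(x, lo, hi, dtype = "uint16") {
  stopifnot(hi >= lo)
  info <- dtypeInfo(dtype)
  out <- x * (hi - lo) + lo
  attr(out, "constant") <- NULL
  if (info$integer)
    out <- round(out)
  out[out < info$min] <- info$min
  out[out > info$max] <- info$max
  out
}

#' Quantization interval index of a coefficient magnitude
#'
#' Interval i covers magnitudes [2i/beta, 2(i+1)/beta); boundaries belong
#' to the higher interval (lower-closed convention) and the top interval
#' \code{beta - 1} absorbs magnitudes at or above 2.
#'
#' @param cAbs Non-negative coefficient magnitude(s).
#' @param beta Number of intervals (integer >= 2).
#' @return Integer index/indices in \code{0 .. beta - 1}.
#' @examples
#' intervalIndex(0.5, 500)  # 125
#' @export
intervalIndex <- function(cAbs, beta) {
  stopifnot(all(cAbs >= 0), beta >= 2)
  pmin(floor(cAbs * beta / 2), beta - 1)
}

#' Embed a message microblock into a cover coefficient block
#'
#' The DC coefficient (position (1,1)) is kept bit-identical to the
#' cover's. Each of the 15 detail coefficients is replaced by
#' \code{sign(c) * (2/beta) * (m + i)} where \code{i} is the cover
#' coefficient's interval index and \code{m} is the message pixel,
#' clamped to \code{1 - clampEps} (\code{sign(0)} is taken as +1).
#'
#' @param coverCb 4x4 cover coefficient block.
#' @param msgMb 4x4 message microblock with values in [0, 1].
#' @param beta Interval count.
#' @param clampEps Message clamp (default \code{2^-12}).
#' @return 4x4 stego coefficient block.
#' @export
embedBlock <- function(coverCb, msgMb, beta, clampEps = 2^-12) {
  stopifnot(all(dim(coverCb) == 4L), all(dim(msgMb) == 4L))
  i <- intervalIndex(abs(coverCb), beta)
  s <- sign(coverCb)
  s[s == 0] <- 1
  m <- pmin(msgMb, 1 - clampEps)
  stego <- s * (2 / beta) * (m + i)
  stego[1L, 1L] <- coverCb[1L, 1L]
  stego
}

#' Blindly extract a message microblock from a stego coefficient block
#'
#' For each detail coefficient, \code{m = (beta/2) * (|c| - 2i/beta)}
#' with \code{i} the interval index of \code{|c|}, clipped to [0, 1].
#' The DC position carries no message; it is filled with the mean of its
#' two nearest reconstructed neighbors, positions (1,2) and (2,1).
#'
#' @param stegoCb 4x4 stego coefficient block.
#' @param beta Interval count used at embedding.
#' @return 4x4 reconstructed message microblock in [0, 1].
#' @export
extractBlock <- function(stegoCb, beta) {
  stopifnot(all(dim(stegoCb) == 4L))
  a <- abs(stegoCb)
  i <- intervalIndex(a, beta)
  m <- (beta / 2) * (a - 2 * i / beta)
  m[m < 0] <- 0
  m[m > 1] <- 1
  m[1L, 1L] <- (m[1L, 2L] + m[2L, 1L]) / 2
  m
}

## Vectorized embed over the 4|4-tiled core of a slice: identical to
## applying embedBlock tile by tile.
.embedCore <- function(coverCoef, msgCore, beta, clampEps) {
  dc <- .dcMask(nrow(coverCoef), ncol(coverCoef))
  i <- intervalIndex(abs(coverCoef), beta)
  s <- sign(coverCoef)
  s[s == 0] <- 1
  m <- pmin(msgCore, 1 - clampEps)
  stego <- s * (2 / beta) * (m + i)
  stego[dc] <- coverCoef[dc]
  stego
}

.extractCore <- function(stegoCoef, beta) {
  M <- nrow(stegoCoef)
  N <- ncol(stegoCoef)
  a <- abs(stegoCoef)
  i <- intervalIndex(a, beta)
  m <- (beta / 2) * (a - 2 * i / beta)
  m[m < 0] <- 0
  m[m > 1] <- 1
  dcr <- seq(1L, M, by = 4L)
  dcc <- seq(1L, N, by = 4L)
  m[dcr, dcc] <- (m[dcr, dcc + 1L] + m[dcr + 1L, dcc]) / 2
  m
}

.sliceRange <- function(x, range) {
  if (is.null(range)) range(x) else range
}

#' Embed one slice into another (quantization hiding)
#'
#' Both slices are normalized, the cover's 4x4 microblocks are DCT
#' transformed, the message's normalized pixels are embedded into the
#' detail coefficients (\code{\link{embedBlock}}), and the result is
#' inverse transformed and denormalized with the cover's range into the
#' cover's sample type. Margins (dimensions mod 4) are copied from the
#' cover. A cover with a degenerate normalization range is returned
#' unchanged (nothing can be embedded).
#'
#' @param cover,msg \code{m x n} numeric matrices of equal shape.
#' @param beta Quantization interval count.
#' @param range \code{c(lo, hi)} normalization range shared by both
#'   slices (volume mode), or \code{NULL} to use each slice's own
#'   extrema (per-slice mode).
#' @param dtype Sample type of the output stego slice.
#' @param clampEps Message clamp.
#' @return Integer-valued stego matrix, same shape as \code{cover}.
#' @export
embedSlice <- function(cover, msg, beta, range = NULL, dtype = "uint16",
                       clampEps = 2^-12) {
  if (!identical(dim(cover), dim(msg)))
    stop("cover and message slices differ in shape")
  m <- nrow(cover)
  n <- ncol(cover)
  if (m < 4L || n < 4L)
    stop("slice smaller than 4x4")
  rc <- .sliceRange(cover, range)
  rm_ <- .sliceRange(msg, range)
  nc <- normalizeSlice(cover, rc[1], rc[2])
  if (isTRUE(attr(nc, "constant")))
    return(cover)
  nm <- normalizeSlice(msg, rm_[1], rm_[2])
  M <- 4L * (m %/% 4L)
  N <- 4L * (n %/% 4L)
  coverCoef <- .blockDCT(nc[seq_len(M), seq_len(N), drop = FALSE])
  stegoCoef <- .embedCore(coverCoef, nm[seq_len(M), seq_len(N),
                                        drop = FALSE], beta, clampEps)
  out <- nc
  attr(out, "constant") <- NULL
  out[seq_len(M), seq_len(N)] <- .blockDCT(stegoCoef, inverse = TRUE)
  denormalizeSlice(out, rc[1], rc[2], dtype)
}

#' Blindly reconstruct the embedded slice from a stego slice
#'
#' The stego slice is normalized, block transformed, and the message is
#' read back from the detail coefficients (\code{\link{extractBlock}}).
#' Margins carry no payload and are filled with the stego's own values
#' (the best blind estimate). The reconstruction is denormalized, passed
#' through a 3x3 median filter, and cast to \code{dtype}. Extraction is
#' blind: it needs only the stego slice, \code{beta} and the range.
#'
#' @param stego Stego slice matrix.
#' @param beta Interval count used at embedding.
#' @param range \code{c(lo, hi)} normalization range (volume mode), or
#'   \code{NULL} to fall back to the stego slice's own extrema.
#' @param dtype Sample type of the output.
#' @param medianPadding Border mode of the median filter.
#' @param medianFilter Set \code{FALSE} to skip the post-filter.
#' @return Integer-valued reconstructed slice, same shape as \code{stego}.
#' @export
extractSlice <- function(stego, beta, range = NULL, dtype = "uint16",
                         medianPadding = c("zero", "replicate"),
                         medianFilter = TRUE) {
  medianPadding <- match.arg(medianPadding)
  m <- nrow(stego)
  n <- ncol(stego)
  if (m < 4L || n < 4L)
    stop("slice smaller than 4x4")
  r <- .sliceRange(stego, range)
  ns <- normalizeSlice(stego, r[1], r[2])
  if (isTRUE(attr(ns, "constant")))
    return(stego)
  M <- 4L * (m %/% 4L)
  N <- 4L * (n %/% 4L)
  coef <- .blockDCT(ns[seq_len(M), seq_len(N), drop = FALSE])
  rec <- ns
  attr(rec, "constant") <- NULL
  rec[seq_len(M), seq_len(N)] <- .extractCore(coef, beta)
  info <- dtypeInfo(dtype)
  out <- rec * (r[2] - r[1]) + r[1]
  if (medianFilter)
    out <- medianFilter3x3(out, padding = medianPadding)
  if (info$integer)
    out <- round(out)
  out[out < info$min] <- info$min
  out[out > info$max] <- info$max
  out
}

#' 3x3 neighborhood median filter
#'
#' Each output pixel is the median of its 3x3 neighborhood. Borders are
#' zero-padded by default; \code{padding = "replicate"} repeats the edge
#' pixels instead.
#'
#' @param x Numeric matrix.
#' @param padding \code{"zero"} or \code{"replicate"}.
#' @return Filtered matrix of the same shape.
#' @export
medianFilter3x3 <- function(x, padding = c("zero", "replicate")) {
  padding <- match.arg(padding)
  m <- nrow(x)
  n <- ncol(x)
  p <- matrix(0, m + 2L, n + 2L)
  p[2:(m + 1L), 2:(n + 1L)] <- x
  if (padding == "replicate") {
    p[1L, 2:(n + 1L)] <- x[1L, ]
    p[m + 2L, 2:(n + 1L)] <- x[m, ]
    p[, 1L] <- p[, 2L]
    p[, n + 2L] <- p[, n + 1L]
  }
  nb <- array(0, dim = c(m, n, 9L))
  k <- 0L
  for (dr in 0:2) for (dc in 0:2) {
    k <- k + 1L
    nb[, , k] <- p[dr + seq_len(m), dc + seq_len(n)]
  }
  out <- apply(matrix(nb, m * n, 9L), 1L, function(v) sort.int(v)[5L])
  matrix(out, m, n)
}
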
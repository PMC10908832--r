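## Image-quality metrics: PSNR, SNR, SSIM, histogram entropy, bit error
## rate, and five-number summaries for box plots.

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(peakval^2 / MSE)} in decibels; \code{Inf} for
#' identical images. \code{peakval} is the sample type's range, e.g.
#' 65535 for uint16.
#'
#' @param f,g Numeric arrays of equal shape.
#' @param peakval Peak representable value.
#' @return PSNR in dB.
#' @export
psnr <- function(f, g, peakval) {
  if (!identical(dim(f), dim(g)))
    stop("shape mismatch")
  mse <- mean((f - g)^2)
  if (mse == 0) return(Inf)
  10 * log10(peakval^2 / mse)
}

#' Signal-to-noise ratio
#'
#' \code{10 * log10(sum(f^2) / sum((f - g)^2))} in decibels; \code{Inf}
#' for identical images, \code{NaN} when the reference is all zero.
#'
#' @param f Reference array.
#' @param g Comparison array of equal shape.
#' @return SNR in dB.
#' @export
snr <- function(f, g) {
  if (!identical(dim(f), dim(g)))
    stop("shape mismatch")
  num <- sum(f^2)
  den <- sum((f - g)^2)
  if (den == 0) return(Inf)
  if (num == 0) return(NaN)
  10 * log10(num / den)
}

.gaussianKernel1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

## Separable "valid"-mode filtering via banded matrices: rows then
## columns, output (m-k+1) x (n-k+1).
.validFilter <- function(x, g) {
  k <- length(g)
  band <- function(len) {
    A <- matrix(0, len - k + 1L, len)
    for (i in seq_len(len - k + 1L))
      A[i, i:(i + k - 1L)] <- g
    A
  }
  band(nrow(x)) %*% x %*% t(band(ncol(x)))
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma = 1.5) and
#' stabilizers \code{c1 = (0.01 * peakval)^2},
#' \code{c2 = (0.03 * peakval)^2}; local statistics are Gaussian-weighted
#' moments and the map is averaged over the valid (fully-windowed)
#' region. Values lie in [-1, 1]; 1 means identical.
#'
#' @param f,g Numeric matrices of equal shape, both dimensions >= 11.
#' @param peakval Dynamic range of the sample type.
#' @return Mean SSIM.
#' @export
ssim <- function(f, g, peakval) {
  if (!identical(dim(f), dim(g)))
    stop("shape mismatch")
  if (min(dim(f)) < 11L)
    stop("image smaller than the 11x11 SSIM window")
  w <- .gaussianKernel1d()
  c1 <- (0.01 * peakval)^2
  c2 <- (0.03 * peakval)^2
  muF <- .validFilter(f, w)
  muG <- .validFilter(g, w)
  sFF <- .validFilter(f * f, w) - muF^2
  sGG <- .validFilter(g * g, w) - muG^2
  sFG <- .validFilter(f * g, w) - muF * muG
  map <- ((2 * muF * muG + c1) * (2 * sFG + c2)) /
    ((muF^2 + muG^2 + c1) * (sFF + sGG + c2))
  mean(map)
}

#' Shannon entropy of the intensity histogram
#'
#' Intensities are affinely rescaled to [0, 255] and counted into
#' \code{bins} equal-width bins; \code{H = -sum(P * log2(P))} over the
#' occupied bins. A constant image has zero entropy.
#'
#' @param x Numeric array.
#' @param bins Histogram bin count (default 256).
#' @return Entropy in bits, in \code{[0, log2(bins)]}.
#' @export
imageEntropy <- function(x, bins = 256L) {
  if (!length(x))
    stop("empty image")
  lo <- min(x)
  hi <- max(x)
  if (hi == lo)
    return(0)
  idx <- floor((x - lo) / (hi - lo) * bins)
  idx[idx >= bins] <- bins - 1L
  p <- tabulate(idx + 1L, nbins = bins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Bit error rate between two equal-type images
#'
#' The fraction of differing bits in the binary sample representations:
#' XOR of the integer samples, popcount, divided by
#' \code{samples * bits-per-sample}.
#'
#' @param f,g Integer-valued arrays of equal shape.
#' @param dtype Shared sample type (determines bits per sample).
#' @return Fraction in [0, 1].
#' @export
ber <- function(f, g, dtype = "uint16") {
  if (!identical(dim(f), dim(g)))
    stop("shape mismatch")
  info <- dtypeInfo(dtype)
  if (!info$integer)
    stop("bit error rate is defined for integer sample types")
  x <- bitwXor(as.integer(f), as.integer(g))
  nbits <- 0
  for (k in seq_len(info$bits) - 1L)
    nbits <- nbits + sum(bitwAnd(bitwShiftR(x, k), 1L))
  nbits / (length(f) * info$bits)
}

#' Five-number summary
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by linear interpolation (\code{quantile} type 7).
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector \code{(min, q1, median, q3, max)}.
#' @examples
#' fiveNumber(1:5)
#' @export
fiveNumber <- function(values) {
  if (!length(values))
    stop("empty input")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Full quality report between two volumes
#'
#' Computes PSNR, SNR, SSIM, entropy (of the second volume) and BER per
#' slice, plus two per-volume aggregations: the mean over slices and
#' single whole-volume values (PSNR/SNR/BER pooled over all voxels;
#' volume SSIM as the slice mean; entropy of the pooled histogram).
#' Five-number summaries of the per-slice values support box plots.
#'
#' @param reference Reference \code{VolumeImage} (e.g. the original).
#' @param test Comparison \code{VolumeImage} of equal shape and dtype
#'   (e.g. stego or reconstructed).
#' @param beta Optional beta recorded in the report rows.
#' @return A \code{\link[=QualityReport-accessors]{QualityReport}}.
#' @export
qualityReport <- function(reference, test, beta = NA_real_) {
  if (!identical(dim(reference@data), dim(test@data)))
    stop("volumes differ in shape")
  if (!identical(reference@dtype, test@dtype))
    stop("volumes differ in dtype")
  peak <- dtypeInfo(reference@dtype)$max
  S <- numSlices(reference)
  vals <- lapply(seq_len(S), function(k) {
    f <- reference@data[, , k]
    g <- test@data[, , k]
    c(psnr_db = psnr(f, g, peak), snr_db = snr(f, g),
      ssim = ssim(f, g, peak), entropy_bits = imageEntropy(g),
      ber_fraction = ber(f, g, reference@dtype))
  })
  mat <- do.call(rbind, vals)
  perSlice <- data.frame(
    metric = rep(colnames(mat), each = S),
    beta = beta,
    slice_index = rep(seq_len(S) - 1L, times = ncol(mat)),
    value = as.vector(mat))
  sliceMean <- colMeans(mat)
  pooled <- c(psnr_db = psnr(reference@data, test@data, peak),
              snr_db = snr(reference@data, test@data),
              ssim = mean(mat[, "ssim"]),
              entropy_bits = imageEntropy(test@data),
              ber_fraction = ber(reference@data, test@data,
                                 reference@dtype))
  volume <- data.frame(
    metric = rep(names(sliceMean), 2),
    beta = beta,
    aggregation = rep(c("slice-mean", "pooled"), each = length(sliceMean)),
    value = c(sliceMean, pooled))
  fn <- t(apply(mat, 2, function(v) fiveNumber(v[is.finite(v)])))
  fiveNum <- data.frame(metric = rownames(fn), beta = beta, fn,
                        row.names = NULL)
  new("QualityReport", perSlice = perSlice, volume = volume,
      fiveNumber = fiveNum)
}

#' Write a QualityReport as CSV
#'
#' One row per slice and metric plus aggregate rows
#' (\code{slice_index = NA}), columns \code{metric}, \code{beta},
#' \code{slice_index}, \code{aggregation}, \code{value}.
#'
#' @param report A \code{QualityReport}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeQualityCSV <- function(report, path) {
  ps <- report@perSlice
  ps$aggregation <- "slice"
  agg <- report@volume
  agg$slice_index <- NA_integer_
  out <- rbind(ps[, c("metric", "beta", "slice_index", "aggregation",
                      "value")],
               agg[, c("metric", "beta", "slice_index", "aggregation",
                       "value")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
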
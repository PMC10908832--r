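## Deterministic MRI-like phantoms: sums of drifting ellipsoidal
## Gaussian blobs with strong adjacent-slice correlation, so the
## cover/message pairing of the codec sees realistic similarity without
## downloading any data.

#' Generate a deterministic MRI-like phantom volume
#'
#' The volume is a sum of \code{nBlobs} 2-D elliptical Gaussians whose
#' centers move linearly along the slice axis at a rate set by
#' \code{sliceDrift} (fraction of the in-plane extent per slice), which
#' makes adjacent slices strongly correlated, as in real anatomy.
#' After the smooth field is affinely mapped onto the dtype's range,
#' Rician noise of scale \code{noiseSd} (intensity units; the standard
#' deviation of the two underlying Gaussian channels) is applied — the
#' standard noise model for magnitude MR images, giving a strictly
#' positive Rayleigh-distributed background rather than a clipped-at-zero
#' one. Samples are then rounded and clamped to the dtype range. The
#' same seed always yields a bit-identical volume.
#'
#' @param shape Integer vector \code{c(m, n, S)}, minimum
#'   \code{c(16, 16, 4)}.
#' @param dtype Target integer sample type (default \code{"uint16"}).
#' @param seed RNG seed.
#' @param nBlobs Number of Gaussian blobs.
#' @param noiseSd Rician noise scale in intensity units.
#' @param sliceDrift Center drift per slice as a fraction of
#'   \code{min(m, n)}; smaller values give higher adjacent-slice
#'   correlation.
#' @return A \code{VolumeImage}.
#' @examples
#' v <- generatePhantom(c(32, 32, 4), seed = 1)
#' dim(volData(v))
#' @export
generatePhantom <- function(shape = c(64, 64, 16), dtype = "uint16",
                            seed = 1L, nBlobs = 12L, noiseSd = 655,
                            sliceDrift = 0.05) {
  if (length(shape) != 3L || any(shape < c(16, 16, 4)))
    stop("shape must be c(m, n, S) with m, n >= 16 and S >= 4")
  if (noiseSd < 0)
    stop("noiseSd must be non-negative")
  info <- dtypeInfo(dtype)
  if (!info$integer)
    stop("phantoms are generated with integer sample types")
  m <- shape[1L]; n <- shape[2L]; S <- shape[3L]
  ext <- min(m, n)
  out <- withr::with_seed(as.integer(seed), {
    cx <- stats::runif(nBlobs, 0.2, 0.8) * m
    cy <- stats::runif(nBlobs, 0.2, 0.8) * n
    ang <- stats::runif(nBlobs, 0, 2 * pi)
    sx <- stats::runif(nBlobs, 0.07, 0.16) * ext
    sy <- stats::runif(nBlobs, 0.07, 0.16) * ext
    amp <- stats::runif(nBlobs, 0.5, 1)
    field <- array(0, dim = c(m, n, S))
    for (s in seq_len(S)) {
      drift <- sliceDrift * ext * (s - 1L)
      plane <- matrix(0, m, n)
      for (b in seq_len(nBlobs)) {
        gx <- exp(-(seq_len(m) - (cx[b] + drift * cos(ang[b])))^2 /
                    (2 * sx[b]^2))
        gy <- exp(-(seq_len(n) - (cy[b] + drift * sin(ang[b])))^2 /
                    (2 * sy[b]^2))
        plane <- plane + amp[b] * outer(gx, gy)
      }
      field[, , s] <- plane
    }
    lo <- min(field); hi <- max(field)
    peakTarget <- if (info$max > 0) info$max else 1
    mapped <- (field - lo) / (hi - lo) * peakTarget
    if (noiseSd > 0)
      mapped <- sqrt((mapped + stats::rnorm(length(mapped),
                                            sd = noiseSd))^2 +
                     stats::rnorm(length(mapped), sd = noiseSd)^2)
    mapped <- round(mapped)
    mapped[mapped < info$min] <- info$min
    mapped[mapped > info$max] <- info$max
    mapped
  })
  VolumeImage(out, dtype)
}

#' Write a standard set of phantom fixtures
#'
#' Writes four NIfTI phantoms exercising the codec's edge cases — even
#' slice count, odd slice count, in-plane dimensions not divisible by 4,
#' and a volume containing constant slices — plus a JSON manifest
#' listing path, shape, dtype, seed and generator parameters for each.
#'
#' @param dir Writable output directory (created if absent).
#' @param seed Base RNG seed; fixture k uses \code{seed + k - 1}.
#' @return Invisibly, the manifest as a list (also written to
#'   \code{manifest.json} in \code{dir}).
#' @export
writeFixtureSet <- function(dir, seed = 1L) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  specs <- list(
    list(name = "even_s",   shape = c(64L, 64L, 8L)),
    list(name = "odd_s",    shape = c(32L, 32L, 7L)),
    list(name = "non_mult4", shape = c(30L, 26L, 6L)),
    list(name = "constant_slices", shape = c(16L, 16L, 4L)))
  manifest <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    sd <- as.integer(seed) + k - 1L
    vol <- generatePhantom(sp$shape, seed = sd)
    if (sp$name == "constant_slices") {
      dat <- volData(vol)
      dat[, , 1:2] <- 1000  # degenerate per-slice normalization range
      vol <- VolumeImage(dat, volDtype(vol))
    }
    path <- file.path(dir, paste0(sp$name, ".nii.gz"))
    writeVolume(vol, path)
    manifest[[k]] <- list(path = path, shape = sp$shape,
                          dtype = volDtype(vol), seed = sd,
                          params = list(nBlobs = 12L, noiseSd = 655,
                                        sliceDrift = 0.05))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
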
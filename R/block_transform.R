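## 4x4 microblock tiling and the orthonormal 2-D DCT used by the codec.

#' The orthonormal 4-point DCT-II matrix
#'
#' Row 0 is constant \code{1/2}; row k > 0, column n is
#' \code{sqrt(2/4) * cos((2n+1) k pi / 8)}. Satisfies
#' \code{T \%*\% t(T) == diag(4)} to machine precision, so the 2-D block
#' transform \code{T \%*\% B \%*\% t(T)} is energy-preserving and exactly
#' invertible.
#'
#' @return A 4x4 numeric matrix.
#' @examples
#' T <- dctMatrix()
#' max(abs(T %*% t(T) - diag(4)))  # ~1e-16
#' @export
dctMatrix <- function() {
  k <- 0:3
  n <- 0:3
  T <- sqrt(2 / 4) * cos(outer(k, 2 * n + 1) * pi / 8)
  T[1, ] <- 1 / 2
  T
}

.DCT4 <- NULL  # initialized at load; cached kron blocks per dimension
.kronCache <- new.env(parent = emptyenv())

.dct4 <- function() {
  if (is.null(.DCT4))
    dctMatrix()
  else
    .DCT4
}

## Block-diagonal expansion of the 4-point DCT for an axis of length 4b:
## applying it to the rows/columns of a slice transforms every 4x4 tile
## independently and at once.
.kronDct <- function(len) {
  key <- as.character(len)
  m <- .kronCache[[key]]
  if (is.null(m)) {
    m <- kronecker(diag(len / 4L), dctMatrix())
    .kronCache[[key]] <- m
  }
  m
}

## Blockwise 2-D DCT (or its inverse) of a matrix whose dimensions are
## multiples of 4; each 4x4 tile is transformed independently.
.blockDCT <- function(x, inverse = FALSE) {
  KM <- .kronDct(nrow(x))
  KN <- .kronDct(ncol(x))
  if (inverse)
    t(KM) %*% x %*% KN
  else
    KM %*% x %*% t(KN)
}

## Logical mask of the approximation (DC) positions, i.e. entry (0,0) of
## every 4x4 tile, for a core matrix of size M x N.
.dcMask <- function(M, N) {
  outer((seq_len(M) - 1L) %% 4L == 0L, (seq_len(N) - 1L) %% 4L == 0L, `&`)
}

#' Forward 2-D DCT of a 4x4 microblock
#'
#' \code{T \%*\% mb \%*\% t(T)}: one approximation (DC) coefficient at
#' position (1,1) and fifteen detail coefficients. For microblocks with
#' values in [0,1] the DC lies in [0,4] and every detail coefficient has
#' magnitude below 2.
#'
#' @param mb 4x4 numeric matrix.
#' @return 4x4 coefficient matrix.
#' @export
forwardBlock <- function(mb) {
  stopifnot(is.matrix(mb), all(dim(mb) == 4L))
  T <- .dct4()
  T %*% mb %*% t(T)
}

#' Inverse 2-D DCT of a 4x4 coefficient block
#'
#' \code{t(T) \%*\% cb \%*\% T}; exact inverse of
#' \code{\link{forwardBlock}}.
#'
#' @param cb 4x4 coefficient matrix.
#' @return 4x4 pixel-domain matrix.
#' @export
inverseBlock <- function(cb) {
  stopifnot(is.matrix(cb), all(dim(cb) == 4L))
  T <- .dct4()
  t(T) %*% cb %*% T
}

#' Tile a slice into 4x4 microblocks
#'
#' Partitions an \code{m x n} matrix into \code{floor(m/4) x floor(n/4)}
#' non-overlapping 4x4 blocks (row-major). Residual right/bottom strips
#' (widths m mod 4, n mod 4) are carried unmodified as
#' margins; \code{\link{untileBlocks}} reassembles the input bit-exactly.
#'
#' @param x Numeric matrix with \code{m >= 4} and \code{n >= 4}.
#' @return A list of class \code{"BlockGrid"}: \code{blocks} (a
#'   \code{4 x 4 x nbr x nbc} array), \code{marginRight},
#'   \code{marginBottom}, and \code{shape}.
#' @export
tileBlocks <- function(x) {
  m <- nrow(x)
  n <- ncol(x)
  if (m < 4L || n < 4L)
    stop("slice smaller than 4x4")
  nbr <- m %/% 4L
  nbc <- n %/% 4L
  core <- x[seq_len(4L * nbr), seq_len(4L * nbc), drop = FALSE]
  blocks <- aperm(array(core, dim = c(4L, nbr, 4L, nbc)), c(1L, 3L, 2L, 4L))
  structure(list(
    blocks       = blocks,
    marginRight  = x[seq_len(4L * nbr), seq_len(n - 4L * nbc) + 4L * nbc,
                     drop = FALSE],
    marginBottom = x[seq_len(m - 4L * nbr) + 4L * nbr, , drop = FALSE],
    shape        = c(m, n)), class = "BlockGrid")
}

#' Reassemble a BlockGrid into a slice
#'
#' Exact inverse of \code{\link{tileBlocks}}, including margins.
#'
#' @param grid A \code{"BlockGrid"} as returned by \code{tileBlocks}.
#' @return Numeric matrix of the original shape.
#' @export
untileBlocks <- function(grid) {
  b <- grid$blocks
  nbr <- dim(b)[3L]
  nbc <- dim(b)[4L]
  core <- array(aperm(b, c(1L, 3L, 2L, 4L)), dim = c(4L * nbr, 4L * nbc))
  m <- grid$shape[1L]
  n <- grid$shape[2L]
  out <- matrix(0, m, n)
  out[seq_len(4L * nbr), seq_len(4L * nbc)] <- core
  if (ncol(grid$marginRight))
    out[seq_len(4L * nbr), seq_len(n - 4L * nbc) + 4L * nbc] <-
      grid$marginRight
  if (nrow(grid$marginBottom))
    out[seq_len(m - 4L * nbr) + 4L * nbr, ] <- grid$marginBottom
  out
}
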
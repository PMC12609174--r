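# Internal numerics shared across modules.

FWHM_TO_SIGMA <- 1 / 2.355

.gaussKernel1d <- function(sigma) {
  # truncate at 4 sigma; normalised to unit mass
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along margin `along` of a 3D array with nearest-edge
# replication, implemented by summing shifted copies (fast enough for the
# grid sizes this package targets, and dependency-free).
.convolveAxis <- function(x, kernel, along) {
  d <- dim(x)
  n <- d[along]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = d)
  idx_all <- seq_len(n)
  for (j in seq_along(kernel)) {
    shift <- j - r - 1L
    src <- pmin(pmax(idx_all + shift, 1L), n)  # replicate edges
    sl <- switch(along,
                 x[src, , , drop = FALSE],
                 x[, src, , drop = FALSE],
                 x[, , src, drop = FALSE])
    out <- out + kernel[j] * sl
  }
  out
}

#' Gaussian smoothing of a 3D map
#'
#' Separable Gaussian filter with per-axis width `sigma = FWHM / (2.355 *
#' voxel_size)`. Boundaries use nearest-neighbour replication, so a
#' constant map is exactly preserved. `fwhmMm = 0` is the identity.
#'
#' @param x 3D numeric array.
#' @param fwhmMm full width at half maximum of the kernel, in mm.
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @return Smoothed array of the same shape.
#' @examples
#' m <- array(0, dim = c(9, 9, 9)); m[5, 5, 5] <- 1
#' sum(gaussianSmooth(m, fwhmMm = 4))  # kernel mass ~= 1
#' @export
gaussianSmooth <- function(x, fwhmMm, voxelSize = c(1, 1, 1)) {
  stopifnot(fwhmMm >= 0, length(dim(x)) == 3L)
  if (fwhmMm == 0) return(x)
  for (ax in 1:3) {
    sigma <- fwhmMm * FWHM_TO_SIGMA / voxelSize[ax]
    if (sigma > 0) x <- .convolveAxis(x, .gaussKernel1d(sigma), ax)
  }
  x
}

# Derive a reproducible sub-seed (kept within 32-bit signed range).
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2011 + as.numeric(k) * 7919) %% 2147483629)
}

.logMsg <- function(...) {
  message(sprintf("[graytex %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}
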
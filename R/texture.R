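# Masked 3D GLCM texture pipeline:
#   normalise (mu +/- k*sigma clip)  ->  uniform quantisation to L levels
#   ->  grey-level co-occurrence accumulation over an offset set
#   ->  autocorrelation statistic sum_ij i*j*p(i,j).
# Each ROI is processed independently within its own mask; only voxel pairs
# with BOTH ends inside the mask contribute to the co-occurrence counts.

#' Quantisation settings for texture extraction
#'
#' @slot nLevels integer number of grey levels L (>= 2); 32 is the
#'   conventional choice for T1 radiomics.
#' @slot clipSigmas intensities are clipped to `mu +/- clipSigmas * sigma`
#'   computed within the ROI before binning (dynamic limited
#'   normalisation).
#' @seealso [quantizationSpec()]
#' @export
setClass("QuantizationSpec",
  slots = c(nLevels = "integer", clipSigmas = "numeric"))

setValidity("QuantizationSpec", function(object) {
  msg <- character()
  if (object@nLevels < 2L) msg <- c(msg, "nLevels must be >= 2")
  if (object@clipSigmas <= 0) msg <- c(msg, "clipSigmas must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param nLevels,clipSigmas see the class slots.
#' @return a [QuantizationSpec-class].
#' @rdname QuantizationSpec-class
#' @export
quantizationSpec <- function(nLevels = 32L, clipSigmas = 3) {
  new("QuantizationSpec", nLevels = as.integer(nLevels),
      clipSigmas = clipSigmas)
}

#' Voxel offset set for co-occurrence accumulation
#'
#' The offset vectors (one per direction, scaled by `distance`) define
#' which voxel pairs are counted. With `symmetric = TRUE` each pair is
#' accumulated in both orders, making the matrix symmetric. The default
#' `"3d13"` set holds the 13 unique direction vectors of the
#' 26-neighbourhood (rotation-robust standard radiomics practice);
#' `"axial2"` is the two in-plane directions of the classic 2D toy
#' (horizontal + vertical, distance 1).
#'
#' @slot offsets integer matrix, one offset (dx, dy, dz) per row, already
#'   scaled by distance.
#' @slot distance the inter-voxel distance d.
#' @slot symmetric logical, accumulate both pair orders.
#' @seealso [offsetSet()]
#' @export
setClass("OffsetSet",
  slots = c(offsets = "matrix", distance = "integer", symmetric = "logical"))

setValidity("OffsetSet", function(object) {
  o <- object@offsets
  msg <- character()
  if (ncol(o) != 3L) msg <- c(msg, "offsets must have 3 columns")
  if (any(rowSums(o != 0) == 0)) msg <- c(msg, "zero offset not allowed")
  key <- apply(o, 1, paste, collapse = ",")
  neg <- apply(-o, 1, paste, collapse = ",")
  if (object@symmetric && any(neg %in% key))
    msg <- c(msg, "symmetric sets must not contain an offset and its negation")
  if (anyDuplicated(key)) msg <- c(msg, "duplicate offsets")
  if (length(msg)) msg else TRUE
})

.DIRS_3D13 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(g != 0) > 0, ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
})

#' @param directions `"3d13"`, `"axial2"`, or an integer matrix of unit
#'   direction vectors (one per row).
#' @param distance inter-voxel distance d (positive integer, default 1).
#' @param symmetric accumulate both pair orders (default TRUE).
#' @return an [OffsetSet-class].
#' @rdname OffsetSet-class
#' @export
offsetSet <- function(directions = "3d13", distance = 1L, symmetric = TRUE) {
  stopifnot(distance >= 1)
  if (is.character(directions)) {
    directions <- switch(match.arg(directions, c("3d13", "axial2")),
                         "3d13" = .DIRS_3D13,
                         "axial2" = rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)))
  }
  directions <- matrix(as.integer(directions), ncol = 3)
  new("OffsetSet", offsets = directions * as.integer(distance),
      distance = as.integer(distance), symmetric = isTRUE(symmetric))
}

setMethod("show", "OffsetSet", function(object) {
  cat(sprintf("OffsetSet: %d direction(s), distance %d, %s\n",
              nrow(object@offsets), object@distance,
              if (object@symmetric) "symmetric" else "asymmetric"))
})

#' Grey-level co-occurrence matrix
#'
#' @slot counts L x L matrix of pair counts (all offsets pooled).
#' @slot p L x L matrix of pair probabilities (`counts / nPairs`).
#' @slot nPairs total number of accumulated (ordered) pairs.
#' @slot nLevels L.
#' @slot offsets the [OffsetSet-class] used.
#' @seealso [glcm()], [autocorrelation()]
#' @export
setClass("GLCMatrix",
  slots = c(counts = "matrix", p = "matrix", nPairs = "numeric",
            nLevels = "integer", offsets = "OffsetSet"))

setValidity("GLCMatrix", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (object@nPairs > 0 && abs(sum(object@p) - 1) > 1e-8)
    msg <- c(msg, "probabilities must sum to 1")
  if (object@nPairs > 0 && object@offsets@symmetric &&
      max(abs(object@counts - t(object@counts))) > 0)
    msg <- c(msg, "symmetric accumulation must yield a symmetric matrix")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GLCMatrix", function(object) {
  cat(sprintf("GLCMatrix: %d levels, %g pairs over %d offset(s)\n",
              object@nLevels, object@nPairs, nrow(object@offsets@offsets)))
})

#' ROI intensity normalisation (dynamic limited method)
#'
#' Computes the mean and standard deviation over in-mask voxels and clips
#' every value to `mu +/- clipSigmas * sigma`. A constant ROI (sigma = 0)
#' is flagged degenerate and passed through unchanged.
#'
#' @param values numeric vector of in-ROI intensities.
#' @param spec a [QuantizationSpec-class].
#' @return list with `values` (clipped), `mu`, `sigma`, `nClipped`,
#'   `degenerate`.
#' @examples
#' normalizeRoi(c(0:10, 1000), quantizationSpec())$nClipped
#' @export
normalizeRoi <- function(values, spec = quantizationSpec()) {
  if (length(values) == 0L) stop("empty ROI mask")
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (length(values) == 1L || is.na(sigma)) sigma <- 0
  if (sigma == 0)
    return(list(values = values, mu = mu, sigma = 0, nClipped = 0L,
                degenerate = TRUE))
  lo <- mu - spec@clipSigmas * sigma
  hi <- mu + spec@clipSigmas * sigma
  nClipped <- sum(values < lo | values > hi)
  list(values = pmin(pmax(values, lo), hi), mu = mu, sigma = sigma,
       nClipped = as.integer(nClipped), degenerate = FALSE)
}

#' Uniform quantisation to discrete grey levels
#'
#' Equal-width binning of the (post-clip) intensity range into L levels:
#' `level(v) = min(L, 1 + floor(L * (v - vmin) / (vmax - vmin)))`, so the
#' maximum maps to level L exactly. A degenerate ROI (`vmax == vmin`) maps
#' every voxel to level 1 with a warning.
#'
#' @param values numeric vector of (clipped) in-ROI intensities.
#' @param spec a [QuantizationSpec-class].
#' @return integer vector of levels in `1..L`.
#' @examples
#' quantize(c(0, 1, 2, 3), quantizationSpec(nLevels = 4))
#' @export
quantize <- function(values, spec = quantizationSpec()) {
  stopifnot(all(is.finite(values)))
  L <- spec@nLevels
  vmin <- min(values); vmax <- max(values)
  if (vmax == vmin) {
    warning("degenerate ROI (constant intensity): all voxels at level 1")
    return(rep(1L, length(values)))
  }
  pmin(L, 1L + as.integer(floor(L * (values - vmin) / (vmax - vmin))))
}

#' Masked 3D grey-level co-occurrence matrix
#'
#' Accumulates, for every offset and every in-mask voxel whose offset
#' neighbour is also in-mask, one count at (level(v), level(v + o)); with
#' symmetric accumulation the transposed entry is counted too. Counts from
#' all offsets are pooled before normalisation to probabilities.
#'
#' @param levels 3D integer array of quantised levels with `NA` outside the
#'   mask.
#' @param offsets an [OffsetSet-class].
#' @param nLevels L; defaults to the maximum level present.
#' @return A [GLCMatrix-class]; if no valid pair exists `nPairs` is 0 and
#'   downstream features are reported missing.
#' @export
glcm <- function(levels, offsets = offsetSet(), nLevels = NULL) {
  stopifnot(length(dim(levels)) == 3L)
  if (is.null(nLevels)) {
    nLevels <- suppressWarnings(max(levels, na.rm = TRUE))
    if (!is.finite(nLevels)) nLevels <- 1L
  }
  L <- as.integer(nLevels)
  d <- dim(levels)
  counts <- numeric(L * L)
  for (r in seq_len(nrow(offsets@offsets))) {
    o <- offsets@offsets[r, ]
    lo <- pmax(1L, 1L - o); hi <- pmin(d, d - o)
    if (any(lo > hi)) next
    rx <- seq.int(lo[1], hi[1])
    ry <- seq.int(lo[2], hi[2])
    rz <- seq.int(lo[3], hi[3])
    A <- levels[rx, ry, rz, drop = FALSE]
    B <- levels[rx + o[1], ry + o[2], rz + o[3], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    i <- A[ok]; j <- B[ok]
    counts <- counts + tabulate((i - 1L) * L + j, nbins = L * L)
    if (offsets@symmetric)
      counts <- counts + tabulate((j - 1L) * L + i, nbins = L * L)
  }
  cm <- matrix(counts, nrow = L, ncol = L, byrow = TRUE)
  n <- sum(cm)
  p <- if (n > 0) cm / n else matrix(0, L, L)
  new("GLCMatrix", counts = cm, p = p, nPairs = n, nLevels = L,
      offsets = offsets)
}

#' GLCM autocorrelation
#'
#' The texture statistic `sum_i sum_j i * j * p(i, j)`: high for spatially
#' homogeneous regions (co-occurring high levels), low where microlesions
#' or heterogeneous tissue break up the local intensity structure. Bounded
#' in `[1, L^2]`.
#'
#' @param g a [GLCMatrix-class].
#' @return the autocorrelation value, or `NA` with a warning when the GLCM
#'   holds no pairs.
#' @export
autocorrelation <- function(g) {
  stopifnot(is(g, "GLCMatrix"))
  if (g@nPairs == 0) {
    warning("empty GLCM (no valid voxel pairs): feature is missing")
    return(NA_real_)
  }
  lv <- seq_len(g@nLevels)
  as.numeric(t(lv) %*% g@p %*% lv)
}

# Minimum usable ROI size for texture (voxels); smaller regions give
# unstable co-occurrence estimates and are reported missing.
MIN_ROI_VOXELS <- 27L

#' Region-wise texture extraction
#'
#' Runs normalise -> quantise -> GLCM -> autocorrelation independently
#' within each parcel of the atlas and within the composite region (the
#' union of all `in_composite` parcels, normalised and quantised within
#' its own mask). Failures in one region never abort the subject: the
#' region's value is reported missing.
#'
#' @param volume a [BrainVolume-class].
#' @param atlas an aligned [RegionAtlas-class].
#' @param spec a [QuantizationSpec-class].
#' @param offsets an [OffsetSet-class].
#' @param subjectId id written into the output rows.
#' @return Long-format feature table (`measure = "autocorrelation"`), one
#'   row per parcel plus one for the composite region.
#' @export
extractTexture <- function(volume, atlas, spec = quantizationSpec(),
                           offsets = offsetSet(), subjectId = "S001") {
  checkAligned(volume, atlas)
  labs <- regionLabels(atlas)
  rt <- regionTable(atlas)
  regionIds <- c(rt$region_id, compositeId(atlas))
  masks <- c(lapply(rt$region_id, function(id) labs == id),
             list(array(labs %in% rt$region_id[rt$in_composite],
                        dim = dim(labs))))
  vals <- vapply(masks, function(mask) {
    tryCatch({
      nvox <- sum(mask)
      if (nvox < MIN_ROI_VOXELS) {
        warning("region below minimum size (", nvox, " voxels): missing")
        return(NA_real_)
      }
      norm <- normalizeRoi(volume@data[mask], spec)
      lv <- array(NA_integer_, dim = dim(mask))
      if (norm$degenerate) {
        lv[mask] <- 1L
      } else {
        lv[mask] <- quantize(norm$values, spec)
      }
      g <- glcm(lv, offsets, nLevels = spec@nLevels)
      if (g@nPairs == 0) {
        warning("no valid voxel pairs in region: missing")
        return(NA_real_)
      }
      autocorrelation(g)
    }, error = function(e) {
      warning("texture extraction failed for a region: ",
              conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  data.frame(subject_id = subjectId, region_id = regionIds,
             measure = "autocorrelation", value = vals,
             stringsAsFactors = FALSE)
}
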
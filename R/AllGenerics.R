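#' Accessors for image and atlas objects
#'
#' `voxelSize()` returns the voxel edge lengths in mm; `imgData()` the raw
#' 3D array; `regionLabels()` the atlas label array; `regionTable()` the
#' parcel table; `compositeId()` the reserved id of the composite region;
#' `gmMap()`, `wmMap()`, `csfMap()` the tissue-probability arrays.
#'
#' @param x a [BrainVolume-class], [RegionAtlas-class] or
#'   [TissueMaps-class] object as appropriate.
#' @return The slot content (array, data.frame or numeric vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("compositeId", function(x) standardGeneric("compositeId"))
#' @rdname accessors
#' @export
setGeneric("gmMap", function(x) standardGeneric("gmMap"))
#' @rdname accessors
#' @export
setGeneric("wmMap", function(x) standardGeneric("wmMap"))
#' @rdname accessors
#' @export
setGeneric("csfMap", function(x) standardGeneric("csfMap"))

#' @rdname accessors
setMethod("voxelSize", "BrainVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "RegionAtlas", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "TissueMaps", function(x) x@voxelSize)
#' @rdname accessors
setMethod("imgData", "BrainVolume", function(x) x@data)
#' @rdname accessors
setMethod("regionLabels", "RegionAtlas", function(x) x@labels)
#' @rdname accessors
setMethod("regionTable", "RegionAtlas", function(x) x@regionTable)
#' @rdname accessors
setMethod("compositeId", "RegionAtlas", function(x) x@compositeId)
#' @rdname accessors
setMethod("gmMap", "TissueMaps", function(x) x@gm)
#' @rdname accessors
setMethod("wmMap", "TissueMaps", function(x) x@wm)
#' @rdname accessors
setMethod("csfMap", "TissueMaps", function(x) x@csf)

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainVolume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "RegionAtlas", function(object) {
  d <- dim(object@labels)
  n <- nrow(object@regionTable)
  cat(sprintf("RegionAtlas: %d x %d x %d voxels, %d parcel(s) + composite (id %d)\n",
              d[1], d[2], d[3], n, object@compositeId))
  cat(sprintf("  %d voxels labelled, %d in composite parcels\n",
              sum(object@labels > 0),
              sum(object@labels %in%
                  object@regionTable$region_id[object@regionTable$in_composite])))
})

setMethod("show", "TissueMaps", function(object) {
  d <- dim(object@gm)
  cat(sprintf("TissueMaps: %d x %d x %d voxels; GM/WM/CSF volumes %.0f / %.0f / %.0f mm^3\n",
              d[1], d[2], d[3],
              sum(object@gm) * prod(object@voxelSize),
              sum(object@wm) * prod(object@voxelSize),
              sum(object@csf) * prod(object@voxelSize)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  grid %s voxels @ %s mm, K = %d regions, seed %d\n",
              paste(object@gridShape, collapse = "x"),
              paste(signif(object@voxelSizeMm, 3), collapse = "x"),
              object@nRegions, object@seed))
  cat(sprintf("  n: HC %d / mild %d / moderate %d\n",
              object@groupSizes["HC"], object@groupSizes["mild"],
              object@groupSizes["moderate"]))
  cat(sprintf("  atrophy alpha: %s; disruption rho: %s\n",
              paste(signif(object@atrophy, 3), collapse = "/"),
              paste(signif(object@disruption, 3), collapse = "/")))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@manifest$group)
  cat(sprintf("SyntheticCohort: %d subjects (%s)\n",
              nrow(object@manifest),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  shared atlas with %d parcels on %s grid\n",
              nrow(object@atlas@regionTable),
              paste(dim(object@atlas@labels), collapse = "x")))
})
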
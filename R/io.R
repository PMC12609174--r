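# NIfTI / CSV readers and writers plus grid-alignment checks.
#
# Affines are carried opaquely: this package requires pre-aligned
# image/atlas pairs and performs no resampling or registration.

#' Read and write 3D volumes as NIfTI-1
#'
#' `readVolume()` loads a `.nii`/`.nii.gz` file into a
#' [BrainVolume-class], validating that every voxel is finite;
#' `writeVolume()` writes one back. Voxel sizes are taken from the NIfTI
#' header.
#'
#' @param path file path.
#' @param x a [BrainVolume-class].
#' @return `readVolume()` a [BrainVolume-class]; `writeVolume()` the path,
#'   invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume in ", path)
  vs <- RNifti::pixdim(img)[1:3]
  brainVolume(arr, voxelSize = vs)
}

#' @rdname readVolume
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "BrainVolume"))
  img <- RNifti::asNifti(x@data, internal = FALSE)
  RNifti::pixdim(img) <- x@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label atlas with its region table
#'
#' The atlas volume must contain non-negative integer labels (0 =
#' background); the region table CSV must provide `region_id`, `name` and
#' `in_composite` columns.
#'
#' @param path NIfTI path of the label volume.
#' @param regionTablePath CSV path of the region table; if omitted, a table
#'   is derived from the labels present with all parcels in the composite.
#' @param compositeId reserved composite id (default `max(region_id) + 1`).
#' @return A [RegionAtlas-class].
#' @export
readAtlas <- function(path, regionTablePath = NULL, compositeId = NULL) {
  vol <- readVolume(path)
  arr <- vol@data
  if (any(arr < 0) || max(abs(arr - round(arr))) > 1e-6)
    stop("atlas voxels must be non-negative integers: ", path)
  arr <- round(arr)
  storage.mode(arr) <- "integer"
  rt <- NULL
  if (!is.null(regionTablePath)) {
    rt <- utils::read.csv(regionTablePath, stringsAsFactors = FALSE)
    rt$in_composite <- as.logical(rt$in_composite)
  }
  regionAtlas(arr, regionTable = rt, compositeId = compositeId,
              voxelSize = vol@voxelSize)
}

#' Read a subject manifest
#'
#' Expects columns `subject_id`, `group`, `age`, `sex`; `group` must come
#' from the closed set HC / mild / moderate and `sex` from female / male.
#'
#' @param path CSV path.
#' @return data.frame of subject records.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  bad <- which(!m$group %in% .groups)
  if (length(bad))
    stop("manifest row(s) ", paste(bad, collapse = ", "),
         " have unknown group label(s): ",
         paste(unique(m$group[bad]), collapse = ", "))
  badSex <- which(!m$sex %in% c("female", "male"))
  if (length(badSex))
    stop("manifest row(s) ", paste(badSex, collapse = ", "),
         " have invalid sex entries")
  if (any(!is.finite(m$age)) || any(m$age <= 0))
    stop("ages must be positive")
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject ids in manifest")
  m
}

#' Check that an image and an atlas share one grid
#'
#' @param volume a [BrainVolume-class] (or [TissueMaps-class]).
#' @param atlas a [RegionAtlas-class].
#' @return Invisibly `TRUE`; stops with an alignment error otherwise.
#' @export
checkAligned <- function(volume, atlas) {
  d <- if (is(volume, "TissueMaps")) dim(volume@gm) else dim(volume@data)
  if (!identical(d, dim(regionLabels(atlas))))
    stop("image grid ", paste(d, collapse = "x"),
         " does not match atlas grid ",
         paste(dim(regionLabels(atlas)), collapse = "x"))
  invisible(TRUE)
}

#' Long-format feature tables
#'
#' The feature table is the hinge between imaging and statistics: one row
#' per (subject, region, measure) with `measure` in
#' `{autocorrelation, volume}` and `value` possibly `NA` (missing values
#' are carried explicitly, never dropped). `writeFeatureTable()` /
#' `readFeatureTable()` round-trip it through CSV;
#' `validateFeatureTable()` enforces the schema.
#'
#' @param table a feature table data.frame.
#' @param path CSV path.
#' @return `readFeatureTable()` the validated data.frame;
#'   `writeFeatureTable()` the path invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  validateFeatureTable(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateFeatureTable(t)
  t
}

#' @rdname writeFeatureTable
#' @export
validateFeatureTable <- function(table) {
  need <- c("subject_id", "region_id", "measure", "value")
  if (!all(need %in% names(table)))
    stop("feature table needs columns ", paste(need, collapse = ", "))
  if (!all(table$measure %in% c("autocorrelation", "volume")))
    stop("measure must be 'autocorrelation' or 'volume'")
  key <- paste(table$subject_id, table$region_id, table$measure)
  if (anyDuplicated(key))
    stop("duplicate (subject, region, measure) rows in feature table")
  invisible(table)
}

#' Convert a feature table to a SummarizedExperiment
#'
#' Regions become rows, subjects columns, and each measure an assay; the
#' manifest is attached as column data. Useful for interoperating with
#' Bioconductor tooling.
#'
#' @param table long-format feature table.
#' @param manifest subject manifest data.frame.
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay
#'   per measure present.
#' @export
featureSummarizedExperiment <- function(table, manifest) {
  validateFeatureTable(table)
  subjects <- manifest$subject_id
  regions <- sort(unique(table$region_id))
  assays <- lapply(split(table, table$measure), function(t) {
    m <- matrix(NA_real_, nrow = length(regions), ncol = length(subjects),
                dimnames = list(as.character(regions), subjects))
    m[cbind(as.character(t$region_id), t$subject_id)] <- t$value
    m
  })
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(manifest, row.names = manifest$subject_id))
}
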
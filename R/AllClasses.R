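#' @import methods
NULL

#' BrainVolume: a 3D intensity image with voxel geometry
#'
#' Container for a single-subject 3D scalar image (e.g. a T1-weighted MRI or
#' a tissue-density map) together with its voxel spacing. All region-wise
#' feature computations operate on this unit. Voxel indexing is 0-based in
#' documentation of offsets; arrays follow R's native column-major layout.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#'
#' @seealso [brainVolume()], [RegionAtlas-class]
#' @export
setClass("BrainVolume",
  slots = c(data = "array", voxelSize = "numeric"))

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive finite reals")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "image contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a BrainVolume
#'
#' @param data 3D numeric array.
#' @param voxelSize numeric(3) voxel edge lengths in mm (default 1 mm
#'   isotropic, the common T1 acquisition resolution).
#' @return A [BrainVolume-class] object.
#' @examples
#' v <- brainVolume(array(rnorm(8^3), dim = c(8, 8, 8)))
#' voxelSize(v)
#' @export
brainVolume <- function(data, voxelSize = c(1, 1, 1)) {
  new("BrainVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' RegionAtlas: an integer parcellation aligned to an image grid
#'
#' Labels every voxel with a region id (0 = background). The region table
#' lists the parcels; parcels flagged `in_composite` are additionally pooled
#' into one composite super-region (the analogue of a composite
#' frontotemporal ROI built from many subregions), analysed alongside the
#' individual parcels under the reserved `compositeId`.
#'
#' @slot labels 3D integer array of region labels, 0 = background.
#' @slot regionTable data.frame with columns `region_id`, `name`,
#'   `in_composite`.
#' @slot compositeId integer id reserved for the composite region (not a
#'   label value present in `labels`).
#' @slot voxelSize numeric(3) voxel edge lengths in mm.
#'
#' @seealso [regionAtlas()], [makeAtlas()]
#' @export
setClass("RegionAtlas",
  slots = c(labels = "array", regionTable = "data.frame",
            compositeId = "integer", voxelSize = "numeric"))

setValidity("RegionAtlas", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  lv <- object@labels
  if (any(lv < 0) || any(lv != round(lv)))
    msg <- c(msg, "labels must be non-negative integers")
  rt <- object@regionTable
  need <- c("region_id", "name", "in_composite")
  if (!all(need %in% names(rt)))
    msg <- c(msg, "regionTable needs columns region_id, name, in_composite")
  else {
    if (anyDuplicated(rt$region_id))
      msg <- c(msg, "region ids must be unique")
    if (0L %in% rt$region_id)
      msg <- c(msg, "region id 0 is reserved for background")
    present <- setdiff(unique(as.integer(lv)), 0L)
    if (!all(present %in% rt$region_id))
      msg <- c(msg, "labels contain ids absent from regionTable")
    if (object@compositeId %in% rt$region_id ||
        object@compositeId %in% present)
      msg <- c(msg, "compositeId must not collide with a parcel id")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive reals")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionAtlas
#'
#' @param labels 3D integer array (0 = background).
#' @param regionTable data.frame with `region_id`, `name`, `in_composite`;
#'   built automatically from the labels present if omitted.
#' @param compositeId reserved id for the composite region; defaults to
#'   `max(region_id) + 1`.
#' @param voxelSize numeric(3) voxel size in mm.
#' @return A [RegionAtlas-class].
#' @export
regionAtlas <- function(labels, regionTable = NULL, compositeId = NULL,
                        voxelSize = c(1, 1, 1)) {
  storage.mode(labels) <- "integer"
  if (is.null(regionTable)) {
    ids <- sort(setdiff(unique(as.integer(labels)), 0L))
    regionTable <- data.frame(region_id = ids,
                              name = sprintf("region_%03d", ids),
                              in_composite = TRUE)
  }
  if (is.null(compositeId))
    compositeId <- max(regionTable$region_id, 0L) + 1L
  new("RegionAtlas", labels = labels, regionTable = regionTable,
      compositeId = as.integer(compositeId),
      voxelSize = as.numeric(voxelSize))
}

#' TissueMaps: GM/WM/CSF probability maps on one grid
#'
#' Voxel-wise tissue probabilities in `[0, 1]` whose sum is at most 1 (the
#' remainder being non-brain). These play the role of modulated, normalised
#' segmentation output; regional grey-matter volume and intracranial volume
#' are computed from them.
#'
#' @slot gm,wm,csf 3D numeric arrays in `[0, 1]`, identical shape.
#' @slot voxelSize numeric(3) voxel edge lengths in mm.
#' @seealso [tissueMaps()], [regionalVolume()], [icv()]
#' @export
setClass("TissueMaps",
  slots = c(gm = "array", wm = "array", csf = "array", voxelSize = "numeric"))

setValidity("TissueMaps", function(object) {
  msg <- character()
  d <- dim(object@gm)
  if (length(d) != 3L) msg <- c(msg, "gm must be a 3D array")
  if (!identical(d, dim(object@wm)) || !identical(d, dim(object@csf)))
    msg <- c(msg, "gm, wm, csf shapes must match")
  rng <- range(object@gm, object@wm, object@csf)
  if (rng[1] < 0 || rng[2] > 1 + 1e-8)
    msg <- c(msg, "tissue probabilities must lie in [0, 1]")
  tol <- 1e-6
  if (length(msg) == 0 &&
      max(object@gm + object@wm + object@csf) > 1 + tol)
    msg <- c(msg, "gm + wm + csf exceeds 1 somewhere")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive reals")
  if (length(msg)) msg else TRUE
})

#' Construct TissueMaps
#' @param gm,wm,csf 3D arrays of tissue probabilities.
#' @param voxelSize numeric(3) voxel size in mm.
#' @return A [TissueMaps-class].
#' @export
tissueMaps <- function(gm, wm, csf, voxelSize = c(1, 1, 1)) {
  new("TissueMaps", gm = gm, wm = wm, csf = csf,
      voxelSize = as.numeric(voxelSize))
}

#' SyntheticConfig: the truth parameters of a phantom cohort
#'
#' Describes the study conditions under which a synthetic cohort is drawn:
#' grid geometry, number of regions, per-group sample sizes, grey-matter
#' atrophy fractions (alpha), microlesion disruption fractions (rho), age
#' and sex distributions, and noise structure. Defaults mirror a three-group
#' dementia-staging cohort (33 controls, 21 mild, 11 moderate) with
#' progressive microstructural disruption.
#'
#' @slot gridShape integer(3) grid dimensions in voxels.
#' @slot voxelSizeMm numeric(3) voxel size in mm.
#' @slot nRegions integer, number of atlas parcels K.
#' @slot groupSizes named integer vector over `HC`, `mild`, `moderate`.
#' @slot baselineGm mean grey-matter density in regions, in (0, 1].
#' @slot atrophy named numeric, fractional GM reduction alpha per group in
#'   `[0, 1)`.
#' @slot disruption named numeric, fraction rho of in-region voxels replaced
#'   by hypointense microlesions, per group, in `[0, 1)`.
#' @slot lesionIntensityFactor multiplier in `[0, 1)` applied to lesioned
#'   voxel intensities.
#' @slot pvFraction fraction of in-region voxels carrying partial-volume
#'   (CSF-contaminated) intensity in every subject, in `[0, 0.5)`. These
#'   anchor the low end of each ROI's intensity range so that healthy
#'   tissue occupies the upper grey levels after per-ROI quantisation.
#' @slot ageMean,ageSd named numerics, per-group age distribution (years).
#' @slot ageSlope signed GM-density change per year of age.
#' @slot sexProbFemale named numeric, per-group probability of female sex.
#' @slot subjectGmSd between-subject standard deviation of baseline GM
#'   density (biological heterogeneity; gives groups overlapping volume
#'   distributions).
#' @slot subjectRhoSd between-subject standard deviation of the disruption
#'   fraction (individual variability of microstructural burden).
#' @slot noiseSd standard deviation of the additive noise components.
#' @slot smoothFwhmMm correlation length (FWHM, mm) of the smooth baseline
#'   random field.
#' @slot seed integer RNG seed.
#' @seealso [syntheticConfig()], [simulateCohort()]
#' @export
setClass("SyntheticConfig",
  slots = c(gridShape = "integer", voxelSizeMm = "numeric",
            nRegions = "integer", groupSizes = "integer",
            baselineGm = "numeric", atrophy = "numeric",
            disruption = "numeric", lesionIntensityFactor = "numeric",
            pvFraction = "numeric",
            ageMean = "numeric", ageSd = "numeric", ageSlope = "numeric",
            sexProbFemale = "numeric", subjectGmSd = "numeric",
            subjectRhoSd = "numeric", noiseSd = "numeric",
            smoothFwhmMm = "numeric", seed = "integer"))

.groups <- c("HC", "mild", "moderate")

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be 3 positive reals")
  if (object@nRegions < 1L)
    msg <- c(msg, "nRegions must be >= 1")
  for (s in c("groupSizes", "atrophy", "disruption", "ageMean", "ageSd",
              "sexProbFemale")) {
    v <- slot(object, s)
    if (!all(.groups %in% names(v)))
      msg <- c(msg, sprintf("%s must be named over %s", s,
                            paste(.groups, collapse = ", ")))
  }
  if (any(object@groupSizes < 0))
    msg <- c(msg, "group sizes must be non-negative")
  if (any(object@atrophy < 0 | object@atrophy >= 1))
    msg <- c(msg, "atrophy fractions must lie in [0, 1)")
  if (any(object@disruption < 0 | object@disruption >= 1))
    msg <- c(msg, "disruption fractions must lie in [0, 1)")
  if (object@lesionIntensityFactor < 0 || object@lesionIntensityFactor >= 1)
    msg <- c(msg, "lesionIntensityFactor must lie in [0, 1)")
  if (object@pvFraction < 0 || object@pvFraction >= 0.5)
    msg <- c(msg, "pvFraction must lie in [0, 0.5)")
  if (any(object@sexProbFemale < 0 | object@sexProbFemale > 1))
    msg <- c(msg, "sexProbFemale must lie in [0, 1]")
  if (object@baselineGm <= 0 || object@baselineGm > 1)
    msg <- c(msg, "baselineGm must lie in (0, 1]")
  if (object@subjectGmSd < 0) msg <- c(msg, "subjectGmSd must be >= 0")
  if (object@subjectRhoSd < 0) msg <- c(msg, "subjectRhoSd must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@smoothFwhmMm < 0) msg <- c(msg, "smoothFwhmMm must be >= 0")
  if (length(msg)) msg else TRUE
})

.namedOverGroups <- function(x, what) {
  if (length(x) == 1L && is.null(names(x)))
    x <- stats::setNames(rep(x, 3L), .groups)
  if (!all(.groups %in% names(x)))
    stop(what, " must be a single value or named over HC, mild, moderate")
  x[.groups]
}

#' Construct a SyntheticConfig
#'
#' Per-group parameters accept either a single value (recycled over the
#' three groups) or a named vector over `HC`, `mild`, `moderate`. The
#' defaults encode the reference study conditions: group sizes 33/21/11;
#' ages 63.1 +/- 7.9, 61.5 +/- 8.5 and 64.4 +/- 9.3 years; female
#' proportions 0.363, 0.047 and 0.181; no atrophy or disruption in
#' controls; mild atrophy in both patient groups (alpha 0.15 vs 0.18) but
#' clearly progressive microlesion disruption (rho 0.10 vs 0.30), so that
#' disease stage separates on texture more than on volume.
#'
#' @param gridShape integer(3); default `c(48, 48, 48)` voxels.
#' @param voxelSizeMm numeric(3); default 1 mm isotropic.
#' @param nRegions number of parcels K; default 8.
#' @param groupSizes named integer vector; default `c(HC=33, mild=21, moderate=11)`.
#' @param baselineGm default 0.8.
#' @param atrophy per-group alpha; default `c(HC=0, mild=0.15, moderate=0.18)`.
#' @param disruption per-group rho; default `c(HC=0, mild=0.10, moderate=0.30)`.
#' @param lesionIntensityFactor default 0.3.
#' @param pvFraction baseline partial-volume fraction present in all
#'   groups; default 0.05.
#' @param ageMean,ageSd per-group age distribution (years).
#' @param ageSlope GM-density change per year; default -0.002.
#' @param sexProbFemale per-group female probability.
#' @param subjectGmSd between-subject sd of baseline GM density; default
#'   0.06 (groups overlap rather than separate perfectly).
#' @param subjectRhoSd between-subject sd of the disruption fraction;
#'   default 0.05.
#' @param noiseSd default 0.05.
#' @param smoothFwhmMm default 4 mm.
#' @param seed integer seed; default 1.
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(gridShape = c(16, 16, 16), nRegions = 2,
#'                        groupSizes = c(HC = 2, mild = 2, moderate = 2))
#' cfg
#' @export
syntheticConfig <- function(gridShape = c(48L, 48L, 48L),
                            voxelSizeMm = c(1, 1, 1),
                            nRegions = 8L,
                            groupSizes = c(HC = 33L, mild = 21L, moderate = 11L),
                            baselineGm = 0.8,
                            atrophy = c(HC = 0, mild = 0.15, moderate = 0.18),
                            disruption = c(HC = 0, mild = 0.10, moderate = 0.30),
                            lesionIntensityFactor = 0.3,
                            pvFraction = 0.05,
                            ageMean = c(HC = 63.1, mild = 61.5, moderate = 64.4),
                            ageSd = c(HC = 7.9, mild = 8.5, moderate = 9.3),
                            ageSlope = -0.002,
                            sexProbFemale = c(HC = 0.363, mild = 0.047,
                                              moderate = 0.181),
                            subjectGmSd = 0.06,
                            subjectRhoSd = 0.05,
                            noiseSd = 0.05,
                            smoothFwhmMm = 4,
                            seed = 1L) {
  gs <- .namedOverGroups(groupSizes, "groupSizes")
  new("SyntheticConfig",
      gridShape = as.integer(gridShape),
      voxelSizeMm = as.numeric(voxelSizeMm),
      nRegions = as.integer(nRegions),
      groupSizes = stats::setNames(as.integer(gs), names(gs)),
      baselineGm = baselineGm,
      atrophy = .namedOverGroups(atrophy, "atrophy"),
      disruption = .namedOverGroups(disruption, "disruption"),
      lesionIntensityFactor = lesionIntensityFactor,
      pvFraction = pvFraction,
      ageMean = .namedOverGroups(ageMean, "ageMean"),
      ageSd = .namedOverGroups(ageSd, "ageSd"),
      ageSlope = ageSlope,
      sexProbFemale = .namedOverGroups(sexProbFemale, "sexProbFemale"),
      subjectGmSd = subjectGmSd,
      subjectRhoSd = subjectRhoSd,
      noiseSd = noiseSd,
      smoothFwhmMm = smoothFwhmMm,
      seed = as.integer(seed))
}

#' SyntheticCohort: a generated phantom study
#'
#' Bundles everything one draw of the generator produces: the subject
#' manifest, per-subject intensity images and tissue maps, the shared atlas,
#' and the truth configuration used.
#'
#' @slot manifest data.frame with `subject_id`, `group`, `age`, `sex`.
#' @slot images named list of [BrainVolume-class], one per subject.
#' @slot gmMaps named list of [TissueMaps-class], one per subject.
#' @slot atlas shared [RegionAtlas-class].
#' @slot config the [SyntheticConfig-class] truth.
#' @seealso [simulateCohort()]
#' @export
setClass("SyntheticCohort",
  slots = c(manifest = "data.frame", images = "list", gmMaps = "list",
            atlas = "RegionAtlas", config = "SyntheticConfig"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- object@manifest$subject_id
  if (anyDuplicated(ids)) msg <- c(msg, "subject ids must be unique")
  if (!identical(sort(names(object@images)), sort(ids)) ||
      !identical(sort(names(object@gmMaps)), sort(ids)))
    msg <- c(msg, "images and gmMaps must be named by subject_id")
  d <- dim(object@atlas@labels)
  ok <- vapply(object@images, function(v) identical(dim(v@data), d),
               logical(1))
  if (!all(ok)) msg <- c(msg, "all images must share the atlas grid")
  if (length(msg)) msg else TRUE
})
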
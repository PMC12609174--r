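# Phantom cohort generator: atlases, subjects, cohorts.
#
# The phantom emulates a three-group dementia-staging study. Two disease
# mechanisms are controlled independently:
#   * atrophy (alpha): a fractional reduction of grey-matter density inside
#     regions, which lowers measured regional volume;
#   * microlesion disruption (rho): a random fraction of in-region voxels
#     whose T1 intensity is multiplied by a hypointense factor, which
#     degrades spatial texture (GLCM autocorrelation) while leaving the
#     tissue-probability maps - and hence measured volume - untouched.
# Keeping the two mechanisms orthogonal lets cohorts be built in which
# disease stage separates on texture but not on volume, the dissociation
# the analysis pipeline is designed to detect.

#' Build a deterministic phantom atlas
#'
#' Places `K` disjoint ellipsoidal parcels on a regular lattice inside an
#' ellipsoidal brain mask, label 0 outside parcels. Placement is a
#' deterministic function of the configuration, so identical configurations
#' yield identical atlases. All parcels are flagged as members of the
#' composite super-region (the union of all K parcels), which is analysed
#' under the reserved `compositeId`.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [RegionAtlas-class] whose parcels each contain at least 27
#'   voxels.
#' @examples
#' atl <- makeAtlas(syntheticConfig(gridShape = c(24, 24, 24), nRegions = 4))
#' regionTable(atl)
#' @export
makeAtlas <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  d <- config@gridShape
  K <- config@nRegions
  # lattice of parcel centres inside the central 60% of the brain ellipsoid
  per <- ceiling(K^(1 / 3))
  centres <- as.matrix(expand.grid(x = seq_len(per), y = seq_len(per),
                                   z = seq_len(per)))[seq_len(K), , drop = FALSE]
  lattice_pos <- function(i, n, extent)
    extent / 2 + (i - (n + 1) / 2) * extent * 0.6 / max(n, 1)
  cx <- lattice_pos(centres[, 1], per, d[1])
  cy <- lattice_pos(centres[, 2], per, d[2])
  cz <- lattice_pos(centres[, 3], per, d[3])
  spacing <- min(d * 0.6 / per)
  radius <- spacing * 0.45
  if (4 / 3 * pi * radius^3 < 27)
    stop("grid too small to fit ", K, " regions of usable size ",
         "(each parcel needs >= 27 voxels)")
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  labels <- array(0L, dim = d)
  for (k in seq_len(K)) {
    dx2 <- outer(outer((ix - cx[k])^2, (iy - cy[k])^2, "+"),
                 (iz - cz[k])^2, "+")
    labels[dx2 <= radius^2] <- k
  }
  counts <- tabulate(labels, nbins = K)
  if (any(counts < 27))
    stop("grid too small to fit ", K, " regions of usable size")
  rt <- data.frame(region_id = seq_len(K),
                   name = sprintf("region_%03d", seq_len(K)),
                   in_composite = TRUE)
  regionAtlas(labels, rt, compositeId = K + 1L,
              voxelSize = config@voxelSizeMm)
}

# Ellipsoidal brain mask enclosing the parcel lattice.
.brainMask <- function(gridShape) {
  d <- gridShape
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  r <- d * 0.48
  e <- outer(outer(((ix - d[1] / 2) / r[1])^2, ((iy - d[2] / 2) / r[2])^2,
                   "+"), ((iz - d[3] / 2) / r[3])^2, "+")
  e <= 1
}

#' Simulate one phantom subject
#'
#' Draws age and sex from the group's distributions, builds a grey-matter
#' density field (baseline scaled by `1 - alpha_g` inside regions, a linear
#' age effect, a smooth random field and white noise), derives tissue maps
#' from that density, and finally implants hypointense voxels in the
#' intensity image: a baseline partial-volume fraction (`pvFraction`,
#' common to all groups) plus the group's microlesion fraction `rho_g`,
#' each with T1 intensity multiplied by `lesionIntensityFactor`. These
#' perturb only the intensity image: they model partial-volume
#' contamination and sub-voxel microstructural disruption visible to
#' texture analysis but below the resolution of volumetry. With
#' `pvFraction`, `rho_g`, `noiseSd` and `ageSlope` all zero the in-region
#' intensity is exactly constant at the atrophy-scaled baseline.
#'
#' Uses the R session's current RNG stream; seed externally (as
#' [simulateCohort()] does) for reproducibility.
#'
#' @param config a [SyntheticConfig-class].
#' @param atlas the shared [RegionAtlas-class].
#' @param group one of `"HC"`, `"mild"`, `"moderate"`.
#' @param subjectId subject identifier string.
#' @return A list with `record` (one-row manifest data.frame), `image`
#'   ([BrainVolume-class], T1-like arbitrary units) and `maps`
#'   ([TissueMaps-class]).
#' @export
simulateSubject <- function(config, atlas, group, subjectId = "S001") {
  if (!group %in% .groups)
    stop("unknown group label: ", group)
  d <- config@gridShape
  age <- stats::rnorm(1, config@ageMean[group], config@ageSd[group])
  age <- max(age, 18)
  sex <- if (stats::runif(1) < config@sexProbFemale[group]) "female" else "male"

  inRegion <- regionLabels(atlas) > 0L
  brain <- .brainMask(d)
  cohortMeanAge <- stats::weighted.mean(
    config@ageMean, pmax(config@groupSizes, if (all(config@groupSizes == 0)) 1 else 0))

  density <- array(0, dim = d)
  # subject-level biological heterogeneity: baseline GM density offset
  gmOffset <- if (config@subjectGmSd > 0)
    stats::rnorm(1, 0, config@subjectGmSd) else 0
  base <- config@baselineGm * (1 - config@atrophy[group]) + gmOffset +
    config@ageSlope * (age - cohortMeanAge)
  density[inRegion] <- base
  if (config@noiseSd > 0) {
    smoothField <- gaussianSmooth(array(stats::rnorm(prod(d)), dim = d),
                                  config@smoothFwhmMm, config@voxelSizeMm)
    sdv <- stats::sd(smoothField)
    if (sdv > 0) smoothField <- smoothField / sdv * config@noiseSd
    white <- array(stats::rnorm(prod(d), sd = config@noiseSd), dim = d)
    density[inRegion] <- density[inRegion] + smoothField[inRegion] +
      white[inRegion]
  }
  density <- pmin(pmax(density, 0), 1)
  density[!inRegion] <- 0

  # tissue maps reflect the pre-lesion density (volume channel)
  gm <- density
  wm <- array(0, dim = d); csf <- array(0, dim = d)
  wm[brain] <- 0.8 * (1 - density[brain])
  csf[brain] <- 0.2 * (1 - density[brain])
  maps <- tissueMaps(gm, wm, csf, voxelSize = config@voxelSizeMm)

  # Intensity image: density on a plausible T1 scale. Two kinds of
  # hypointense voxels are implanted: a baseline partial-volume fraction
  # (pvFraction, identical across groups) that anchors the low end of
  # every ROI's intensity range so healthy tissue occupies the upper grey
  # levels after per-ROI quantisation, plus the group's microlesion
  # fraction rho on top of it.
  intensity <- 300 + 700 * density
  intensity[!brain] <- 0
  rhoSubj <- config@disruption[group]
  if (config@subjectRhoSd > 0 && rhoSubj + config@pvFraction > 0)
    rhoSubj <- min(0.9, max(0, rhoSubj +
                              stats::rnorm(1, 0, config@subjectRhoSd)))
  lowFrac <- config@pvFraction + rhoSubj
  if (lowFrac > 0) {
    idx <- which(inRegion)
    nlow <- round(lowFrac * length(idx))
    if (nlow > 0) {
      low <- sample(idx, nlow)
      intensity[low] <- intensity[low] * config@lesionIntensityFactor
    }
  }
  image <- brainVolume(intensity, voxelSize = config@voxelSizeMm)

  record <- data.frame(subject_id = subjectId, group = group,
                       age = age, sex = sex, stringsAsFactors = FALSE)
  list(record = record, image = image, maps = maps)
}

#' Simulate a full phantom cohort
#'
#' Builds the shared atlas and draws every subject across the three groups
#' from a generator seeded by `config@seed`; two calls with the same
#' configuration are identical.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [SyntheticCohort-class].
#' @examples
#' cfg <- syntheticConfig(gridShape = c(20, 20, 20), nRegions = 2,
#'                        groupSizes = c(HC = 2, mild = 2, moderate = 2))
#' coh <- simulateCohort(cfg)
#' coh
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  atlas <- makeAtlas(config)
  groups <- rep(names(config@groupSizes), times = config@groupSizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  images <- vector("list", n); maps <- vector("list", n)
  records <- vector("list", n)
  withr::with_seed(config@seed, {
    for (i in seq_len(n)) {
      s <- simulateSubject(config, atlas, groups[i], ids[i])
      records[[i]] <- s$record
      images[[i]] <- s$image
      maps[[i]] <- s$maps
    }
  })
  names(images) <- ids; names(maps) <- ids
  new("SyntheticCohort",
      manifest = do.call(rbind, records),
      images = images, gmMaps = maps, atlas = atlas, config = config)
}

#' Write a cohort to disk
#'
#' Writes NIfTI-1 volumes (per-subject T1-like image and GM/WM/CSF maps,
#' plus the shared atlas), a CSV manifest and a JSON copy of the truth
#' configuration.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- cohort@config@voxelSizeMm
  writeVolume(brainVolume(array(as.numeric(regionLabels(cohort@atlas)),
                                dim = dim(regionLabels(cohort@atlas))),
                          voxelSize = vs),
              file.path(dir, "atlas.nii.gz"))
  utils::write.csv(regionTable(cohort@atlas),
                   file.path(dir, "atlas_regions.csv"), row.names = FALSE)
  for (id in cohort@manifest$subject_id) {
    writeVolume(cohort@images[[id]], file.path(dir, paste0(id, "_T1.nii.gz")))
    m <- cohort@gmMaps[[id]]
    writeVolume(brainVolume(gmMap(m), vs), file.path(dir, paste0(id, "_gm.nii.gz")))
    writeVolume(brainVolume(wmMap(m), vs), file.path(dir, paste0(id, "_wm.nii.gz")))
    writeVolume(brainVolume(csfMap(m), vs), file.path(dir, paste0(id, "_csf.nii.gz")))
  }
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort@manifest, mpath, row.names = FALSE)
  cfg <- cohort@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  jsonlite::write_json(cfgList, file.path(dir, "truth_config.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(mpath)
}
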
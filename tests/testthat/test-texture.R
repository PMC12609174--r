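# GLCM texture pipeline: normalisation, quantisation, co-occurrence,
# autocorrelation, region-wise extraction.

test_that("ROI normalisation clips at mu +/- k sigma and flags degeneracy", {
  v <- 0:10
  n <- normalizeRoi(v, quantizationSpec())
  expect_equal(n$values, as.numeric(v))  # all within mu +/- 3 sigma
  expect_equal(n$nClipped, 0L)
  expect_false(n$degenerate)

  const <- normalizeRoi(rep(4, 50))
  expect_true(const$degenerate)
  expect_equal(const$sigma, 0)
  expect_equal(const$values, rep(4, 50))

  # one voxel far above the bulk gets clipped to exactly mu + 3 sigma
  set.seed(1)
  bulk <- rnorm(200)
  v2 <- c(bulk, mean(bulk) + 10 * sd(bulk))
  n2 <- normalizeRoi(v2)
  hi <- n2$mu + 3 * n2$sigma
  expect_equal(max(n2$values), hi)
  expect_gte(n2$nClipped, 1L)
  expect_error(normalizeRoi(numeric(0)), "empty")
})

test_that("uniform quantisation follows the equal-width binning rule", {
  expect_identical(quantize(c(0, 1, 2, 3), quantizationSpec(nLevels = 4)),
                   1:4)
  expect_warning(q <- quantize(rep(2, 10), quantizationSpec(nLevels = 8)),
                 "degenerate")
  expect_identical(q, rep(1L, 10))
  # the maximum maps to level L exactly, and values obey the floor formula
  set.seed(2)
  for (L in c(2L, 5L, 32L)) {
    v <- runif(100, -3, 7)
    lv <- quantize(v, quantizationSpec(nLevels = L))
    expect_equal(lv[which.max(v)], L)
    expected <- pmin(L, 1 + floor(L * (v - min(v)) / (max(v) - min(v))))
    expect_equal(lv, as.integer(expected))
    expect_true(all(lv >= 1 & lv <= L))
  }
})

test_that("GLCM on a homogeneous 3x3 grid matches the hand count", {
  g <- array(1L, dim = c(3, 3, 1))
  m <- glcm(g, offsetSet("axial2"), nLevels = 3)
  expect_equal(m@nPairs, 24)  # 12 adjacencies, both orders
  expect_equal(m@p[1, 1], 1)
  expect_equal(sum(m@p), 1)
  expect_equal(autocorrelation(m), 1)
})

test_that("GLCM equals exhaustive pair enumeration on random masked grids", {
  set.seed(3)
  for (rep in 1:60) {
    L <- sample(2:8, 1)
    g <- randomLevelGrid(L = L)
    sym <- sample(c(TRUE, FALSE), 1)
    dirs <- switch(sample(3, 1),
                   rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)),
                   graytex:::.DIRS_3D13,
                   rbind(c(0L, 0L, 1L)))
    d <- sample(1:2, 1)
    os <- offsetSet(dirs, distance = d, symmetric = sym)
    m <- glcm(g, os, nLevels = L)
    oracle <- bruteGlcm(g, dirs * d, sym, L)
    expect_equal(unname(m@counts), oracle$counts)
    expect_equal(m@nPairs, oracle$nPairs)
    if (m@nPairs > 0) {
      expect_equal(unname(m@p), oracle$p)
      expect_equal(autocorrelation(m), bruteAutocorrelation(oracle$p))
    }
  }
})

test_that("single-voxel masks yield an empty GLCM and a missing feature", {
  g <- array(NA_integer_, dim = c(4, 4, 4))
  g[2, 2, 2] <- 3L
  m <- glcm(g, offsetSet(), nLevels = 4)
  expect_equal(m@nPairs, 0)
  expect_warning(v <- autocorrelation(m), "missing")
  expect_true(is.na(v))
})

test_that("autocorrelation closed forms and bounds hold", {
  # all mass at (q, q) gives q^2
  for (q in c(1L, 3L, 7L)) {
    g <- array(q, dim = c(4, 4, 2))
    m <- glcm(g, offsetSet(), nLevels = 8L)
    expect_equal(autocorrelation(m), q^2)
  }
  # uniform p over L x L gives ((L + 1) / 2)^2
  for (L in c(2L, 6L)) {
    u <- new("GLCMatrix", counts = matrix(1, L, L),
             p = matrix(1 / L^2, L, L), nPairs = L^2, nLevels = L,
             offsets = offsetSet(symmetric = TRUE))
    expect_equal(autocorrelation(u), ((L + 1) / 2)^2)
  }
  # fuzz: bounds [1, L^2] never violated
  set.seed(4)
  for (rep in 1:100) {
    L <- sample(2:8, 1)
    g <- randomLevelGrid(L = L)
    m <- glcm(g, offsetSet(), nLevels = L)
    if (m@nPairs > 0) {
      a <- autocorrelation(m)
      expect_gte(a, 1); expect_lte(a, L^2)
    }
  }
})

test_that("a lesioned toy grid scores lower autocorrelation than a homogeneous one", {
  # 3x3 in-plane grids at L = 3, horizontal + vertical offsets, d = 1:
  # preserved tissue = all level 3; neuronal loss = some voxels at level 1
  spec3 <- offsetSet("axial2")
  homog <- array(3L, dim = c(3, 3, 1))
  lesioned <- homog
  lesioned[c(1, 5, 9)] <- 1L
  aHomog <- autocorrelation(glcm(homog, spec3, nLevels = 3))
  aLes <- autocorrelation(glcm(lesioned, spec3, nLevels = 3))
  expect_equal(aHomog, 9)
  expect_lt(aLes, aHomog)
  # and both match the exhaustive oracle
  or <- bruteGlcm(lesioned, rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)), TRUE, 3)
  expect_equal(aLes, bruteAutocorrelation(or$p))
})

test_that("the texture feature is invariant to intensity shift and scale", {
  set.seed(5)
  cfg <- tinyConfig(groupSizes = c(HC = 1L, mild = 0L, moderate = 0L))
  coh <- simulateCohort(cfg)
  vol <- coh@images[[1]]
  base <- extractTexture(vol, coh@atlas)$value
  shifted <- brainVolume(vol@data + 137.5, voxelSize(vol))
  scaled <- brainVolume(vol@data * 3.25, voxelSize(vol))
  expect_equal(extractTexture(shifted, coh@atlas)$value, base)
  expect_equal(extractTexture(scaled, coh@atlas)$value, base)
})

test_that("region-wise extraction handles composites, degenerate and empty atlases", {
  set.seed(6)
  cfg <- tinyConfig(nRegions = 1L,
                    groupSizes = c(HC = 1L, mild = 0L, moderate = 0L))
  coh <- simulateCohort(cfg)
  ft <- extractTexture(coh@images[[1]], coh@atlas)
  # single region: composite row equals the region row
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$value[1], ft$value[2])

  # all-background atlas: every row missing
  labs <- array(0L, dim = c(8, 8, 8))
  emptyAtlas <- regionAtlas(labs,
                            data.frame(region_id = 1L, name = "r1",
                                       in_composite = TRUE))
  vol <- brainVolume(array(rnorm(512), dim = c(8, 8, 8)))
  ftEmpty <- suppressWarnings(extractTexture(vol, emptyAtlas))
  expect_true(all(is.na(ftEmpty$value)))

  # misaligned grids are rejected at pairing time
  expect_error(extractTexture(brainVolume(array(0, dim = c(4, 4, 4))),
                              coh@atlas), "does not match")
})

test_that("expected autocorrelation decreases with lesion fraction", {
  set.seed(7)
  means <- sapply(c(0, 0.1, 0.2, 0.3), function(rho) {
    vals <- sapply(1:20, function(s) {
      cfg <- tinyConfig(nRegions = 1L,
                        groupSizes = c(HC = 1L, mild = 0L, moderate = 0L),
                        disruption = c(HC = rho, mild = 0, moderate = 0),
                        seed = 1000L + s)
      coh <- simulateCohort(cfg)
      ft <- extractTexture(coh@images[[1]], coh@atlas)
      ft$value[1]
    })
    mean(vals)
  })
  expect_true(all(diff(means) < 0))
})
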
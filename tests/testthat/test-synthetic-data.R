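test_that("equal seeds render bit-identical scenes", {
  p <- testSceneParams(seed = 7L)
  a <- generateMitoScene(p)
  b <- generateMitoScene(p)
  expect_identical(channels(a), channels(b))
  expect_identical(truthMask(a), truthMask(b))
  expect_identical(truthLabels(a), truthLabels(b))
  expect_identical(truthCellMap(a), truthCellMap(b))
})

test_that("degenerate planted fractions give single-class scenes", {
  s1 <- generateMitoScene(testSceneParams(fragmentedFraction = 1, seed = 2L))
  expect_true(all(truthLabels(s1) == "fragmented"))
  s0 <- generateMitoScene(testSceneParams(nCells = 3L,
                                          fragmentedFraction = 0, seed = 4L))
  expect_true(all(truthLabels(s0) == "fused"))
})

test_that("planted fraction is realized up to rounding", {
  for (f in c(0.25, 0.5, 0.8)) {
    sc <- generateMitoScene(testSceneParams(fragmentedFraction = f,
                                            seed = 11L))
    n <- length(truthLabels(sc))
    expect_equal(sum(truthLabels(sc) == "fragmented"), round(f * n))
  }
})

test_that("zero-noise rendering reproduces the truth object count", {
  p <- testSceneParams(noise = list(gaussianSd = 0, poissonScale = 0),
                       seed = 3L)
  sc <- generateMitoScene(p)
  thr <- p@backgroundLevel + 0.25 * p@amplitude
  lab <- labelObjects(channels(sc)$mito > thr)
  expect_equal(max(lab), max(truthMask(sc)))
})

test_that("generator contract: class geometry is separable", {
  sc <- generateMitoScene(testSceneParams(seed = 7L))
  f <- measureObjects(truthMask(sc))
  frag <- truthLabels(sc) == "fragmented"
  expect_gt(mean(f$formfactor[frag]), mean(f$formfactor[!frag]))
  expect_lt(mean(f$area_px[frag]), mean(f$area_px[!frag]))
  # fused objects span a far wider size range
  expect_gt(var(f$area_px[!frag]), var(f$area_px[frag]))
})

test_that("impossible packing is rejected with an informative error", {
  p <- testSceneParams(imageSize = c(96L, 96L), nCells = 4L,
                       objectsPerCell = c(40L, 40L), seed = 1L)
  expect_error(generateMitoScene(p), "overlap")
})

test_that("scene params validity catches bad ranges", {
  expect_error(sceneParams(fragmentedFraction = 1.2), "fragmentedFraction")
  expect_error(sceneParams(fragmentedShape = list(
    areaRange = c(80, 20), eccentricityRange = c(0, 0.5))), "areaRange")
})

test_that("MMP time-lapse renders planted trajectories and deaths", {
  p <- testSceneParams(imageSize = c(128L, 128L), nCells = 10L,
                       nucleusRadius = 6,
                       noise = list(gaussianSd = 5, poissonScale = 0),
                       seed = 21L)
  truth <- timelapseTruth(10L, nFrames = 3L, baseline = 1000,
                          nDead = 3L, deathOnset = 2L, piFraction = 0.15,
                          seed = 21L)
  tl <- generateMmpTimelapse(p, truth)
  mm <- measureMmpTimecourse(tl$frames, tl$regions, piThreshold = 1000)
  # no PI before onset, planted 0.30 dead fraction afterwards
  expect_equal(deathFraction(mm, frame = 1), 0)
  expect_equal(deathFraction(mm, frame = 3), 0.30)
  # constant planted rho123 recovered within noise tolerance
  nMin <- min(vapply(tl$regions, function(r) nrow(r$cytoplasm), numeric(1)))
  expect_lt(max(abs(mm$rho123 - 1000)), 5 * 5 / sqrt(nMin) + 1)
})

test_that("time-lapse with no dead cells keeps PI at background", {
  p <- testSceneParams(imageSize = c(96L, 96L), nCells = 4L,
                       nucleusRadius = 6,
                       noise = list(gaussianSd = 0, poissonScale = 0),
                       seed = 5L)
  truth <- timelapseTruth(4L, nFrames = 2L, seed = 5L)
  tl <- generateMmpTimelapse(p, truth)
  for (fr in tl$frames)
    expect_true(all(fr$pi == p@backgroundLevel))
})

test_that("time-lapse rejects mismatched cell counts", {
  p <- testSceneParams(imageSize = c(96L, 96L), nCells = 4L,
                       nucleusRadius = 6, seed = 5L)
  expect_error(generateMmpTimelapse(p, timelapseTruth(7L, nFrames = 2L)),
               "cells")
})

test_that("FRET pair plants the requested per-pixel ratio", {
  mask <- matrix(FALSE, 64, 64); mask[17:48, 17:48] <- TRUE
  pair <- generateFretPair(matrix(1, 64, 64), mask, gaussianSd = 0)
  expect_equal(measureFretRatio(pair$em408, pair$em488)$ratio, 1.0)
  pair <- generateFretPair(matrix(0.5, 64, 64), mask, gaussianSd = 10,
                           seed = 3L)
  expect_lt(abs(measureFretRatio(pair$em408, pair$em488)$ratio - 0.5), 0.02)
  expect_error(generateFretPair(matrix(0, 64, 64), mask), "positive")
})

test_that("feature-table sampling matches weights and is seed-stable", {
  m <- referenceGmm(weights = c(0.5, 0.5))
  expect_equal(nrow(sampleFeatureTable(m, 0L)), 0L)
  tab <- sampleFeatureTable(m, 10000L, seed = 8L)
  counts <- table(tab$component)
  expect_lt(abs(counts[[1]] - 5000), 3 * sqrt(10000 * 0.25))
  expect_identical(tab, sampleFeatureTable(m, 10000L, seed = 8L))
})

test_that("scenes round-trip through TIFF and params through YAML", {
  dir <- withr::local_tempdir()
  p <- testSceneParams(imageSize = c(96L, 96L), nCells = 2L,
                       objectsPerCell = c(3L, 5L), seed = 13L)
  sc <- generateMitoScene(p)
  paths <- writeScene(sc, dir)
  back <- readImageTiff(paths["mito"])
  expect_equal(dim(back), dim(channels(sc)$mito))
  expect_lt(max(abs(back - round(channels(sc)$mito))), 1.5)
  maskBack <- readImageTiff(paths["truth_mask"])
  expect_equal(max(maskBack), max(truthMask(sc)))
  yml <- file.path(dir, "params.yaml")
  writeSceneParams(p, yml)
  expect_equal(readSceneParams(yml), p)
})
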
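test_that("cytoplasm rings equal the nearest-nucleus brute force", {
  set.seed(31)
  for (i in 1:6) {
    nuc <- matrix(0L, 48, 48)
    n <- sample(1:3, 1)
    for (k in seq_len(n)) {
      r <- sample(8:40, 1); c <- sample(8:40, 1)
      nuc[max(1, r - 2):min(48, r + 2), max(1, c - 2):min(48, c + 2)] <- k
    }
    # skip layouts where a later nucleus overwrote an earlier one entirely
    if (length(setdiff(unique(as.integer(nuc)), 0L)) != n) next
    rg <- buildCellRegions(nuc, maxDistance = 10)
    bf <- bruteForceRegions(nuc, 10)
    for (k in seq_len(n))
      expect_true(pixelSetEqual(rg[[k]]$cytoplasm, bf[[k]]))
  }
})

test_that("single-pixel nucleus ring matches the exact disc count", {
  nuc <- matrix(0L, 41, 41); nuc[21, 21] <- 1L
  rg <- buildCellRegions(nuc, maxDistance = 10)
  # brute force: pixels with 0 < d <= 10 of the centre
  g <- expand.grid(r = 1:41, c = 1:41)
  d <- sqrt((g$r - 21)^2 + (g$c - 21)^2)
  expect_equal(nrow(rg[[1]]$cytoplasm), sum(d > 0 & d <= 10))
})

test_that("well-separated nuclei get disjoint rings; close ones split", {
  nuc <- matrix(0L, 64, 64)
  nuc[10, 10] <- 1L; nuc[10, 40] <- 2L   # 30 px apart: disjoint
  rg <- buildCellRegions(nuc, maxDistance = 10)
  k1 <- paste(rg[[1]]$cytoplasm[, 1], rg[[1]]$cytoplasm[, 2])
  k2 <- paste(rg[[2]]$cytoplasm[, 1], rg[[2]]$cytoplasm[, 2])
  expect_length(intersect(k1, k2), 0)
  nucClose <- matrix(0L, 64, 64)
  nucClose[30, 26] <- 1L; nucClose[30, 38] <- 2L   # 12 px apart: contested
  rgc <- buildCellRegions(nucClose, maxDistance = 10)
  bf <- bruteForceRegions(nucClose, 10)
  expect_true(pixelSetEqual(rgc[[1]]$cytoplasm, bf[[1]]))
  expect_true(pixelSetEqual(rgc[[2]]$cytoplasm, bf[[2]]))
  expect_identical(buildCellRegions(matrix(0L, 8, 8)), list())
})

test_that("death rule is boundary-exact at the 10% threshold", {
  nuc <- matrix(0L, 30, 30)
  nuc[11:20, 11:20] <- 1L   # nucleus of exactly 100 px
  rg <- buildCellRegions(nuc, maxDistance = 5)
  mkFrame <- function(nPi) {
    pi_ <- matrix(0, 30, 30)
    if (nPi > 0) pi_[11:20, 11:20][seq_len(nPi)] <- 100
    list(rho123 = matrix(50, 30, 30), pi = pi_)
  }
  m9 <- measureMmpTimecourse(list(mkFrame(9L)), rg, piThreshold = 50)
  m10 <- measureMmpTimecourse(list(mkFrame(10L)), rg, piThreshold = 50)
  expect_equal(m9$pi_fraction, 0.09)
  expect_false(m9$dead)
  expect_equal(m10$pi_fraction, 0.10)
  expect_true(m10$dead)
})

test_that("rho123 means are exact on noiseless planted frames", {
  nuc <- matrix(0L, 40, 40); nuc[18:22, 18:22] <- 1L
  rg <- buildCellRegions(nuc, maxDistance = 6)
  rho <- matrix(0, 40, 40)
  rho[rg[[1]]$cytoplasm] <- 1000
  m <- measureMmpTimecourse(list(list(rho123 = rho,
                                      pi = matrix(0, 40, 40))),
                            rg, piThreshold = 50)
  expect_equal(m$rho123, 1000)
  mi <- measureMmpTimecourse(list(list(rho123 = rho,
                                       pi = matrix(0, 40, 40))),
                             rg, piThreshold = 50,
                             aggregate = "integrated")
  expect_equal(mi$rho123, 1000 * nrow(rg[[1]]$cytoplasm))
})

test_that("FRET ratio handles planted, zero and degenerate cases", {
  mask <- matrix(FALSE, 48, 48); mask[13:36, 13:36] <- TRUE
  pair <- generateFretPair(matrix(1, 48, 48), mask, gaussianSd = 0)
  expect_equal(measureFretRatio(pair$em408, pair$em488)$ratio, 1.0)
  # 488 identically zero in the cell area: ratio 0, not an error
  fr <- measureFretRatio(pair$em408, matrix(0, 48, 48))
  expect_equal(fr$ratio, 0)
  # orientation switch inverts the ratio
  pair2 <- generateFretPair(matrix(0.5, 48, 48), mask, gaussianSd = 0)
  r1 <- measureFretRatio(pair2$em408, pair2$em488)$ratio
  r2 <- measureFretRatio(pair2$em408, pair2$em488,
                         orientation = "408/488")$ratio
  expect_equal(r1, 0.5, tolerance = 1e-2)
  expect_equal(r2, 1 / r1)
  # a blank 408 image has no cell area: error, never NaN
  expect_error(measureFretRatio(matrix(0, 8, 8), matrix(1, 8, 8)), "area")
})

test_that("vehicle normalization maps vehicle to 1 and scales others", {
  veh <- data.frame(timepoint = 0:3, value = c(2, 4, 8, 10))
  self <- normalizeToVehicle(veh, veh)
  expect_true(all(self$perValue$norm_value == 1))
  # normalizing an already vehicle-normalized series is the identity
  again <- normalizeToVehicle(
    data.frame(timepoint = 0:3, value = self$perValue$norm_value),
    data.frame(timepoint = 0:3, value = rep(1, 4)))
  expect_true(all(again$perValue$norm_value == 1))
  dbl <- normalizeToVehicle(
    data.frame(timepoint = 0:3, value = 2 * veh$value), veh)
  expect_true(all(dbl$perValue$norm_value == 2))
  expect_error(normalizeToVehicle(
    data.frame(timepoint = 0:1, value = 1:2),
    data.frame(timepoint = 0:1, value = c(1, 0))), "zero")
  expect_error(normalizeToVehicle(
    data.frame(timepoint = c(0, 9), value = 1:2), veh), "timepoints")
})

test_that("replicate normalization recovers a planted effect", {
  set.seed(5)
  veh <- data.frame(timepoint = 1:6, value = 100)
  sdNoise <- 4
  reps <- do.call(rbind, lapply(1:4, function(r)
    data.frame(timepoint = 1:6,
               value = 60 + rnorm(6, 0, sdNoise), replicate = r)))
  norm <- normalizeToVehicle(reps, veh)
  expect_equal(mean(norm$summary$mean), 0.6, tolerance = 0.02)
  expect_equal(mean(norm$summary$se), sdNoise / 100 / sqrt(4),
               tolerance = 0.6)
})

test_that("OPA1 cleavage ratio and nuclei normalization arithmetic", {
  expect_equal(opa1CleavageRatio(2, 2), 0.5)
  expect_equal(opa1CleavageRatio(3, 0), 1.0)
  expect_equal(opa1CleavageRatio(0, 5), 0.0)
  expect_error(opa1CleavageRatio(0, 0), "zero")
  expect_error(opa1CleavageRatio(-1, 2), "non-negative")
  expect_equal(nucleiCountNormalize(1000, 100), 10)
  expect_equal(nucleiCountNormalize(0, 50), 0)
  expect_equal(nucleiCountNormalize(2000, 200),
               nucleiCountNormalize(1000, 100))
  expect_error(nucleiCountNormalize(5, 0), ">= 1")
})
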
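squarePixels <- function(n, r0 = 1L, c0 = 1L) {
  as.matrix(expand.grid(row = r0:(r0 + n - 1L), col = c0:(c0 + n - 1L)))
}

test_that("area is the pixel count", {
  expect_equal(measureArea(squarePixels(3)), 9L)
  expect_equal(measureArea(matrix(c(5L, 5L), 1)), 1L)
  expect_error(measureArea(squarePixels(3)[0, ]), "empty")
})

test_that("perimeter counts inner and outer boundary pixels", {
  expect_equal(measurePerimeter(squarePixels(3)), 8L)   # centre is interior
  expect_equal(measurePerimeter(matrix(c(1L, 1L), 1)), 1L)
  # 5x5 square with a centre hole: 16 outer boundary pixels plus the 4
  # hole-adjacent pixels of the middle ring (edge adjacency)
  sq <- squarePixels(5)
  hole <- sq[, 1] == 3 & sq[, 2] == 3
  expect_equal(measurePerimeter(sq[!hole, ]), 20L)
  expect_equal(measurePerimeter(sq[!hole, ]),
               bruteForcePerimeter(sq[!hole, ]))
})

test_that("formfactor implements both variants", {
  expect_equal(measureFormfactor(100, 40), 4 * pi * 100 / 1600)
  expect_equal(measureFormfactor(100, 40, "literal"), 4 * pi * 100 / 40)
  expect_error(measureFormfactor(10, 0), "positive")
})

test_that("rasterized disks have near-unit standard formfactor", {
  # boundary-pixel-count perimeters undercount diagonal runs, so disks land
  # slightly above 1 (directly computed bias band; see the vignette)
  for (rad in c(5, 12, 25, 50)) {
    n <- 2 * rad + 3
    g <- expand.grid(row = 1:n, col = 1:n)
    ctr <- (n + 1) / 2
    px <- as.matrix(g[(g$row - ctr)^2 + (g$col - ctr)^2 <= rad^2, ])
    ff <- measureFormfactor(measureArea(px), measurePerimeter(px))
    expect_gt(ff, 0.9)
    expect_lt(ff, 1.4)
  }
})

test_that("solidity is 1 for convex sets and < 1 for concave ones", {
  expect_equal(measureSolidity(squarePixels(4)), 1.0)
  # plus pentomino: hull contains the 3x3 box centre pattern = 5/hull
  plus <- rbind(c(2, 1), c(1, 2), c(2, 2), c(3, 2), c(2, 3))
  colnames(plus) <- c("row", "col")
  expect_equal(measureSolidity(plus), 5 / bruteForceHullCount(plus))
  ell <- rbind(c(1, 1), c(2, 1), c(3, 1), c(3, 2), c(3, 3))
  colnames(ell) <- c("row", "col")   # L-shape: hull triangle contains (2,2)
  expect_equal(measureSolidity(ell), 5 / 6)
  expect_lt(measureSolidity(ell), 1)
  # straight line of pixels is convex at pixel resolution
  line <- cbind(row = 1:5, col = rep(2L, 5))
  expect_equal(measureSolidity(line), 1.0)
})

test_that("all four features match exhaustive oracles on random blobs", {
  set.seed(7)
  for (i in 1:40) {
    px <- randomBlob(12L)
    expect_equal(measureArea(px), nrow(px))
    expect_equal(measurePerimeter(px), bruteForcePerimeter(px))
    hull <- bruteForceHullCount(px)
    if (!is.na(hull))
      expect_equal(measureSolidity(px), nrow(px) / hull)
    a <- measureArea(px); p <- measurePerimeter(px)
    expect_equal(measureFormfactor(a, p), 4 * pi * a / p^2)
    expect_equal(measureFormfactor(a, p, "literal"), 4 * pi * a / p)
  }
})

test_that("features are invariant to translation and 90-degree rotation", {
  set.seed(8)
  for (i in 1:10) {
    px <- randomBlob(10L)
    shifted <- px + matrix(rep(c(13L, 29L), each = nrow(px)), ncol = 2)
    rotated <- cbind(row = px[, 2], col = max(px[, 1]) + 1L - px[, 1])
    for (other in list(shifted, rotated)) {
      expect_identical(measureArea(px), measureArea(other))
      expect_identical(measurePerimeter(px), measurePerimeter(other))
      expect_equal(measureSolidity(px), measureSolidity(other))
    }
  }
})

test_that("nearest-neighbour upscaling scales area x4 and perimeter ~x2", {
  upscale <- function(px) {
    up <- do.call(rbind, lapply(seq_len(nrow(px)), function(i) {
      r <- px[i, 1] * 2L; c <- px[i, 2] * 2L
      rbind(c(r - 1L, c - 1L), c(r - 1L, c), c(r, c - 1L), c(r, c))
    }))
    colnames(up) <- c("row", "col")
    up
  }
  # filled square: boundary counts are exact (4n-4 -> 8n-4)
  sq <- squarePixels(6)
  expect_equal(measureArea(upscale(sq)), 4L * measureArea(sq))
  expect_equal(measurePerimeter(sq), 20L)
  expect_equal(measurePerimeter(upscale(sq)), 44L)
  # disk: block upscaling adds stair-step corner pixels, so the boundary
  # count scales by a factor slightly above 2
  g <- expand.grid(row = 1:15, col = 1:15)
  disk <- as.matrix(g[(g$row - 8)^2 + (g$col - 8)^2 <= 36, ])
  ratio <- measurePerimeter(upscale(disk)) / measurePerimeter(disk)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.8)
})

test_that("measureObjects emits one ordered record per label", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:9, 8:11] <- TRUE
  lab <- labelObjects(m)
  f <- measureObjects(lab, metadata = list(image_id = "im1",
                                           condition = "veh", replicate = 1L))
  expect_equal(nrow(f), 2L)
  expect_equal(f$object_id, 1:2)
  expect_equal(f$area_px, c(9L, 8L))
  expect_true(all(c("image_id", "condition", "replicate") %in% names(f)))
  # empty mask: empty table
  expect_equal(nrow(measureObjects(matrix(0L, 5, 5))), 0L)
  # permuting labels preserves the multiset of feature records
  perm <- lab
  perm[lab == 1L] <- 2L; perm[lab == 2L] <- 1L
  fp <- measureObjects(perm)
  cols <- c("area_px", "perimeter_px", "formfactor", "solidity")
  expect_equal(f[order(f$area_px), cols], fp[order(fp$area_px), cols],
               ignore_attr = TRUE)
})
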
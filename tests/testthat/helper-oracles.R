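# independent brute-force oracles and small fixtures shared by the tests

# scene parameters scaled for fast desk-size fields
testSceneParams <- function(imageSize = c(192L, 192L), nCells = 4L,
                            nucleusRadius = 10, objectsPerCell = c(5L, 9L),
                            fusedShape = list(tubeLengthRange = c(20, 60),
                                              tubeWidth = 4,
                                              branchProbability = 0.3),
                            ...) {
  sceneParams(imageSize = imageSize, nCells = nCells,
              nucleusRadius = nucleusRadius,
              objectsPerCell = objectsPerCell, fusedShape = fusedShape, ...)
}

# queue-based flood fill, independent of the igraph labelling path
floodFillLabel <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L)
    rbind(c(-1,-1),c(-1,0),c(-1,1),c(0,-1),c(0,1),c(1,-1),c(1,0),c(1,1))
  else rbind(c(-1,0),c(1,0),c(0,-1),c(0,1))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L; c <- (p - 1L) %/% H + 1L
      for (i in seq_len(nrow(nb))) {
        rr <- r + nb[i, 1]; cc <- c + nb[i, 2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        q <- (cc - 1L) * H + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# partitions equal up to label permutation
samePartition <- function(a, b) {
  fa <- as.integer(a[a > 0 | b > 0]); fb <- as.integer(b[a > 0 | b > 0])
  if (any((fa == 0) != (fb == 0))) return(FALSE)
  identical(as.integer(factor(paste(fa))), as.integer(factor(paste(fb))))
}

# naive per-point mixture log-likelihood using mvtnorm densities
naiveGmmLogLik <- function(model, x) {
  x <- as.matrix(x)
  s <- 0
  for (i in seq_len(nrow(x))) {
    dens <- 0
    for (k in seq_along(gmmWeights(model)))
      dens <- dens + gmmWeights(model)[k] *
        mvtnorm::dmvnorm(x[i, ], gmmMeans(model)[k, ],
                         gmmCovariances(model)[[k]])
    s <- s + log(dens)
  }
  s
}

# hull membership by exhaustive supporting-line enumeration: a grid point is
# inside the hull iff it lies on the inner side of every directed pair line
# that has all object pixels on that side
bruteForceHullCount <- function(pixels) {
  pts <- unique(pixels[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n == 1) return(1L)
  g <- expand.grid(row = min(pts[, 1]):max(pts[, 1]),
                   col = min(pts[, 2]):max(pts[, 2]))
  inside <- rep(TRUE, nrow(g))
  supporting <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    cr <- (b[2] - a[2]) * (pts[, 1] - a[1]) - (b[1] - a[1]) * (pts[, 2] - a[2])
    if (all(cr >= -1e-9)) {
      supporting <- supporting + 1L
      cg <- (b[2] - a[2]) * (g$row - a[1]) - (b[1] - a[1]) * (g$col - a[2])
      inside <- inside & cg >= -1e-9
    }
  }
  if (supporting == 0L) return(NA_integer_)  # fully collinear set
  sum(inside)
}

# boundary pixels by direct double-loop neighbourhood test
bruteForcePerimeter <- function(pixels) {
  n <- 0L
  inSet <- function(r, c) any(pixels[, 1] == r & pixels[, 2] == c)
  for (i in seq_len(nrow(pixels))) {
    r <- pixels[i, 1]; c <- pixels[i, 2]
    if (!inSet(r - 1, c) || !inSet(r + 1, c) ||
        !inSet(r, c - 1) || !inSet(r, c + 1)) n <- n + 1L
  }
  n
}

# random connected blob inside a maxSize x maxSize box
randomBlob <- function(maxSize = 12L, nGrow = 30L) {
  px <- matrix(c(sample.int(maxSize, 1), sample.int(maxSize, 1)), 1)
  for (i in seq_len(nGrow)) {
    base <- px[sample.int(nrow(px), 1), ]
    step <- sample(c(-1L, 0L, 1L), 2, replace = TRUE)
    cand <- base + step
    if (any(cand < 1) || any(cand > maxSize)) next
    px <- rbind(px, cand)
  }
  px <- unique(px)
  colnames(px) <- c("row", "col")
  # keep it 4-connected so perimeter oracles are well-defined on one object
  m <- matrix(FALSE, maxSize, maxSize)
  m[px] <- TRUE
  lab <- floodFillLabel(m, 4L)
  keep <- which(lab == lab[px[1, 1] + (px[1, 2] - 1L) * maxSize])
  out <- arrayInd(keep, c(maxSize, maxSize))
  colnames(out) <- c("row", "col")
  out
}

# per-pixel nearest-nucleus cytoplasm rings by brute force
bruteForceRegions <- function(nuclei, maxDistance) {
  H <- nrow(nuclei); W <- ncol(nuclei); n <- max(nuclei)
  nucs <- lapply(seq_len(n), function(k) which(nuclei == k, arr.ind = TRUE))
  cyt <- lapply(seq_len(n), function(k) NULL)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (nuclei[r, c] > 0L) next
    d <- vapply(nucs, function(m)
      sqrt(min((m[, 1] - r)^2 + (m[, 2] - c)^2)), numeric(1))
    k <- which.min(d)   # ties resolve to the lower label
    if (d[k] > 0 && d[k] <= maxDistance)
      cyt[[k]] <- rbind(cyt[[k]], c(r, c))
  }
  cyt
}

pixelSetEqual <- function(a, b) {
  if (is.null(b)) return(nrow(a) == 0)
  setequal(paste(a[, 1], a[, 2]), paste(b[, 1], b[, 2]))
}
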
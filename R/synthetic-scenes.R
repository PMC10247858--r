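#' Generate a synthetic two-channel mitochondrial scene
#'
#' Renders a field of cells, each with one nucleus and a mitochondrial
#' population mixing two morphology classes: "fragmented" objects are filled
#' ellipses with areas and eccentricities drawn from
#' \code{fragmentedShape}, and "fused" objects are dilated random-walk tubes
#' with optional branching drawn from \code{fusedShape}. Objects are placed
#' without overlap (a minimal gap is enforced so PSF blur cannot merge
#' neighbours), convolved with a Gaussian PSF, and corrupted with Poisson
#' shot noise plus additive Gaussian read noise. Ground truth (label mask,
#' per-object class, owning cell) is returned alongside the rendered
#' channels, standing in for the manual curation a real experiment needs.
#'
#' @param params a \code{\link{sceneParams}} object.
#' @return A \linkS4class{SyntheticScene} with channels \code{nuclei} and
#'   \code{mito}.
#' @examples
#' sc <- generateMitoScene(sceneParams(imageSize = c(192L, 192L),
#'   nCells = 4L, nucleusRadius = 10, seed = 3L))
#' sc
#' @export
generateMitoScene <- function(params) {
  validObject(params)
  withSeed(params@seed, renderScene(params))
}

renderScene <- function(params) {
  H <- params@imageSize[1]; W <- params@imageSize[2]
  rn <- params@nucleusRadius
  centers <- placeCellCenters(params@nCells, H, W, rn)

  occupied <- matrix(FALSE, H, W)
  truthMask <- matrix(0L, H, W)
  nucMask <- matrix(0L, H, W)

  # nuclei: slightly eccentric ellipses, one per cell
  for (i in seq_len(params@nCells)) {
    r1 <- rn * stats::runif(1, 0.85, 1.15)
    r2 <- rn * stats::runif(1, 0.85, 1.15)
    px <- rasterEllipse(centers[i, ], r1, r2, stats::runif(1, 0, pi), H, W)
    nucMask[px] <- i
  }

  labels <- character(0)
  cellMap <- integer(0)
  nextLabel <- 0L
  cellRadius <- rn * 3.5   # mitochondria live in an annulus around the nucleus

  nObjPerCell <- vapply(seq_len(params@nCells), function(i)
    if (params@objectsPerCell[1] == params@objectsPerCell[2])
      params@objectsPerCell[1]
    else sample(params@objectsPerCell[1]:params@objectsPerCell[2], 1L),
    integer(1))
  # stratified class assignment: the planted fraction is realized exactly
  # (up to rounding), so fraction-recovery benchmarks measure the pipeline,
  # not the generator's sampling noise
  nTotal <- sum(nObjPerCell)
  fragFlags <- rep(FALSE, nTotal)
  fragFlags[sample.int(nTotal, round(params@fragmentedFraction * nTotal))] <- TRUE
  flagOffset <- 0L

  for (i in seq_len(params@nCells)) {
    nObj <- nObjPerCell[i]
    isFrag <- fragFlags[flagOffset + seq_len(nObj)]
    flagOffset <- flagOffset + nObj
    for (j in seq_len(nObj)) {
      px <- placeObject(
        center = centers[i, ], innerR = rn + 3, outerR = cellRadius,
        fragmented = isFrag[j], params = params,
        occupied = occupied, H = H, W = W
      )
      occupied[dilatePixelsIdx(px, params@minGap, H, W)] <- TRUE
      nextLabel <- nextLabel + 1L
      truthMask[px] <- nextLabel
      labels <- c(labels, if (isFrag[j]) "fragmented" else "fused")
      cellMap <- c(cellMap, i)
    }
  }

  mito <- renderChannel(truthMask > 0L, truthMask, params)
  nuclei <- renderChannel(nucMask > 0L, nucMask, params)

  new("SyntheticScene",
      channels = list(nuclei = nuclei, mito = mito),
      truthMask = truthMask, truthLabels = labels,
      truthCellMap = cellMap, params = params)
}

# jittered-grid placement: deterministic feasibility for up to ~30 cells
placeCellCenters <- function(n, H, W, rn) {
  margin <- ceiling(rn * 3)
  if (H - 2 * margin < 1 || W - 2 * margin < 1)
    stop("image too small to place cells at this nucleus radius")
  k <- ceiling(sqrt(n))
  gh <- (H - 2 * margin) / k
  gw <- (W - 2 * margin) / k
  cells <- utils::head(as.matrix(expand.grid(gi = seq_len(k), gj = seq_len(k))), n)
  jr <- stats::runif(n, 0.25, 0.75)
  jc <- stats::runif(n, 0.25, 0.75)
  cbind(row = round(margin + (cells[, 1] - 1 + jr) * gh),
        col = round(margin + (cells[, 2] - 1 + jc) * gw))
}

# linear indices of a pixel set dilated by a disc
dilatePixelsIdx <- function(px, radius, H, W) {
  d <- dilatePixels(px, radius, c(H, W))
  (d[, 2] - 1L) * H + d[, 1]
}

# filled, rotated ellipse rasterized on the pixel grid
rasterEllipse <- function(center, r1, r2, theta, H, W) {
  r <- ceiling(max(r1, r2))
  rows <- max(1, center[1] - r):min(H, center[1] + r)
  cols <- max(1, center[2] - r):min(W, center[2] + r)
  g <- expand.grid(row = rows, col = cols)
  dy <- g$row - center[1]; dx <- g$col - center[2]
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / r1)^2 + (v / r2)^2 <= 1
  idx <- cbind(g$row[inside], g$col[inside])
  if (nrow(idx) == 0) idx <- cbind(center[1], center[2])
  storage.mode(idx) <- "integer"
  idx
}

# persistent random walk dilated to a tube, optionally with one branch
rasterTube <- function(anchor, len, width, branchProb, H, W) {
  path <- walkFrom(anchor, len)
  if (stats::runif(1) < branchProb) {
    mid <- path[max(1L, nrow(path) %/% 2L), ]
    path <- rbind(path, walkFrom(mid, max(5L, round(len / 2))))
  }
  path <- unique(round(path))
  px <- dilatePixels(path, width / 2, c(H, W))
  storage.mode(px) <- "integer"
  px
}

walkFrom <- function(start, len) {
  theta <- stats::runif(1, 0, 2 * pi)
  steps <- matrix(0, len, 2)
  pos <- as.numeric(start)
  for (s in seq_len(len)) {
    theta <- theta + stats::rnorm(1, 0, 0.35)
    pos <- pos + c(sin(theta), cos(theta))
    steps[s, ] <- pos
  }
  rbind(start, steps)
}

# draw one object of the requested class inside the cell annulus without
# touching previously placed objects; bounded retries
placeObject <- function(center, innerR, outerR, fragmented, params,
                        occupied, H, W, maxTries = 500L) {
  border <- 2L
  for (try in seq_len(maxTries)) {
    # widen the search annulus when the cell neighbourhood is saturated
    oR <- outerR * (1 + 2 * (try - 1) / maxTries)
    rho <- sqrt(stats::runif(1, (innerR / oR)^2, 1)) * oR
    phi <- stats::runif(1, 0, 2 * pi)
    anchor <- round(center + rho * c(sin(phi), cos(phi)))
    px <- if (fragmented) {
      area <- stats::runif(1, params@fragmentedShape$areaRange[1],
                           params@fragmentedShape$areaRange[2])
      ecc <- stats::runif(1, params@fragmentedShape$eccentricityRange[1],
                          params@fragmentedShape$eccentricityRange[2])
      # area = pi*a*b with b = a*sqrt(1-ecc^2)
      a <- sqrt(area / (pi * sqrt(1 - ecc^2)))
      rasterEllipse(anchor, a, a * sqrt(1 - ecc^2),
                    stats::runif(1, 0, pi), H, W)
    } else {
      len <- round(stats::runif(1, params@fusedShape$tubeLengthRange[1],
                                params@fusedShape$tubeLengthRange[2]))
      rasterTube(anchor, len, params@fusedShape$tubeWidth,
                 params@fusedShape$branchProbability, H, W)
    }
    if (nrow(px) == 0) next   # walk left the image entirely
    if (any(px[, 1] <= border | px[, 1] > H - border |
            px[, 2] <= border | px[, 2] > W - border)) next
    if (any(occupied[(px[, 2] - 1L) * H + px[, 1]])) next
    return(px)
  }
  stop("could not place object without overlap after ", maxTries,
       " retries; reduce object count or size")
}

# amplitude rendering + PSF + noise for one labelled mask
renderChannel <- function(fg, labelMask, params) {
  img <- matrix(params@backgroundLevel, nrow(fg), ncol(fg))
  n <- max(labelMask)
  if (n > 0) {
    amp <- params@amplitude * stats::runif(n, 0.8, 1.2)
    sel <- labelMask > 0L
    img[sel] <- img[sel] + amp[labelMask[sel]]
  }
  img <- gaussianBlur(img, params@psfSigma)
  img <- addCameraNoise(img, params@noise)
  clipIntensity(img)
}

addCameraNoise <- function(img, noise) {
  d <- dim(img)
  x <- as.numeric(img)
  if (noise$poissonScale > 0)
    x <- stats::rpois(length(x), lambda = pmax(x, 0) * noise$poissonScale) /
      noise$poissonScale
  if (noise$gaussianSd > 0)
    x <- x + stats::rnorm(length(x), 0, noise$gaussianSd)
  matrix(x, d[1], d[2])
}
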
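# internal helpers shared across modules

# derive independent sub-seeds from a master seed without touching the
# caller's RNG state more than once; keeps every derived seed < 2^31
deriveSeeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(restoreRng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restoreRng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

withSeed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restoreRng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# odd-sized normalized Gaussian kernel (sums to 1)
gaussianKernel <- function(sigma) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 2-D convolution with replicated borders; deterministic
convolve2d <- function(img, kernel) {
  stopifnot(is.matrix(img), is.matrix(kernel))
  out <- EBImage::filter2(img, kernel, boundary = "replicate")
  matrix(as.numeric(EBImage::imageData(out)), nrow(img), ncol(img))
}

gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  convolve2d(img, gaussianKernel(sigma))
}

clipIntensity <- function(img, lo = 0, hi = 65535) {
  img[img < lo] <- lo
  img[img > hi] <- hi
  img
}

# Otsu threshold on an arbitrary-range image
otsuThreshold <- function(img, levels = 256L) {
  r <- range(img)
  if (r[1] == r[2]) return(r[1])
  x <- (img - r[1]) / (r[2] - r[1])
  t01 <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = levels)
  r[1] + t01 * (r[2] - r[1])
}

# pixel set <-> keys (pixels are 2-column integer matrices: row, col)
pixelKeys <- function(px, nrowHint = NULL) {
  # collision-free key independent of any image size
  px[, 1] * 1e6 + px[, 2]
}

# offsets of a disc of given radius (includes the centre)
discOffsets <- function(radius) {
  r <- ceiling(radius)
  dd <- expand.grid(dr = -r:r, dc = -r:r)
  dd <- dd[dd$dr^2 + dd$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(dd)
}

# dilate a pixel set by a disc, clipped to the image
dilatePixels <- function(px, radius, imageSize) {
  off <- discOffsets(radius)
  rows <- rep(px[, 1], each = nrow(off)) + off[, 1]
  cols <- rep(px[, 2], each = nrow(off)) + off[, 2]
  keep <- rows >= 1 & rows <= imageSize[1] & cols >= 1 & cols <= imageSize[2]
  unique(cbind(row = rows[keep], col = cols[keep]))
}

# standard error of the mean
se <- function(x) stats::sd(x) / sqrt(length(x))

asMatrixImage <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(as.numeric(EBImage::imageData(x)), d[1], d[2])
}
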
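#' @import methods
NULL

#' Parameters of a synthetic microscopy scene
#'
#' An S4 container holding every knob of the synthetic-scene generator:
#' geometry, cell packing, the shape generators for the two morphology
#' classes, optics (PSF) and the noise model. Identical \code{SceneParams}
#' (including \code{seed}) always render to bit-identical scenes.
#'
#' @slot imageSize integer(2), image height and width in pixels.
#' @slot pixelSize numeric(1), physical pixel size in micrometres.
#' @slot nCells integer(1), number of cells in the field.
#' @slot nucleusRadius numeric(1), mean nuclear radius in pixels.
#' @slot objectsPerCell integer(2), min/max mitochondrial objects per cell.
#' @slot fragmentedFraction numeric(1) in [0,1], target fraction of objects
#'   drawn from the fragmented (small, roundish) generator.
#' @slot fragmentedShape list with \code{areaRange} (px^2) and
#'   \code{eccentricityRange} for the elliptical fragmented objects.
#' @slot fusedShape list with \code{tubeLengthRange} (px), \code{tubeWidth}
#'   (px) and \code{branchProbability} for the tubular fused objects.
#' @slot psfSigma numeric(1), Gaussian point-spread sigma in pixels.
#' @slot noise list with \code{gaussianSd} (additive read noise, intensity
#'   units) and \code{poissonScale} (shot-noise scaling; 0 disables).
#' @slot backgroundLevel numeric(1), background intensity (a.u.).
#' @slot amplitude numeric(1), mean foreground intensity above background.
#' @slot minGap numeric(1), minimal pixel gap enforced between objects.
#' @slot seed integer(1), RNG seed.
#' @export
setClass("SceneParams",
  representation(
    imageSize = "integer",
    pixelSize = "numeric",
    nCells = "integer",
    nucleusRadius = "numeric",
    objectsPerCell = "integer",
    fragmentedFraction = "numeric",
    fragmentedShape = "list",
    fusedShape = "list",
    psfSigma = "numeric",
    noise = "list",
    backgroundLevel = "numeric",
    amplitude = "numeric",
    minGap = "numeric",
    seed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 32L))
    msg <- c(msg, "imageSize must be two integers >= 32")
  if (object@nCells < 1L)
    msg <- c(msg, "nCells must be >= 1")
  if (object@fragmentedFraction < 0 || object@fragmentedFraction > 1)
    msg <- c(msg, "fragmentedFraction must lie in [0, 1]")
  rangeOk <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  if (!rangeOk(object@fragmentedShape$areaRange))
    msg <- c(msg, "fragmentedShape$areaRange must be a valid min<=max range")
  if (!rangeOk(object@fragmentedShape$eccentricityRange))
    msg <- c(msg, "fragmentedShape$eccentricityRange must be a valid range")
  if (!rangeOk(object@fusedShape$tubeLengthRange))
    msg <- c(msg, "fusedShape$tubeLengthRange must be a valid range")
  if (!rangeOk(object@objectsPerCell))
    msg <- c(msg, "objectsPerCell must be a valid min<=max range")
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
  if (object@noise$gaussianSd < 0 || object@noise$poissonScale < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct scene parameters
#'
#' Defaults reproduce the acquisition geometry of the assay the package
#' models: 1024 x 1024 pixel confocal fields at 0.1 um/pixel containing
#' between 5 and 30 HepG2 cells, a mitochondrial channel mixing small
#' roundish ("fragmented") and elongated/branched ("fused") objects, Gaussian
#' PSF blur, and Poisson-plus-Gaussian camera noise. Size and shape ranges of
#' the two classes are generator assumptions chosen to produce clearly
#' bimodal feature distributions (the assay itself publishes no numeric
#' ranges); see the package vignette.
#'
#' @param imageSize integer(2) image height/width in px.
#' @param pixelSize physical pixel size, um/px.
#' @param nCells number of cells (the assay fields contain 5--30).
#' @param nucleusRadius mean nuclear radius, px.
#' @param objectsPerCell integer(2), min/max mitochondrial objects per cell.
#' @param fragmentedFraction target fraction of fragmented objects in [0,1].
#' @param fragmentedShape list(areaRange, eccentricityRange).
#' @param fusedShape list(tubeLengthRange, tubeWidth, branchProbability).
#' @param psfSigma Gaussian PSF sigma, px.
#' @param noise list(gaussianSd, poissonScale).
#' @param backgroundLevel background intensity, a.u.
#' @param amplitude mean foreground intensity above background, a.u.
#' @param minGap minimal gap between rendered objects, px.
#' @param seed RNG seed.
#' @return A \linkS4class{SceneParams} object.
#' @examples
#' p <- sceneParams(imageSize = c(256L, 256L), nCells = 5L, seed = 1L)
#' @export
sceneParams <- function(imageSize = c(1024L, 1024L),
                        pixelSize = 0.1,
                        nCells = 12L,
                        nucleusRadius = 40,
                        objectsPerCell = c(8L, 20L),
                        fragmentedFraction = 0.5,
                        fragmentedShape = list(
                          areaRange = c(20, 80),
                          eccentricityRange = c(0, 0.7)
                        ),
                        fusedShape = list(
                          tubeLengthRange = c(30, 120),
                          tubeWidth = 4,
                          branchProbability = 0.3
                        ),
                        psfSigma = 1,
                        noise = list(gaussianSd = 50, poissonScale = 1),
                        backgroundLevel = 100,
                        amplitude = 500,
                        minGap = 4,
                        seed = 1L) {
  # nuclei scale with the field so small test scenes stay packable
  if (missing(nucleusRadius))
    nucleusRadius <- 40 * min(imageSize) / 1024
  new("SceneParams",
    imageSize = as.integer(imageSize), pixelSize = pixelSize,
    nCells = as.integer(nCells), nucleusRadius = nucleusRadius,
    objectsPerCell = as.integer(objectsPerCell),
    fragmentedFraction = fragmentedFraction,
    fragmentedShape = fragmentedShape, fusedShape = fusedShape,
    psfSigma = psfSigma, noise = noise,
    backgroundLevel = backgroundLevel, amplitude = amplitude,
    minGap = minGap, seed = as.integer(seed))
}

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams:", paste(object@imageSize, collapse = " x "),
      "px @", object@pixelSize, "um/px;",
      object@nCells, "cells;",
      "fragmented fraction", object@fragmentedFraction,
      "; seed", object@seed, "\n")
})

#' A rendered synthetic scene with ground truth
#'
#' Holds rendered intensity channels together with the ground truth that
#' produced them: the labelled object mask, the per-object morphology class
#' and the owning cell of each object.
#'
#' @slot channels named list of numeric matrices (intensity images), at least
#'   \code{nuclei} and \code{mito}.
#' @slot truthMask integer matrix, 0 = background, labels 1..n.
#' @slot truthLabels character vector, class per label
#'   ("fragmented"/"fused").
#' @slot truthCellMap integer vector, owning cell id per label.
#' @slot params the \linkS4class{SceneParams} used for rendering.
#' @export
setClass("SyntheticScene",
  representation(
    channels = "list",
    truthMask = "matrix",
    truthLabels = "character",
    truthCellMap = "integer",
    params = "SceneParams"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  n <- max(object@truthMask)
  if (length(object@truthLabels) != n)
    msg <- c(msg, "one truth class per labelled object required")
  if (!all(object@truthLabels %in% c("fragmented", "fused")))
    msg <- c(msg, "truth classes must be 'fragmented' or 'fused'")
  if (length(object@truthCellMap) != n)
    msg <- c(msg, "one owning cell per labelled object required")
  for (ch in object@channels)
    if (!identical(dim(ch), dim(object@truthMask)))
      msg <- c(msg, "all channels must share dimensions with truthMask")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene:", paste(dim(object@truthMask), collapse = " x "),
      "px;", length(object@truthLabels), "objects (",
      sum(object@truthLabels == "fragmented"), "fragmented /",
      sum(object@truthLabels == "fused"), "fused );",
      "channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' @describeIn SyntheticScene-class access the rendered channels.
#' @param object,x a \code{SyntheticScene}.
#' @export
channels <- function(x) x@channels

#' @describeIn SyntheticScene-class access the ground-truth label image.
#' @export
truthMask <- function(x) x@truthMask

#' @describeIn SyntheticScene-class per-object ground-truth classes.
#' @export
truthLabels <- function(x) x@truthLabels

#' @describeIn SyntheticScene-class per-object owning cell ids.
#' @export
truthCellMap <- function(x) x@truthCellMap

#' A trained pixel-classification model
#'
#' Couples a filter-bank specification with a trained random forest that
#' classifies every pixel into foreground (mitochondrial signal) or
#' background, mirroring an interactive "pixel classification" workflow run
#' headlessly.
#'
#' @slot filterBank the filter-bank specification list (see
#'   \code{\link{filterBankSpec}}).
#' @slot forest the fitted \pkg{randomForest} object.
#' @slot classLevels character(2), class order ("background","foreground").
#' @slot nTrees integer(1).
#' @slot seed integer(1) training seed.
#' @export
setClass("PixelClassifierModel",
  representation(
    filterBank = "list",
    forest = "ANY",
    classLevels = "character",
    nTrees = "integer",
    seed = "integer"
  )
)

setValidity("PixelClassifierModel", function(object) {
  if (length(object@classLevels) != 2L)
    "exactly two classes (background/foreground) are supported" else TRUE
})

setMethod("show", "PixelClassifierModel", function(object) {
  kinds <- vapply(object@filterBank$filters, function(f)
    sprintf("%s(sigma=%g)", f$kind, f$sigma), character(1))
  cat("PixelClassifierModel:", object@nTrees, "trees; features:",
      paste(kinds, collapse = ", "), "; seed", object@seed, "\n")
})

#' A two-component Gaussian mixture over shape-feature space
#'
#' Full-covariance Gaussian mixture fitted by multi-restart EM on the
#' four-feature table (area, perimeter, formfactor, solidity), with the best
#' restart selected by minimal negative log-likelihood and components named
#' "fragmented"/"fused" by mean object area.
#'
#' @slot weights numeric(K) mixing weights, sum 1.
#' @slot means K x d matrix of component means.
#' @slot covariances list of K symmetric positive-definite d x d matrices.
#' @slot negLogLik numeric(1), negative log-likelihood of the training data.
#' @slot logLikHistory numeric vector, log-likelihood per EM iteration of the
#'   selected restart.
#' @slot nRestarts integer(1).
#' @slot seed integer(1).
#' @slot classMap named character, component index -> class name.
#' @slot featureNames character(d).
#' @export
setClass("GmmModel",
  representation(
    weights = "numeric",
    means = "matrix",
    covariances = "list",
    negLogLik = "numeric",
    logLikHistory = "numeric",
    nRestarts = "integer",
    seed = "integer",
    classMap = "character",
    featureNames = "character"
  )
)

setValidity("GmmModel", function(object) {
  msg <- character()
  K <- length(object@weights)
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "mixing weights must sum to 1")
  if (nrow(object@means) != K || length(object@covariances) != K)
    msg <- c(msg, "means/covariances must match the number of components")
  for (S in object@covariances) {
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      msg <- c(msg, "covariances must be symmetric")
    else if (inherits(try(chol(S), silent = TRUE), "try-error"))
      msg <- c(msg, "covariances must be positive definite")
  }
  if (length(object@classMap)) {
    if (!setequal(object@classMap, c("fragmented", "fused")) ||
        length(object@classMap) != K)
      msg <- c(msg, "classMap must be a bijection onto fragmented/fused")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GmmModel", function(object) {
  cat("GmmModel:", length(object@weights), "components over",
      paste(object@featureNames, collapse = ", "), "\n")
  cat("  weights:", signif(object@weights, 4), "\n")
  cat("  -logLik:", format(object@negLogLik), "(best of",
      object@nRestarts, "restarts)\n")
  if (length(object@classMap))
    cat("  classes:", paste(seq_along(object@classMap), object@classMap,
                            sep = "=", collapse = ", "), "\n")
})

#' @describeIn GmmModel-class mixing weights.
#' @param x a \code{GmmModel}.
#' @export
gmmWeights <- function(x) x@weights

#' @describeIn GmmModel-class component means (K x d matrix).
#' @export
gmmMeans <- function(x) x@means

#' @describeIn GmmModel-class list of component covariance matrices.
#' @export
gmmCovariances <- function(x) x@covariances

#' @describeIn GmmModel-class negative log-likelihood of the training data.
#' @export
negLogLik <- function(x) x@negLogLik

#' @describeIn GmmModel-class component-to-class mapping.
#' @export
classMap <- function(x) x@classMap
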
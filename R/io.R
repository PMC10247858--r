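#' Read and write 16-bit grayscale TIFF images
#'
#' Images are numeric matrices in intensity units 0..65535; on disk they are
#' 16-bit unsigned TIFFs. Label images round-trip the same way (labels as
#' 16-bit integers).
#'
#' @param img numeric or integer matrix with values in [0, 65535].
#' @param path file path.
#' @return \code{readImageTiff} returns a numeric matrix on the 0..65535
#'   scale; \code{writeImageTiff} returns \code{path} invisibly.
#' @export
writeImageTiff <- function(img, path) {
  stopifnot(is.matrix(img))
  tiff::writeTIFF(clipIntensity(img) / 65535, path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  round(x * 65535)
}

#' Write a synthetic scene to disk
#'
#' One 16-bit TIFF per channel, the ground-truth label mask as a 16-bit
#' label TIFF, and the per-object truth records (label, class, owning cell)
#' as CSV.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
writeScene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (ch in names(channels(scene))) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    writeImageTiff(channels(scene)[[ch]], p)
    paths[ch] <- p
  }
  pm <- file.path(dir, sprintf("%s_truth_mask.tif", prefix))
  writeImageTiff(truthMask(scene), pm)
  paths["truth_mask"] <- pm
  pt <- file.path(dir, sprintf("%s_truth.csv", prefix))
  utils::write.csv(data.frame(
    object_id = seq_along(truthLabels(scene)),
    class = truthLabels(scene),
    cell_id = truthCellMap(scene)
  ), pt, row.names = FALSE)
  paths["truth_csv"] <- pt
  invisible(paths)
}

#' Round-trip scene parameters through YAML
#'
#' @param params a \linkS4class{SceneParams}.
#' @param path YAML file path.
#' @return \code{readSceneParams} returns a \linkS4class{SceneParams}
#'   identical to the one written.
#' @export
writeSceneParams <- function(params, path) {
  slots <- methods::slotNames("SceneParams")
  lst <- stats::setNames(lapply(slots, function(s) slot(params, s)), slots)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeSceneParams
#' @export
readSceneParams <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(sceneParams, lst)
}

#' Serialize a Gaussian mixture model to JSON
#'
#' Weights, means, covariances, class map and fit metadata are stored as
#' plain JSON with full double precision, so a reloaded model reproduces
#' likelihoods and assignments exactly.
#'
#' @param model a \linkS4class{GmmModel}.
#' @param path JSON file path.
#' @return \code{readGmmModel} returns the reconstructed
#'   \linkS4class{GmmModel}.
#' @export
writeGmmModel <- function(model, path) {
  # flat, explicit layout: one vector per component mean, one column-major
  # vector per covariance, so reading back needs no guessing
  obj <- list(
    weights = model@weights,
    means = lapply(seq_along(model@weights), function(k)
      unname(model@means[k, ])),
    covariances = lapply(model@covariances, function(S) as.numeric(S)),
    negLogLik = model@negLogLik,
    nRestarts = model@nRestarts,
    seed = model@seed,
    classMap = as.list(model@classMap),
    featureNames = model@featureNames
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGmmModel
#' @export
readGmmModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  featureNames <- unlist(obj$featureNames)
  d <- length(featureNames)
  K <- length(obj$weights)
  means <- do.call(rbind, lapply(obj$means, unlist))
  colnames(means) <- featureNames
  covs <- lapply(obj$covariances, function(v) {
    S <- matrix(unlist(v), d, d)
    dimnames(S) <- list(featureNames, featureNames)
    S
  })
  new("GmmModel",
      weights = unlist(obj$weights), means = means, covariances = covs,
      negLogLik = obj$negLogLik, logLikHistory = numeric(0),
      nRestarts = as.integer(obj$nRestarts), seed = as.integer(obj$seed),
      classMap = stats::setNames(unlist(obj$classMap), names(obj$classMap)),
      featureNames = featureNames)
}

#' Read/write sparse pixel annotations as CSV
#'
#' Columns: image, row, col, label.
#'
#' @param annotations annotation data.frame.
#' @param path CSV path.
#' @export
writeAnnotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
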
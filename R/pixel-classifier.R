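#' Train a random-forest pixel classifier
#'
#' Emulates an interactive pixel-classification workflow run headlessly:
#' sparse foreground/background pixel annotations on one or more training
#' images are featurized through the filter bank and fed to a random forest.
#' The trained model predicts a two-class ("Simple Segmentation") mask for
#' any image of the same modality.
#'
#' @param images list of numeric matrices (training images).
#' @param annotations data.frame with columns \code{image} (index into
#'   \code{images}), \code{row}, \code{col}, \code{label}
#'   ("foreground"/"background").
#' @param spec a \code{\link{filterBankSpec}}.
#' @param nTrees number of trees (default 100).
#' @param seed training seed; fixed seed gives identical predictions.
#' @return A \linkS4class{PixelClassifierModel}.
#' @export
trainPixelClassifier <- function(images, annotations,
                                 spec = filterBankSpec(),
                                 nTrees = 100L, seed = 1L) {
  stopifnot(is.list(images), is.data.frame(annotations))
  need <- c("image", "row", "col", "label")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "))
  if (!all(annotations$label %in% c("foreground", "background")))
    stop("labels must be 'foreground' or 'background'")
  if (length(unique(annotations$label)) < 2L)
    stop("annotations must contain at least one pixel of each class")

  feats <- lapply(seq_along(images), function(i) {
    ann <- annotations[annotations$image == i, , drop = FALSE]
    if (nrow(ann) == 0) return(NULL)
    img <- images[[i]]
    if (any(ann$row < 1 | ann$row > nrow(img) |
            ann$col < 1 | ann$col > ncol(img)))
      stop("annotation coordinates outside image ", i)
    fb <- computeFilterBank(img, spec)
    idx <- cbind(ann$row, ann$col)
    x <- vapply(seq_len(dim(fb)[3]),
                function(p) fb[, , p][idx], numeric(nrow(ann)))
    data.frame(x, label = ann$label)
  })
  train <- do.call(rbind, feats)
  names(train)[seq_len(ncol(train) - 1L)] <-
    paste0("f", seq_len(ncol(train) - 1L))
  train$label <- factor(train$label, levels = c("background", "foreground"))

  forest <- withSeed(seed, randomForest::randomForest(
    x = train[, seq_len(ncol(train) - 1L), drop = FALSE],
    y = train$label, ntree = nTrees))
  new("PixelClassifierModel",
      filterBank = unclass(spec), forest = forest,
      classLevels = c("background", "foreground"),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' Predict a binary segmentation mask
#'
#' Featurizes every pixel of an image through the model's filter bank and
#' returns the per-pixel argmax class as a logical foreground mask. Every
#' pixel receives a class; the mask shape always equals the image shape.
#'
#' @param model a \linkS4class{PixelClassifierModel}.
#' @param image numeric matrix.
#' @return logical matrix, \code{TRUE} = foreground.
#' @export
predictSegmentation <- function(model, image) {
  stopifnot(is(model, "PixelClassifierModel"), is.matrix(image))
  spec <- structure(model@filterBank, class = "FilterBankSpec")
  fb <- computeFilterBank(image, spec)
  np <- dim(fb)[3]
  x <- matrix(fb, nrow = length(image), ncol = np)
  colnames(x) <- paste0("f", seq_len(np))
  votes <- stats::predict(model@forest, newdata = as.data.frame(x),
                          type = "vote", norm.votes = TRUE)
  # fixed tie-break (exact .5 vote goes to background) keeps predictions
  # bit-reproducible
  matrix(votes[, "foreground"] > 0.5, nrow(image), ncol(image))
}

#' Training-pixel accuracy of a pixel classifier
#'
#' Fraction of annotated pixels whose predicted class matches the
#' annotation, across all training images.
#'
#' @inheritParams trainPixelClassifier
#' @param model a trained \linkS4class{PixelClassifierModel}.
#' @return numeric(1) accuracy in [0, 1].
#' @export
trainingAccuracy <- function(model, images, annotations) {
  ok <- 0L; tot <- 0L
  for (i in seq_along(images)) {
    ann <- annotations[annotations$image == i, , drop = FALSE]
    if (nrow(ann) == 0) next
    mask <- predictSegmentation(model, images[[i]])
    pred <- ifelse(mask[cbind(ann$row, ann$col)], "foreground", "background")
    ok <- ok + sum(pred == ann$label)
    tot <- tot + nrow(ann)
  }
  ok / tot
}

#' Intersection over union of two masks
#'
#' @param a,b logical matrices of equal shape.
#' @return numeric(1); by convention 1 when both masks are empty.
#' @export
maskIoU <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Sample sparse truth-derived annotations from a synthetic scene
#'
#' Stands in for the manual fore/background scribbles of the interactive
#' workflow: samples \code{nPerClass} pixels from the scene's ground-truth
#' object mask and the same number from the background.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param imageIndex index of the scene's image in the training list.
#' @param nPerClass annotated pixels per class.
#' @param seed RNG seed.
#' @return annotation data.frame (image, row, col, label).
#' @export
annotateFromTruth <- function(scene, imageIndex = 1L, nPerClass = 500L,
                              seed = 1L) {
  withSeed(seed, {
    fgIdx <- which(truthMask(scene) > 0L)
    bgIdx <- which(truthMask(scene) == 0L)
    pick <- function(idx) idx[sample.int(length(idx),
                                         min(nPerClass, length(idx)))]
    fg <- arrayInd(pick(fgIdx), dim(truthMask(scene)))
    bg <- arrayInd(pick(bgIdx), dim(truthMask(scene)))
    data.frame(
      image = imageIndex,
      row = c(fg[, 1], bg[, 1]),
      col = c(fg[, 2], bg[, 2]),
      label = rep(c("foreground", "background"), c(nrow(fg), nrow(bg)))
    )
  })
}
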
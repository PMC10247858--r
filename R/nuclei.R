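#' Watershed segmentation of nuclei
#'
#' Segments nuclei from a Hoechst image: the image is equalized with a
#' Gaussian filter, thresholded (Otsu by default), and touching nuclei are
#' split by a watershed on the Euclidean distance transform, with
#' shallow-maxima merging controlled by \code{tolerance} (the h of an
#' h-maxima seed detection). A blank image yields zero nuclei.
#'
#' @param hoechst numeric matrix, nuclear channel.
#' @param smoothSigma Gaussian equalization sigma, px.
#' @param threshold "otsu" or a numeric intensity cutoff.
#' @param tolerance watershed tolerance (h of the h-maxima seeds), px.
#' @param minSize discard nuclei smaller than this pixel count.
#' @return integer label matrix (0 = background, labels 1..n).
#' @export
segmentNuclei <- function(hoechst, smoothSigma = 2, threshold = "otsu",
                          tolerance = 2, minSize = 20L) {
  stopifnot(is.matrix(hoechst))
  sm <- gaussianBlur(hoechst, smoothSigma)
  # a (near-)constant field has no nuclei; guard against FP wiggle from the
  # blur before thresholding
  if (diff(range(sm)) <= 1e-8 * max(1, abs(max(sm))))
    return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  thr <- if (identical(threshold, "otsu")) otsuThreshold(sm)
         else as.numeric(threshold)
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  dist <- asMatrixImage(EBImage::distmap(EBImage::Image(mask * 1)))
  ws <- EBImage::watershed(EBImage::Image(dist), tolerance = tolerance,
                           ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)),
                nrow(hoechst), ncol(hoechst))
  # contiguous labels in raster order + size filter
  relabelContiguous(lab, minSize)
}

relabelContiguous <- function(lab, minSize = 1L) {
  ids <- setdiff(unique(as.integer(lab)), 0L)
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  sizes <- tabulate(lab[lab > 0L], nbins = max(ids))
  keep <- ids[sizes[ids] >= minSize]
  # order by first raster occurrence
  firstPos <- vapply(keep, function(i) which(lab == i)[1], numeric(1))
  keep <- keep[order(firstPos)]
  remap <- integer(max(ids))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  out
}
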
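#' Specify a pixel-classification filter bank
#'
#' The default bank reproduces the two features the original workflow
#' selected by visual inspection: a Laplacian of Gaussian at sigma = 3.5 px
#' and a Difference of Gaussians at sigma = 3.5 px. The DoG secondary sigma
#' is \code{secondaryRatio * sigma} (default 0.66, the convention of the
#' interactive software this emulates), and the DoG sign convention is
#' \code{G(sigma * ratio) * I - G(sigma) * I}, i.e. positive on blobs
#' narrower than sigma. The raw intensity plane can be added as a third
#' feature.
#'
#' @param sigma Gaussian scale in pixels for both filters.
#' @param secondaryRatio DoG secondary-sigma ratio in (0, 1).
#' @param includeRawIntensity add the unfiltered image as a feature plane.
#' @return list of class \code{FilterBankSpec}.
#' @export
filterBankSpec <- function(sigma = 3.5, secondaryRatio = 0.66,
                           includeRawIntensity = FALSE) {
  stopifnot(sigma > 0, secondaryRatio > 0, secondaryRatio != 1)
  filters <- list(
    list(kind = "laplacian_of_gaussian", sigma = sigma),
    list(kind = "difference_of_gaussians", sigma = sigma,
         secondaryRatio = secondaryRatio)
  )
  if (includeRawIntensity)
    filters <- c(list(list(kind = "raw_intensity", sigma = 0)), filters)
  structure(list(filters = filters), class = "FilterBankSpec")
}

#' Compute per-pixel filter-bank features
#'
#' Applies every filter of the bank to one image and stacks the responses.
#' LoG is the Laplacian (4-connected discrete stencil) of the
#' Gaussian-smoothed image at the requested sigma; DoG is the difference of
#' two Gaussian smoothings, \code{G(sigma*ratio)*I - G(sigma)*I}. Both
#' filters respond zero on a constant image and are fully deterministic.
#'
#' @param image numeric matrix with finite values.
#' @param spec a \code{\link{filterBankSpec}}.
#' @return numeric array \code{c(dim(image), nFilters)} with one feature
#'   plane per filter, named along the third dimension.
#' @examples
#' fb <- computeFilterBank(matrix(rnorm(64^2), 64), filterBankSpec())
#' dim(fb)
#' @export
computeFilterBank <- function(image, spec = filterBankSpec()) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image)))
    stop("image contains non-finite pixels")
  planes <- lapply(spec$filters, function(f) {
    switch(f$kind,
      raw_intensity = image,
      laplacian_of_gaussian = laplacianOfGaussian(image, f$sigma),
      difference_of_gaussians =
        gaussianBlur(image, f$sigma * f$secondaryRatio) -
        gaussianBlur(image, f$sigma),
      stop("unknown filter kind: ", f$kind))
  })
  out <- array(unlist(planes), dim = c(dim(image), length(planes)))
  dimnames(out) <- list(NULL, NULL,
                        vapply(spec$filters, `[[`, character(1), "kind"))
  out
}

laplacianOfGaussian <- function(image, sigma) {
  sm <- gaussianBlur(image, sigma)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  convolve2d(sm, lap)
}
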
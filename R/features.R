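#' Object area in pixels
#'
#' The area of an object is the number of pixels it occupies.
#'
#' @param pixels integer matrix with columns \code{row}, \code{col}.
#' @return integer(1) pixel count.
#' @export
measureArea <- function(pixels) {
  if (!is.matrix(pixels) || nrow(pixels) == 0)
    stop("empty object: area is undefined")
  nrow(pixels)
}

#' Object perimeter as boundary-pixel count
#'
#' The perimeter is the number of object pixels on the boundary: pixels with
#' at least one 4-connected neighbour outside the object. Pixels adjacent to
#' an interior hole count too, so for objects with holes the perimeter is
#' the sum of the inner and outer boundary.
#'
#' @param pixels integer matrix with columns \code{row}, \code{col}.
#' @return integer(1) boundary pixel count (>= 1).
#' @export
measurePerimeter <- function(pixels) {
  if (!is.matrix(pixels) || nrow(pixels) == 0)
    stop("empty object: perimeter is undefined")
  keys <- pixelKeys(pixels)
  boundary <- rep(FALSE, nrow(pixels))
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nk <- pixelKeys(cbind(pixels[, 1] + s[1], pixels[, 2] + s[2]))
    boundary <- boundary | !(nk %in% keys)
  }
  sum(boundary)
}

#' Formfactor (circularity) of an object
#'
#' The default is the standard circularity \code{4 * pi * area /
#' perimeter^2}, which is 1 for an ideal disk and dimensionless. A
#' \code{"literal"} variant computing \code{4 * pi * area / perimeter} is
#' retained behind this switch; it is dimensionally a length and kept only
#' for strict fidelity to pipelines that used it. See the vignette for the
#' rationale.
#'
#' @param area object area, px.
#' @param perimeter object perimeter, px (> 0).
#' @param formula "standard" (4*pi*A/P^2) or "literal" (4*pi*A/P).
#' @return numeric(1).
#' @examples
#' measureFormfactor(100, 40)             # ~0.785
#' measureFormfactor(100, 40, "literal")  # ~31.4
#' @export
measureFormfactor <- function(area, perimeter,
                              formula = c("standard", "literal")) {
  formula <- match.arg(formula)
  stopifnot(area >= 1)
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  if (formula == "standard") 4 * pi * area / perimeter^2
  else 4 * pi * area / perimeter
}

#' Solidity of an object
#'
#' Area divided by the area enclosed by the convex hull of the object, both
#' at pixel resolution: the hull is taken over pixel centres and its area is
#' the count of pixels whose centres lie inside or on the hull. Convex pixel
#' sets have solidity 1; concave ones less.
#'
#' @param pixels integer matrix with columns \code{row}, \code{col}.
#' @return numeric(1) in (0, 1].
#' @export
measureSolidity <- function(pixels) {
  if (!is.matrix(pixels) || nrow(pixels) == 0)
    stop("empty object: solidity is undefined")
  nrow(pixels) / convexHullPixelCount(pixels)
}

# number of grid points inside-or-on the convex hull of a pixel set
convexHullPixelCount <- function(pixels) {
  pts <- unique(pixels[, 1:2, drop = FALSE])
  if (nrow(pts) <= 2) return(countOnSegment(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])     # (x=col, y=row)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) <= 2) return(countOnSegment(pts))
  # candidate grid points: bounding box; test against every hull edge
  rows <- min(pts[, 1]):max(pts[, 1])
  cols <- min(pts[, 2]):max(pts[, 2])
  g <- expand.grid(row = rows, col = cols)
  inside <- rep(TRUE, nrow(g))
  n <- nrow(hull)
  # orient by the polygon's signed area so the interior side is known
  nxt <- c(seq_len(n)[-1], 1L)
  signedArea <- sum(hull[, 2] * hull[nxt, 1] - hull[nxt, 2] * hull[, 1])
  s <- if (signedArea >= 0) 1 else -1
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[nxt[i], ]
    cross <- (b[2] - a[2]) * (g$row - a[1]) - (b[1] - a[1]) * (g$col - a[2])
    inside <- inside & s * cross >= -1e-9
  }
  sum(inside)
}

# degenerate hull: count integer points on the segment between the extremes
countOnSegment <- function(pts) {
  if (nrow(pts) == 1) return(1L)
  o <- order(pts[, 1], pts[, 2])
  a <- pts[o[1], ]; b <- pts[o[nrow(pts)], ]
  g <- .gcd(abs(b[1] - a[1]), abs(b[2] - a[2]))
  as.integer(max(g, 1L) + 1L)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Measure all objects of a label image
#'
#' Computes the four shape descriptors (area, perimeter, formfactor,
#' solidity) for every labelled object and attaches provenance metadata.
#' Records are ordered by label; relabelling permutations change only the
#' order, not the multiset of feature records. Features are reported in
#' pixel units; the physical pixel size belongs in the metadata.
#'
#' @param labeled integer label matrix (see \code{\link{labelObjects}}).
#' @param metadata named list merged into every record (e.g. image_id,
#'   compound, concentration_uM, timepoint_h, replicate).
#' @param formfactorFormula "standard" or "literal"
#'   (see \code{\link{measureFormfactor}}).
#' @return data.frame with one row per object: metadata columns,
#'   \code{object_id}, \code{area_px}, \code{perimeter_px},
#'   \code{formfactor}, \code{solidity}.
#' @export
measureObjects <- function(labeled, metadata = list(image_id = "img"),
                           formfactorFormula = c("standard", "literal")) {
  formfactorFormula <- match.arg(formfactorFormula)
  n <- max(labeled)
  meta <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (n == 0) {
    out <- cbind(meta[0, , drop = FALSE],
                 data.frame(object_id = integer(0), area_px = integer(0),
                            perimeter_px = integer(0), formfactor = numeric(0),
                            solidity = numeric(0)))
    return(out)
  }
  rows <- lapply(seq_len(n), function(i) {
    px <- objectPixels(labeled, i)
    a <- measureArea(px)
    p <- measurePerimeter(px)
    data.frame(object_id = i, area_px = a, perimeter_px = p,
               formfactor = measureFormfactor(a, p, formfactorFormula),
               solidity = measureSolidity(px))
  })
  feat <- do.call(rbind, rows)
  cbind(meta[rep(1L, n), , drop = FALSE], feat, row.names = NULL)
}
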
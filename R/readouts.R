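#' Build per-cell nucleus + cytoplasm regions
#'
#' For every labelled nucleus, the cytoplasm is the set of non-nuclear
#' pixels within \code{maxDistance} (Euclidean) of that nucleus, with every
#' contested pixel assigned to its nearest nucleus (distance ties go to the
#' lower label). This reproduces the "pixels within a maximal distance of 10
#' pixels around the nucleus" convention of intensity-based MMP readouts.
#'
#' @param nuclei integer label matrix of nuclei.
#' @param maxDistance ring radius in pixels (default 10).
#' @return list of cell regions, one per label, each a list with
#'   \code{cellId}, \code{nucleus} and \code{cytoplasm} (2-column pixel
#'   matrices). Zero nuclei give an empty list.
#' @export
buildCellRegions <- function(nuclei, maxDistance = 10) {
  stopifnot(is.matrix(nuclei))
  n <- max(nuclei)
  if (n == 0) return(list())
  H <- nrow(nuclei); W <- ncol(nuclei)
  anyNucleus <- nuclei > 0L

  minDist <- matrix(Inf, H, W)
  nearest <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    # distance of every pixel to nucleus k: distmap of the complement
    comp <- EBImage::Image((nuclei != k) * 1)
    dk <- asMatrixImage(EBImage::distmap(comp))
    upd <- dk < minDist          # strict: ties keep the lower label
    minDist[upd] <- dk[upd]
    nearest[upd] <- k
  }
  ring <- minDist > 0 & minDist <= maxDistance & !anyNucleus

  lapply(seq_len(n), function(k) {
    nuc <- which(nuclei == k)
    cyt <- which(ring & nearest == k)
    toPx <- function(idx) {
      m <- arrayInd(idx, c(H, W))
      colnames(m) <- c("row", "col")
      m
    }
    list(cellId = k, nucleus = toPx(nuc), cytoplasm = toPx(cyt))
  })
}

#' Per-cell MMP and death measurements over a time-lapse
#'
#' For every frame and cell: the mean rho123 intensity over the cell's
#' cytoplasm ring (the MMP proxy), the fraction of nuclear pixels positive
#' for PI, and the death flag, which is exactly the >= 10\% rule: a cell is
#' dead when at least 10\% of its nuclear pixels are PI-positive.
#'
#' @param frames list of frames, each a named list with matrices
#'   \code{rho123} and \code{pi}.
#' @param regions cell regions from \code{\link{buildCellRegions}}, built on
#'   frame-matched nuclei.
#' @param piThreshold "otsu" (per-frame Otsu on the PI channel) or a numeric
#'   intensity cutoff for PI positivity.
#' @param deathFractionThreshold nuclear PI fraction at or above which a
#'   cell is flagged dead (default 0.10).
#' @param aggregate "mean" (default) or "integrated" rho123 intensity.
#' @return data.frame: cell_id, t (frame index), rho123, pi_fraction, dead.
#' @export
measureMmpTimecourse <- function(frames, regions, piThreshold = "otsu",
                                 deathFractionThreshold = 0.10,
                                 aggregate = c("mean", "integrated")) {
  aggregate <- match.arg(aggregate)
  out <- lapply(seq_along(frames), function(t) {
    fr <- frames[[t]]
    if (!all(c("rho123", "pi") %in% names(fr)))
      stop("each frame needs 'rho123' and 'pi' channels")
    if (length(regions)) {
      mx <- vapply(regions, function(r)
        c(max(r$nucleus[, 1]), max(r$nucleus[, 2])), numeric(2))
      if (max(mx[1, ]) > nrow(fr$rho123) || max(mx[2, ]) > ncol(fr$rho123))
        stop("regions exceed frame dimensions")
    }
    thr <- if (identical(piThreshold, "otsu")) otsuThreshold(fr$pi)
           else as.numeric(piThreshold)
    do.call(rbind, lapply(regions, function(rg) {
      rho <- fr$rho123[rg$cytoplasm]
      piFrac <- mean(fr$pi[rg$nucleus] > thr)
      data.frame(
        cell_id = rg$cellId, t = t,
        rho123 = if (aggregate == "mean") mean(rho) else sum(rho),
        pi_fraction = piFrac,
        dead = piFrac >= deathFractionThreshold
      )
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of dead cells at one frame
#'
#' @param measurements output of \code{\link{measureMmpTimecourse}}.
#' @param frame frame index (default: last).
#' @return numeric(1) fraction of cells flagged dead.
#' @export
deathFraction <- function(measurements, frame = max(measurements$t)) {
  m <- measurements[measurements$t == frame, ]
  if (!nrow(m)) stop("no measurements at frame ", frame)
  mean(m$dead)
}

#' FRET ratio of an ATP biosensor image pair
#'
#' Determines the relevant cell area by thresholding the 408-nm emission
#' image (Otsu by default), then computes the ratio of mean intensities in
#' that area. The default orientation is 488/408; the result records the
#' orientation used. An empty cell area or a zero-mean denominator is an
#' error, never NaN.
#'
#' @param em408,em488 numeric matrices of equal shape (emission at 408 and
#'   488 nm under 408-nm excitation).
#' @param threshold "otsu" or a numeric cutoff applied to \code{em408}.
#' @param orientation "488/408" (default) or "408/488".
#' @return list: ratio, orientation, nPixels (cell-area size), mean408,
#'   mean488.
#' @export
measureFretRatio <- function(em408, em488, threshold = "otsu",
                             orientation = c("488/408", "408/488")) {
  orientation <- match.arg(orientation)
  stopifnot(identical(dim(em408), dim(em488)))
  thr <- if (identical(threshold, "otsu")) otsuThreshold(em408)
         else as.numeric(threshold)
  area <- em408 > thr
  if (!any(area))
    stop("empty cell area: nothing above threshold in the 408-nm image")
  m408 <- mean(em408[area]); m488 <- mean(em488[area])
  den <- if (orientation == "488/408") m408 else m488
  num <- if (orientation == "488/408") m488 else m408
  if (den == 0)
    stop("zero mean intensity in the denominator channel")
  list(ratio = num / den, orientation = orientation,
       nPixels = sum(area), mean408 = m408, mean488 = m488)
}

#' Normalize a measurement series to the vehicle control
#'
#' Divides each value by the vehicle value at the matched timepoint, so the
#' vehicle's own normalized series is identically 1. Replicate mean and SE
#' are computed after normalization.
#'
#' @param series data.frame with columns \code{timepoint}, \code{value} and
#'   optionally \code{replicate}.
#' @param vehicle data.frame with columns \code{timepoint}, \code{value}
#'   (one vehicle value per timepoint, e.g. the replicate mean).
#' @return list with \code{perValue} (the input plus \code{norm_value}) and
#'   \code{summary} (per timepoint: mean and SE of normalized values).
#' @export
normalizeToVehicle <- function(series, vehicle) {
  stopifnot(all(c("timepoint", "value") %in% names(series)),
            all(c("timepoint", "value") %in% names(vehicle)))
  i <- match(series$timepoint, vehicle$timepoint)
  if (anyNA(i))
    stop("vehicle series lacks timepoints: ",
         paste(unique(series$timepoint[is.na(i)]), collapse = ", "))
  v <- vehicle$value[i]
  if (any(v == 0)) stop("vehicle value is zero at a matched timepoint")
  out <- series
  out$norm_value <- series$value / v
  summ <- do.call(rbind, lapply(split(out, out$timepoint), function(g)
    data.frame(timepoint = g$timepoint[1], n = nrow(g),
               mean = mean(g$norm_value),
               se = if (nrow(g) > 1) se(g$norm_value) else NA_real_)))
  summ <- summ[order(summ$timepoint), ]
  rownames(summ) <- NULL
  list(perValue = out, summary = summ)
}

#' OPA1 cleavage ratio from band intensities
#'
#' The level of long OPA1 divided by total OPA1: \code{L / (L + S)}. 1 means
#' fully uncleaved (all long form), 0 fully cleaved.
#'
#' @param intensityL integrated intensity of the L-OPA1 band(s), >= 0.
#' @param intensityS integrated intensity of the S-OPA1 band(s), >= 0.
#' @return numeric in [0, 1]; vectorized.
#' @examples
#' opa1CleavageRatio(2, 2)  # 0.5
#' @export
opa1CleavageRatio <- function(intensityL, intensityS) {
  if (any(intensityL < 0) || any(intensityS < 0))
    stop("band intensities must be non-negative")
  tot <- intensityL + intensityS
  if (any(tot == 0)) stop("total OPA1 intensity is zero")
  intensityL / tot
}

#' Normalize a measurement by nuclear count
#'
#' Plate-level readouts (e.g. luminescence ATP assays) are normalized to the
#' number of nuclei detected in the matched image.
#'
#' @param rawValue measurement value(s).
#' @param nucleiCount nuclei count(s), >= 1.
#' @return normalized value(s).
#' @export
nucleiCountNormalize <- function(rawValue, nucleiCount) {
  if (any(nucleiCount < 1)) stop("nuclei count must be >= 1")
  rawValue / nucleiCount
}
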
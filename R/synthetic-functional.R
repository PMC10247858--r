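#' Plant a ground-truth time course for the MMP/death assay
#'
#' Builds per-cell rhodamine-123 intensity trajectories over hourly frames,
#' together with planted death events: each dead cell has an onset frame
#' after which a fixed fraction of its nuclear pixels turns propidium-iodide
#' (PI) positive. Live cells stay at PI fraction 0; the downstream death rule
#' flags a cell when at least 10\% of its nuclear pixels are PI positive.
#'
#' @param nCells number of cells.
#' @param nFrames number of hourly frames (default 25 = 0..24 h).
#' @param baseline mean rho123 intensity, a.u.
#' @param decayRate per-hour exponential decay of rho123 (0 = constant).
#' @param nDead number of planted dead cells (the first \code{nDead} cells).
#' @param deathOnset frame index (1-based) at which planted deaths occur.
#' @param piFraction nuclear pixel fraction turned PI-positive after onset;
#'   must be >= 0.1 for planted dead cells to be detectable.
#' @param jitterSd multiplicative per-cell trajectory jitter (sd, a.u.).
#' @param seed RNG seed.
#' @return list with \code{trajectories} (nCells x nFrames), \code{dead}
#'   (logical), \code{deathOnset} (integer, NA when alive) and
#'   \code{piFraction} (numeric per cell).
#' @export
timelapseTruth <- function(nCells, nFrames = 25L, baseline = 1000,
                           decayRate = 0, nDead = 0L, deathOnset = 1L,
                           piFraction = 0.15, jitterSd = 0, seed = 1L) {
  stopifnot(nDead <= nCells, deathOnset >= 1L, deathOnset <= nFrames)
  withSeed(seed, {
    t <- seq_len(nFrames) - 1L
    traj <- t(vapply(seq_len(nCells), function(i) {
      lvl <- baseline * exp(-decayRate * t)
      if (jitterSd > 0) lvl <- lvl * (1 + stats::rnorm(nFrames, 0, jitterSd))
      lvl
    }, numeric(nFrames)))
    dead <- seq_len(nCells) <= nDead
    list(trajectories = traj, dead = dead,
         deathOnset = ifelse(dead, as.integer(deathOnset), NA_integer_),
         piFraction = ifelse(dead, piFraction, 0))
  })
}

#' Render a synthetic MMP/death time-lapse
#'
#' Renders per-frame Hoechst (nuclei), rho123 and PI channels for a fixed
#' cell layout. Each cell's cytoplasm (ring around its nucleus) carries its
#' planted rho123 intensity; planted dead cells display PI signal on their
#' planted fraction of nuclear pixels from their onset frame onward.
#'
#' @param params a \code{\link{sceneParams}} (geometry, noise, background
#'   and seed are used; mitochondrial shape parameters are ignored).
#' @param truth a \code{\link{timelapseTruth}} list; its cell count must
#'   equal \code{params@nCells}.
#' @param ringDistance cytoplasm ring width in pixels (default 10).
#' @param piAmplitude intensity of PI-positive pixels, a.u.
#' @return list with \code{frames} (per frame: list of channel matrices
#'   \code{hoechst}, \code{rho123}, \code{pi}), the \code{nuclei} label
#'   matrix, the \code{regions} from \code{\link{buildCellRegions}} and the
#'   planted \code{truth}.
#' @export
generateMmpTimelapse <- function(params, truth, ringDistance = 10,
                                 piAmplitude = 3000) {
  if (nrow(truth$trajectories) != params@nCells)
    stop("truth defines ", nrow(truth$trajectories),
         " cells but params request ", params@nCells)
  nFrames <- ncol(truth$trajectories)
  withSeed(params@seed, {
    H <- params@imageSize[1]; W <- params@imageSize[2]
    centers <- placeCellCenters(params@nCells, H, W, params@nucleusRadius)
    nuclei <- matrix(0L, H, W)
    for (i in seq_len(params@nCells)) {
      px <- rasterEllipse(centers[i, ], params@nucleusRadius,
                          params@nucleusRadius, 0, H, W)
      nuclei[px] <- i
    }
    regions <- buildCellRegions(nuclei, maxDistance = ringDistance)
    # fix the PI-positive pixel subset per cell once, so it persists in time
    piPixels <- lapply(seq_len(params@nCells), function(i) {
      nuc <- regions[[i]]$nucleus
      k <- round(truth$piFraction[i] * nrow(nuc))
      if (k == 0) return(nuc[0, , drop = FALSE])
      nuc[sample.int(nrow(nuc), k), , drop = FALSE]
    })
    hoechstBase <- matrix(params@backgroundLevel, H, W)
    hoechstBase[nuclei > 0L] <- params@backgroundLevel + params@amplitude

    frames <- lapply(seq_len(nFrames), function(t) {
      rho <- matrix(params@backgroundLevel, H, W)
      pi_ <- matrix(params@backgroundLevel, H, W)
      for (i in seq_len(params@nCells)) {
        cyto <- regions[[i]]$cytoplasm
        rho[cyto] <- truth$trajectories[i, t]
        if (isTRUE(truth$dead[i]) && t >= truth$deathOnset[i] &&
            nrow(piPixels[[i]]) > 0)
          pi_[piPixels[[i]]] <- piAmplitude
      }
      list(hoechst = clipIntensity(addCameraNoise(hoechstBase, params@noise)),
           rho123 = clipIntensity(addCameraNoise(rho, params@noise)),
           pi = clipIntensity(addCameraNoise(pi_, params@noise)))
    })
    list(frames = frames, nuclei = nuclei, regions = regions, truth = truth)
  })
}

#' Render a FRET emission image pair with a planted per-pixel ratio
#'
#' Produces the donor-excitation emission pair of an ATP FRET biosensor: the
#' 408-nm emission image carries the base intensity inside the cell mask and
#' background elsewhere, and the 488-nm emission equals the 408 signal times
#' the planted ratio, so the expected per-pixel 488/408 ratio inside the
#' cell area equals \code{ratioMap}.
#'
#' @param ratioMap numeric matrix of planted 488/408 ratios; must be strictly
#'   positive inside the cell mask.
#' @param cellMask logical matrix of cell pixels (default: everywhere).
#' @param baseIntensity 408-nm emission inside cells, a.u.
#' @param background intensity outside cells, a.u.
#' @param gaussianSd additive Gaussian noise sd (applied to both images).
#' @param seed RNG seed (only used when \code{gaussianSd > 0}).
#' @return list with matrices \code{em408} and \code{em488}.
#' @export
generateFretPair <- function(ratioMap, cellMask = NULL, baseIntensity = 1000,
                             background = 10, gaussianSd = 0, seed = 1L) {
  if (is.null(cellMask)) cellMask <- matrix(TRUE, nrow(ratioMap), ncol(ratioMap))
  stopifnot(identical(dim(ratioMap), dim(cellMask)))
  if (any(ratioMap[cellMask] <= 0))
    stop("planted FRET ratios must be strictly positive inside the cell mask")
  em408 <- matrix(background, nrow(ratioMap), ncol(ratioMap))
  em408[cellMask] <- baseIntensity
  em488 <- matrix(background, nrow(ratioMap), ncol(ratioMap))
  em488[cellMask] <- baseIntensity * ratioMap[cellMask]
  if (gaussianSd > 0) {
    withSeed(seed, {
      em408 <- em408 + matrix(stats::rnorm(length(em408), 0, gaussianSd),
                              nrow(em408))
      em488 <- em488 + matrix(stats::rnorm(length(em488), 0, gaussianSd),
                              nrow(em488))
    })
  }
  list(em408 = em408, em488 = em488)
}

#' Sample a feature table directly from a Gaussian mixture
#'
#' Draws i.i.d. feature vectors from a \linkS4class{GmmModel}, returning the
#' true generating component per row. Used to test the EM fitter against
#' known parameters without running the imaging pipeline.
#'
#' @param model a \linkS4class{GmmModel}.
#' @param n number of draws (0 gives an empty table).
#' @param seed RNG seed.
#' @return data.frame with the model's feature columns plus a
#'   \code{component} integer column (the true generating component).
#' @export
sampleFeatureTable <- function(model, n, seed = 1L) {
  validObject(model)
  d <- ncol(model@means)
  chols <- lapply(model@covariances, chol)
  withSeed(seed, {
    comp <- if (n > 0)
      sample.int(length(model@weights), n, replace = TRUE,
                 prob = model@weights)
    else integer(0)
    x <- matrix(NA_real_, n, d)
    for (k in seq_along(model@weights)) {
      idx <- which(comp == k)
      if (!length(idx)) next
      z <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
      x[idx, ] <- z %*% chols[[k]] +
        matrix(model@means[k, ], length(idx), d, byrow = TRUE)
    }
    out <- as.data.frame(x)
    names(out) <- model@featureNames
    out$component <- comp
    out
  })
}
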
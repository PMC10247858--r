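#' Reference well-separated mixture over the four shape features
#'
#' A fixed two-component Gaussian mixture in (area, perimeter, formfactor,
#' solidity) space emulating the fitted morphology model: a "fragmented"
#' component of small, round, convex objects and a "fused" component of
#' large, irregular objects with a much larger variance in area and
#' perimeter. The Mahalanobis separation between the components exceeds 4,
#' so parameter-recovery experiments on samples from this model are
#' well-posed.
#'
#' @param weights mixing weights (fragmented, fused).
#' @return A \linkS4class{GmmModel} usable with
#'   \code{\link{sampleFeatureTable}}.
#' @export
referenceGmm <- function(weights = c(0.6, 0.4)) {
  featureNames <- c("area_px", "perimeter_px", "formfactor", "solidity")
  means <- rbind(
    fragmented = c(45, 26, 0.78, 0.92),
    fused = c(320, 150, 0.22, 0.55)
  )
  colnames(means) <- featureNames
  covFrag <- matrix(c(
    120,   35,  -0.2,  -0.05,
     35,   25,  -0.1,  -0.02,
    -0.2, -0.1, 0.004,  0.001,
   -0.05, -0.02, 0.001, 0.002), 4, 4)
  covFused <- matrix(c(
    9000, 2500,  -1.5,  -1.0,
    2500, 1600,  -0.8,  -0.5,
    -1.5, -0.8, 0.006,  0.002,
    -1.0, -0.5, 0.002,  0.008), 4, 4)
  new("GmmModel",
      weights = weights / sum(weights), means = means,
      covariances = list(covFrag, covFused),
      negLogLik = NA_real_, logLikHistory = numeric(0),
      nRestarts = 0L, seed = 0L,
      classMap = c(`1` = "fragmented", `2` = "fused"),
      featureNames = featureNames)
}

#' Parameter-recovery experiment for the EM fitter
#'
#' Samples \code{n} objects from \code{\link{referenceGmm}}, refits the
#' mixture by multi-restart EM, matches components by mean area and records
#' the worst relative mean error and worst absolute weight error, repeated
#' over \code{nSeeds} independent seeds.
#'
#' @param nSeeds number of independent repetitions.
#' @param n sample size per repetition.
#' @param nRestarts EM restarts per fit.
#' @param seed master seed.
#' @return data.frame per repetition: seed, max_rel_mean_error,
#'   max_abs_weight_error.
#' @export
benchmarkGmmRecovery <- function(nSeeds = 10L, n = 10000L, nRestarts = 10L,
                                 seed = 1L) {
  truth <- referenceGmm()
  seeds <- deriveSeeds(seed, nSeeds)
  out <- lapply(seeds, function(s) {
    tab <- sampleFeatureTable(truth, n, seed = s)
    fit <- fitGmm(tab[, truth@featureNames], nRestarts = nRestarts, seed = s)
    # align components to the truth by class name
    ord <- match(c("fragmented", "fused"), fit@classMap)
    relErr <- abs(fit@means[ord, ] - truth@means) / abs(truth@means)
    wErr <- abs(fit@weights[ord] - truth@weights)
    data.frame(seed = s,
               max_rel_mean_error = max(relErr),
               max_abs_weight_error = max(wErr))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Segmentation benchmark against generator ground truth
#'
#' Trains the LoG/DoG random-forest pixel classifier on truth-derived
#' annotations from training scenes, then scores the predicted masks of
#' fresh scenes against their ground truth by intersection-over-union.
#'
#' @param nScenes number of evaluation scenes.
#' @param imageSize scene size in px (default 256; the statistic is
#'   intensive, not size-dependent).
#' @param seed master seed.
#' @param nTrain number of training scenes.
#' @param nPerClass annotated pixels per class per training scene.
#' @param nTrees random-forest size.
#' @return data.frame per scene: seed, iou.
#' @export
benchmarkSegmentationIoU <- function(nScenes = 20L, imageSize = c(256L, 256L),
                                     seed = 1L, nTrain = 2L,
                                     nPerClass = 500L, nTrees = 100L) {
  seeds <- deriveSeeds(seed, nScenes + nTrain + 1L)
  mkScene <- function(s) generateMitoScene(sceneParams(
    imageSize = imageSize, nCells = 4L, nucleusRadius = 10,
    objectsPerCell = c(5L, 10L),
    fragmentedShape = list(areaRange = c(20, 80),
                           eccentricityRange = c(0, 0.7)),
    fusedShape = list(tubeLengthRange = c(20, 60), tubeWidth = 4,
                      branchProbability = 0.3),
    seed = s))
  trainScenes <- lapply(seeds[seq_len(nTrain)], mkScene)
  ann <- do.call(rbind, lapply(seq_len(nTrain), function(i)
    annotateFromTruth(trainScenes[[i]], i, nPerClass = nPerClass,
                      seed = seeds[nTrain + 1L] + i)))
  model <- trainPixelClassifier(lapply(trainScenes, function(s)
    channels(s)$mito), ann, nTrees = nTrees, seed = seed)
  out <- lapply(seeds[nTrain + 1L + seq_len(nScenes)], function(s) {
    sc <- mkScene(s)
    mask <- predictSegmentation(model, channels(sc)$mito)
    data.frame(seed = s, iou = maskIoU(mask, truthMask(sc) > 0L))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' End-to-end morphology classification benchmark
#'
#' Generates replicate scenes with a planted fragmented fraction, measures
#' the ground-truth objects, fits the pooled two-component mixture,
#' classifies every object and compares against the generator's truth
#' labels: per-object agreement and the count-based fragmented fraction
#' versus the planted value.
#'
#' @param fragmentedFraction planted fraction of fragmented objects.
#' @param nReplicates replicate scenes.
#' @param imageSize scene size, px.
#' @param nRestarts EM restarts for the pooled fit.
#' @param seed master seed.
#' @return list: \code{agreement} (per-object label agreement in [0,1]),
#'   \code{plantedFraction}, \code{recoveredFraction} (mean count-based
#'   fraction across replicates), \code{perReplicate} data.frame.
#' @export
benchmarkClassificationAgreement <- function(fragmentedFraction = 0.5,
                                             nReplicates = 3L,
                                             imageSize = c(256L, 256L),
                                             nRestarts = 10L, seed = 1L) {
  seeds <- deriveSeeds(seed, nReplicates)
  featureCols <- c("area_px", "perimeter_px", "formfactor", "solidity")
  feats <- list(); truthLab <- list()
  for (r in seq_len(nReplicates)) {
    sc <- generateMitoScene(sceneParams(
      imageSize = imageSize, nCells = 4L, nucleusRadius = 10,
      objectsPerCell = c(6L, 12L),
      fragmentedFraction = fragmentedFraction,
      fusedShape = list(tubeLengthRange = c(25, 70), tubeWidth = 4,
                        branchProbability = 0.3),
      seed = seeds[r]))
    f <- measureObjects(truthMask(sc), metadata = list(
      image_id = sprintf("scene%d", r), condition = "planted",
      replicate = r))
    feats[[r]] <- f
    truthLab[[r]] <- truthLabels(sc)
  }
  features <- do.call(rbind, feats)
  truth <- unlist(truthLab)
  fit <- fitGmm(features[, featureCols], nRestarts = nRestarts, seed = seed)
  assignment <- assignClasses(fit, features[, featureCols])
  agreement <- mean(assignment$class == truth)
  fr <- fractionFragmented(features, assignment)
  list(agreement = agreement,
       plantedFraction = fragmentedFraction,
       recoveredFraction = fr$summary$mean_fraction_by_count[1],
       perReplicate = fr$perReplicate)
}

#' Type-I error of the one-way ANOVA under the null
#'
#' Simulates experiments with all group means equal and returns the
#' rejection rate at level \code{alpha}.
#'
#' @param nSim simulated experiments.
#' @param k number of groups.
#' @param nPer replicates per group.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return numeric(1) rejection rate.
#' @export
simulateAnovaTypeI <- function(nSim = 5000L, k = 3L, nPer = 5L,
                               alpha = 0.05, seed = 1L) {
  withSeed(seed, {
    groups <- rep(seq_len(k), each = nPer)
    rej <- vapply(seq_len(nSim), function(i) {
      y <- stats::rnorm(k * nPer)
      anovaOneway(y, groups)$p < alpha
    }, logical(1))
    mean(rej)
  })
}

#' Familywise error of the Dunnett test under the null
#'
#' Simulates experiments with one control and \code{k} treatment groups, all
#' drawn from the same normal distribution, and returns the fraction of
#' experiments in which at least one comparison is (falsely) flagged
#' significant.
#'
#' @param nSim simulated experiments.
#' @param k number of treatment groups.
#' @param nPer replicates per group.
#' @param alpha familywise level.
#' @param seed RNG seed.
#' @return numeric(1) familywise error rate.
#' @export
simulateDunnettFwer <- function(nSim = 5000L, k = 4L, nPer = 5L,
                                alpha = 0.05, seed = 1L) {
  withSeed(seed, {
    groups <- rep(c("control", paste0("t", seq_len(k))), each = nPer)
    rej <- vapply(seq_len(nSim), function(i) {
      y <- stats::rnorm((k + 1L) * nPer)
      any(dunnettTest(y, groups, "control", alpha = alpha)$significant)
    }, logical(1))
    mean(rej)
  })
}

#' Recovery of planted functional readouts
#'
#' Renders seeded MMP time-lapses with a constant planted rho123 intensity
#' and FRET pairs with a planted uniform ratio, measures them with the
#' package's readout functions, and reports recovery errors together with
#' their 3-sigma noise bounds.
#'
#' @param nScenes number of seeded repetitions.
#' @param plantedRho planted cytoplasmic rho123 intensity, a.u.
#' @param plantedRatio planted FRET 488/408 ratio.
#' @param gaussianSd additive noise sd, a.u.
#' @param seed master seed.
#' @return data.frame per scene: rho_error, rho_bound, fret_error,
#'   fret_bound (errors are absolute, bounds are 3 sigma of the respective
#'   estimator).
#' @export
benchmarkReadoutRecovery <- function(nScenes = 20L, plantedRho = 1000,
                                     plantedRatio = 0.5, gaussianSd = 20,
                                     seed = 1L) {
  seeds <- deriveSeeds(seed, nScenes)
  out <- lapply(seeds, function(s) {
    params <- sceneParams(imageSize = c(128L, 128L), nCells = 4L,
                          nucleusRadius = 9,
                          noise = list(gaussianSd = gaussianSd,
                                       poissonScale = 0),
                          seed = s)
    truth <- timelapseTruth(4L, nFrames = 2L, baseline = plantedRho,
                            seed = s)
    tl <- generateMmpTimelapse(params, truth)
    mm <- measureMmpTimecourse(tl$frames, tl$regions, piThreshold = 500)
    # scene-level estimate: cytoplasm means averaged over cells and frames,
    # weighted by ring size through the pixel count of the pooled estimator
    nCyto <- vapply(tl$regions, function(r) nrow(r$cytoplasm), numeric(1))
    rhoErr <- abs(mean(mm$rho123) - plantedRho)
    # var of the mean of per-ring means: sum(sd^2/n_i)/m^2 per frame
    rhoBound <- 3 * gaussianSd *
      sqrt(sum(1 / nCyto) / length(nCyto)^2 / length(tl$frames))

    H <- 96L
    mask <- matrix(FALSE, H, H); mask[25:72, 25:72] <- TRUE
    ratio <- matrix(plantedRatio, H, H)
    pair <- generateFretPair(ratio, mask, baseIntensity = 2000,
                             gaussianSd = gaussianSd, seed = s)
    fr <- measureFretRatio(pair$em408, pair$em488)
    # delta-method sd of a ratio of two independent sample means
    n <- fr$nPixels
    sdRatio <- plantedRatio * gaussianSd / sqrt(n) *
      sqrt(1 / 2000^2 + 1 / (2000 * plantedRatio)^2)
    data.frame(seed = s, rho_error = rhoErr, rho_bound = rhoBound,
               fret_error = abs(fr$ratio - plantedRatio),
               fret_bound = 3 * sdRatio)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
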
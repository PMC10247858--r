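#' Data-size robustness of the mixture fit
#'
#' Refits the two-component mixture on subsamples of the object table and
#' reports the distribution of per-component, per-feature means and
#' variances. Three schemes mirror the robustness questions of the original
#' analysis: \code{leave_one_compound_out} drops one compound at a time,
#' \code{image_halves} refits on random halves of the images, and
#' \code{object_fraction} refits on a random fraction (for example 1/2,
#' 1/10 or 1/500) of all objects.
#'
#' A subsample too small to fit (fewer than 4 distinct rows) is reported
#' with \code{fitted = FALSE} rather than failing the whole analysis.
#'
#' @param features object-feature data.frame; must contain the four feature
#'   columns plus \code{compound} (for leave-one-out) or \code{image_id}
#'   (for image halves).
#' @param scheme one of "leave_one_compound_out", "image_halves",
#'   "object_fraction".
#' @param nReps number of random subsamples (ignored for leave-one-out,
#'   which uses every compound once).
#' @param fraction object fraction for scheme "object_fraction".
#' @param featureCols names of the feature columns.
#' @param nRestarts EM restarts per refit.
#' @param seed RNG seed; identical seeds give identical reports.
#' @return data.frame with one row per subsample x component x feature:
#'   scheme, rep, subset descriptor, n_objects, fitted, component, class,
#'   feature, mean, variance, seed.
#' @export
robustnessAnalysis <- function(features,
                               scheme = c("leave_one_compound_out",
                                          "image_halves", "object_fraction"),
                               nReps = 100L, fraction = 0.5,
                               featureCols = c("area_px", "perimeter_px",
                                               "formfactor", "solidity"),
                               nRestarts = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(all(featureCols %in% names(features)))
  subsets <- switch(scheme,
    leave_one_compound_out = {
      if (!"compound" %in% names(features))
        stop("leave_one_compound_out needs a 'compound' column")
      comps <- sort(unique(features$compound))
      lapply(comps, function(cp) list(
        descriptor = paste0("without_", cp),
        rows = which(features$compound != cp)))
    },
    image_halves = {
      if (!"image_id" %in% names(features))
        stop("image_halves needs an 'image_id' column")
      imgs <- sort(unique(features$image_id))
      seeds <- deriveSeeds(seed, nReps)
      lapply(seq_len(nReps), function(r) withSeed(seeds[r], {
        half <- sample(imgs, ceiling(length(imgs) / 2))
        list(descriptor = paste0("half_", r),
             rows = which(features$image_id %in% half))
      }))
    },
    object_fraction = {
      seeds <- deriveSeeds(seed, nReps)
      lapply(seq_len(nReps), function(r) withSeed(seeds[r], {
        n <- max(1L, round(fraction * nrow(features)))
        list(descriptor = sprintf("fraction_%g_rep_%d", fraction, r),
             rows = sample.int(nrow(features), n))
      }))
    })

  fitSeeds <- deriveSeeds(seed + 1L, length(subsets))
  out <- lapply(seq_along(subsets), function(i) {
    rows <- subsets[[i]]$rows
    x <- features[rows, featureCols, drop = FALSE]
    base <- expand.grid(component = 1:2, feature = featureCols,
                        stringsAsFactors = FALSE)
    base$scheme <- scheme
    base$rep <- i
    base$subset <- subsets[[i]]$descriptor
    base$n_objects <- nrow(x)
    base$seed <- fitSeeds[i]
    if (nrow(unique(as.matrix(x))) < 4L) {
      base$fitted <- FALSE
      base$class <- NA_character_
      base$mean <- NA_real_
      base$variance <- NA_real_
      return(base)
    }
    fit <- fitGmm(x, nRestarts = nRestarts, seed = fitSeeds[i])
    base$fitted <- TRUE
    idx <- cbind(base$component, match(base$feature, fit@featureNames))
    base$class <- unname(fit@classMap[base$component])
    base$mean <- fit@means[idx]
    base$variance <- vapply(seq_len(nrow(base)), function(j)
      fit@covariances[[base$component[j]]][idx[j, 2], idx[j, 2]],
      numeric(1))
    base
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("scheme", "rep", "subset", "n_objects", "fitted", "seed",
          "component", "class", "feature", "mean", "variance")]
}
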
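#' Fit a two-component Gaussian mixture by multi-restart EM
#'
#' Fits a full-covariance Gaussian mixture to the object-feature table by
#' expectation-maximization, restarted from \code{nRestarts} random
#' initializations; the restart with the lowest negative log-likelihood is
#' returned. Per restart, means are drawn from random data rows, covariances
#' start at the pooled data covariance, and weights start uniform. Every
#' covariance update is regularized with \code{1e-6 * mean(diag(S))} on the
#' diagonal so degenerate subsamples cannot crash the fit. EM iterations are
#' guaranteed non-decreasing in data log-likelihood (up to numerical
#' tolerance); convergence is declared when the relative change of the
#' negative log-likelihood falls below \code{tol} or after \code{maxIter}
#' iterations. Restart seeds are drawn as a nested stream from \code{seed}:
#' the first \code{m} restarts of any run are identical across runs, so the
#' best negative log-likelihood is non-increasing in \code{nRestarts}.
#'
#' Components are mapped to the morphology classes by
#' \code{\link{mapComponentNames}} when the feature table contains an area
#' column.
#'
#' @param features numeric matrix or data.frame of features (typically
#'   area_px, perimeter_px, formfactor, solidity).
#' @param k number of components (the morphology model uses 2).
#' @param nRestarts number of random EM restarts (default 100).
#' @param seed RNG seed for the restart stream.
#' @param tol relative negative log-likelihood convergence tolerance.
#' @param maxIter maximal EM iterations per restart.
#' @param standardize z-score features before fitting (sensitivity analysis
#'   only; the production model fits raw pixel-unit features).
#' @param mapClasses name components fragmented/fused by mean area
#'   (requires k = 2).
#' @return A \linkS4class{GmmModel}.
#' @examples
#' x <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 6), 100))
#' colnames(x) <- c("a", "b")
#' fitGmm(x, nRestarts = 5, seed = 1, mapClasses = FALSE)
#' @export
fitGmm <- function(features, k = 2L, nRestarts = 100L, seed = 1L,
                   tol = 1e-6, maxIter = 500L, standardize = FALSE,
                   mapClasses = TRUE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("features must be finite")
  if (nrow(unique(x)) < 2L * k)
    stop("need at least ", 2L * k, " distinct feature rows to fit ",
         k, " components")
  featureNames <- colnames(x)
  if (is.null(featureNames)) featureNames <- paste0("f", seq_len(ncol(x)))
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x); scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  }

  restartSeeds <- deriveSeeds(seed, nRestarts)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(restartSeeds[r], emOneRestart(x, k, tol, maxIter))
    if (is.null(best) || fit$negLogLik < best$negLogLik) best <- fit
  }
  if (standardize) best <- unstandardizeFit(best, center, scale)

  model <- new("GmmModel",
    weights = best$weights, means = best$means,
    covariances = best$covariances, negLogLik = best$negLogLik,
    logLikHistory = best$history, nRestarts = as.integer(nRestarts),
    seed = as.integer(seed), classMap = character(0),
    featureNames = featureNames)
  colnames(model@means) <- featureNames
  if (mapClasses && k == 2L) model@classMap <- mapComponentNames(model)
  model
}

# one EM run from a random initialization; x already standardized if wanted
emOneRestart <- function(x, k, tol, maxIter) {
  n <- nrow(x); d <- ncol(x)
  mu <- x[sample.int(n, k), , drop = FALSE]
  pooled <- stats::cov(x)
  pooled <- regularizeCov(pooled)
  sigma <- replicate(k, pooled, simplify = FALSE)
  w <- rep(1 / k, k)

  ll <- -Inf
  history <- numeric(0)
  for (iter in seq_len(maxIter)) {
    # E-step in log space
    logDens <- vapply(seq_len(k), function(j)
      log(w[j]) + dmvnormLog(x, mu[j, ], sigma[[j]]), numeric(n))
    m <- apply(logDens, 1, max)
    lse <- m + log(rowSums(exp(logDens - m)))
    newLL <- sum(lse)
    history <- c(history, newLL)
    resp <- exp(logDens - lse)

    # M-step
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2, mu[j, ])
      S <- crossprod(xc * resp[, j], xc) / nk[j]
      sigma[[j]] <- regularizeCov(S)
    }
    if (is.finite(ll) && abs(newLL - ll) < tol * abs(newLL)) {
      ll <- newLL
      break
    }
    ll <- newLL
  }
  list(weights = w, means = mu, covariances = sigma,
       negLogLik = -ll, history = history)
}

# trace-scaled ridge keeps covariances positive definite on degenerate data
regularizeCov <- function(S) {
  d <- ncol(S)
  S <- (S + t(S)) / 2
  eps <- 1e-6 * mean(diag(S))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-10
  S + diag(eps, d)
}

dmvnormLog <- function(x, mu, sigma) {
  d <- length(mu)
  ch <- chol(sigma)
  xc <- sweep(x, 2, mu)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

unstandardizeFit <- function(fit, center, scale) {
  k <- length(fit$weights)
  D <- diag(scale, length(scale))
  for (j in seq_len(k)) {
    fit$means[j, ] <- fit$means[j, ] * scale + center
    fit$covariances[[j]] <- D %*% fit$covariances[[j]] %*% D
  }
  # likelihood is reported on the standardized scale it was fit on
  fit
}

#' Log-likelihood of data under a Gaussian mixture
#'
#' \eqn{\sum_i \log \sum_k \pi_k N(x_i; \mu_k, \Sigma_k)}, evaluated in log
#' space for numerical stability.
#'
#' @param model a \linkS4class{GmmModel}.
#' @param features numeric matrix/data.frame with the model's feature
#'   dimension.
#' @return numeric(1).
#' @export
gmmLogLik <- function(model, features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(model@means))
    stop("feature dimension mismatch: model has ", ncol(model@means),
         " features, data has ", ncol(x))
  logDens <- vapply(seq_along(model@weights), function(j)
    log(model@weights[j]) +
      dmvnormLog(x, model@means[j, ], model@covariances[[j]]),
    numeric(nrow(x)))
  if (nrow(x) == 1L) logDens <- matrix(logDens, 1)
  m <- apply(logDens, 1, max)
  sum(m + log(rowSums(exp(logDens - m))))
}

#' Posterior class assignment of objects
#'
#' Computes per-object posterior component probabilities by Bayes' rule and
#' assigns each object to the maximum-posterior component (ties break toward
#' the lower component index). When the model carries a class map, the hard
#' component label is translated to "fragmented"/"fused".
#'
#' @param model a \linkS4class{GmmModel}.
#' @param features numeric matrix/data.frame in the model's feature space.
#' @return data.frame with posterior columns \code{posterior_1..K},
#'   \code{component} (hard label) and, if mapped, \code{class}.
#' @export
assignClasses <- function(model, features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(model@means))
    stop("feature dimension mismatch")
  K <- length(model@weights)
  logDens <- vapply(seq_len(K), function(j)
    log(model@weights[j]) +
      dmvnormLog(x, model@means[j, ], model@covariances[[j]]),
    numeric(nrow(x)))
  if (nrow(x) == 1L) logDens <- matrix(logDens, 1)
  m <- apply(logDens, 1, max)
  post <- exp(logDens - m)
  post <- post / rowSums(post)
  hard <- max.col(post, ties.method = "first")
  out <- as.data.frame(post)
  names(out) <- paste0("posterior_", seq_len(K))
  out$component <- hard
  if (length(model@classMap))
    out$class <- unname(model@classMap[hard])
  out
}

#' Name mixture components by mean object area
#'
#' The component with the smaller mean area is called "fragmented", the
#' other "fused". The naming is a post-hoc convention: the unsupervised fit
#' itself carries no class identity. Exactly equal mean areas are refused
#' and demand a manual assignment.
#'
#' @param model a two-component \linkS4class{GmmModel} whose first feature
#'   (or a feature whose name contains "area") is the object area.
#' @return named character of length 2, component index -> class.
#' @export
mapComponentNames <- function(model) {
  if (length(model@weights) != 2L)
    stop("class naming is defined for two components")
  areaCol <- grep("area", model@featureNames, ignore.case = TRUE)[1]
  if (is.na(areaCol)) areaCol <- 1L
  a <- model@means[, areaCol]
  if (a[1] == a[2])
    stop("components have exactly equal mean area; assign classes manually")
  if (a[1] < a[2]) c(`1` = "fragmented", `2` = "fused")
  else c(`1` = "fused", `2` = "fragmented")
}
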
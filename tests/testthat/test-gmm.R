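test_that("mixture log-likelihood matches the naive oracle", {
  m <- referenceGmm()
  tab <- sampleFeatureTable(m, 100L, seed = 3L)
  x <- tab[, m@featureNames]
  ll <- gmmLogLik(m, x)
  expect_equal(ll, naiveGmmLogLik(m, x), tolerance = 1e-10)
  # additivity: duplicated data doubles the log-likelihood
  expect_equal(gmmLogLik(m, rbind(x, x)), 2 * ll, tolerance = 1e-12)
})

test_that("single point at a component mean gives the closed form", {
  m <- referenceGmm(weights = c(1, 1e-12))
  x <- matrix(m@means[1, ], 1)
  closed <- mvtnorm::dmvnorm(m@means[1, ], m@means[1, ],
                             m@covariances[[1]], log = TRUE)
  expect_equal(gmmLogLik(m, x), log(m@weights[1]) + closed,
               tolerance = 1e-6)
})

test_that("EM recovers parameters of a well-separated mixture", {
  truth <- referenceGmm()
  tab <- sampleFeatureTable(truth, 10000L, seed = 4L)
  fit <- fitGmm(tab[, truth@featureNames], nRestarts = 10L, seed = 4L)
  ord <- match(c("fragmented", "fused"), fit@classMap)
  expect_lt(max(abs(fit@means[ord, ] - truth@means) / abs(truth@means)),
            0.05)
  expect_lt(max(abs(fit@weights[ord] - truth@weights)), 0.03)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  truth <- referenceGmm()
  tab <- sampleFeatureTable(truth, 2000L, seed = 5L)
  fit <- fitGmm(tab[, truth@featureNames], nRestarts = 5L, seed = 5L)
  h <- fit@logLikHistory
  expect_true(all(diff(h) >= -1e-8 * pmax(1, abs(h[-1]))))
})

test_that("best of many restarts dominates best of one (nested seeds)", {
  truth <- referenceGmm()
  tab <- sampleFeatureTable(truth, 500L, seed = 6L)
  x <- tab[, truth@featureNames]
  f1 <- fitGmm(x, nRestarts = 1L, seed = 7L, mapClasses = FALSE)
  f20 <- fitGmm(x, nRestarts = 20L, seed = 7L, mapClasses = FALSE)
  expect_lte(f20@negLogLik, f1@negLogLik + 1e-9)
})

test_that("degenerate near-point data is survived via regularization", {
  x <- matrix(rep(c(1, 2, 3, 4), each = 50), 50, 4)
  x <- x + matrix(rnorm(200, 0, 1e-8), 50, 4)
  colnames(x) <- c("a", "b", "c", "d")
  fit <- fitGmm(x, nRestarts = 3L, seed = 1L, mapClasses = FALSE)
  expect_s4_class(fit, "GmmModel")
  expect_true(all(is.finite(fit@negLogLik)))
  # too few distinct rows is an error
  expect_error(fitGmm(matrix(rep(1:4, 3), 3, 4, byrow = TRUE)), "distinct")
})

test_that("posteriors normalize and argmax picks the nearer component", {
  m <- referenceGmm()
  tab <- sampleFeatureTable(m, 500L, seed = 8L)
  a <- assignClasses(m, tab[, m@featureNames])
  expect_true(all(abs(a$posterior_1 + a$posterior_2 - 1) < 1e-12))
  expect_identical(a$component,
                   max.col(cbind(a$posterior_1, a$posterior_2),
                           ties.method = "first"))
  # a point at a component mean is assigned there with high confidence
  at1 <- assignClasses(m, matrix(m@means[1, ], 1))
  expect_equal(at1$component, 1L)
  expect_gt(at1$posterior_1, 0.99)
})

test_that("equidistant point between symmetric components splits 50/50", {
  m <- new("GmmModel",
           weights = c(0.5, 0.5),
           means = rbind(c(-2, 0), c(2, 0)),
           covariances = list(diag(2), diag(2)),
           negLogLik = NA_real_, logLikHistory = numeric(0),
           nRestarts = 0L, seed = 0L, classMap = character(0),
           featureNames = c("x", "y"))
  a <- assignClasses(m, matrix(c(0, 5), 1))
  expect_equal(a$posterior_1, 0.5, tolerance = 1e-12)
  expect_equal(a$component, 1L)  # tie breaks toward the lower index
})

test_that("component naming follows mean area and is permutation-stable", {
  m <- referenceGmm()
  expect_identical(unname(mapComponentNames(m)[1]), "fragmented")
  # swap components: the semantics must not change
  ms <- new("GmmModel",
            weights = rev(m@weights), means = m@means[2:1, ],
            covariances = m@covariances[2:1],
            negLogLik = NA_real_, logLikHistory = numeric(0),
            nRestarts = 0L, seed = 0L, classMap = character(0),
            featureNames = m@featureNames)
  expect_identical(unname(mapComponentNames(ms)[2]), "fragmented")
  tie <- ms
  tie@means[1, ] <- tie@means[2, ]
  tie@covariances[[1]] <- tie@covariances[[2]]
  expect_error(mapComponentNames(tie), "equal mean area")
})

test_that("fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  truth <- referenceGmm()
  tab <- sampleFeatureTable(truth, 3000L, seed = 9L)
  x <- as.matrix(tab[, truth@featureNames])
  fit <- fitGmm(x, nRestarts = 10L, seed = 9L)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  # same likelihood optimum (mclust maximizes logLik = -negLogLik)
  expect_equal(-fit@negLogLik, mc$loglik, tolerance = 0.01 * abs(mc$loglik))
  ordFit <- order(fit@means[, 1])
  ordMc <- order(mc$parameters$mean[1, ])
  expect_equal(unname(fit@means[ordFit, ]),
               unname(t(mc$parameters$mean)[ordMc, ]), tolerance = 0.02)
})

test_that("model JSON serialization round-trips exactly", {
  truth <- referenceGmm()
  tab <- sampleFeatureTable(truth, 500L, seed = 10L)
  fit <- fitGmm(tab[, truth@featureNames], nRestarts = 3L, seed = 10L)
  path <- withr::local_tempfile(fileext = ".json")
  writeGmmModel(fit, path)
  back <- readGmmModel(path)
  expect_equal(back@weights, fit@weights)
  expect_equal(back@means, fit@means)
  expect_equal(back@covariances, fit@covariances)
  expect_identical(back@classMap, fit@classMap)
  x <- as.matrix(tab[, truth@featureNames])
  expect_equal(gmmLogLik(back, x), gmmLogLik(fit, x))
})
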
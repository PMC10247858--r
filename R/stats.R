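#' One-way fixed-effects ANOVA
#'
#' Classical equal-variance one-way ANOVA on grouped replicate values.
#'
#' @param values numeric vector of measurements.
#' @param groups factor/character vector of group labels, same length.
#' @return list: \code{F}, \code{p}, \code{df1}, \code{df2}, \code{msError}
#'   (pooled error mean square), \code{groupMeans}, \code{groupN}.
#' @export
anovaOneway <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  ni <- tabulate(groups)
  if (any(ni < 2L)) stop("need at least two values per group")
  n <- length(values)
  k <- nlevels(groups)
  mi <- tapply(values, groups, mean)
  gm <- mean(values)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[groups])^2)
  df1 <- k - 1L
  df2 <- n - k
  msw <- ssw / df2
  Fstat <- if (ssb == 0) 0
           else if (msw == 0) Inf
           else (ssb / df1) / msw
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = df1, df2 = df2, msError = msw,
       groupMeans = mi, groupN = ni)
}

#' Dunnett's many-to-one comparisons against a control
#'
#' Compares every treatment group with the shared control using the
#' classical Dunnett procedure: t statistics on the pooled ANOVA error, with
#' familywise adjustment through the joint multivariate-t distribution of
#' the comparison statistics (correlation \eqn{\rho_{ij} = \lambda_i
#' \lambda_j}, \eqn{\lambda_i = \sqrt{n_i/(n_i+n_0)}}), two-sided by
#' default. With a single treatment the adjusted p collapses to the ordinary
#' pooled-variance two-sample t-test p. Adjusted p-values are monotone in
#' |t| and never smaller than the unadjusted p.
#'
#' The multivariate-t probabilities are evaluated by
#' \code{\link[mvtnorm]{pmvt}} (deterministic given \code{mcSeed}).
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length.
#' @param control label of the control group.
#' @param alpha familywise significance level (default 0.05).
#' @param mcSeed seed for the multivariate-t quadrature.
#' @return data.frame, one row per treatment: comparison, estimate
#'   (treatment mean minus control mean), t, df, p_unadjusted, p_adjusted,
#'   significant.
#' @export
dunnettTest <- function(values, groups, control, alpha = 0.05,
                        mcSeed = 1L) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group '", control, "' not found")
  lev <- unique(groups)
  treatments <- setdiff(lev, control)
  if (!length(treatments)) stop("no treatment groups to compare")
  ni <- vapply(lev, function(g) sum(groups == g), numeric(1))
  if (any(ni < 2)) stop("need at least two values per group")
  mi <- vapply(lev, function(g) mean(values[groups == g]), numeric(1))
  n <- length(values)
  g <- length(lev)
  ssw <- sum((values - mi[match(groups, lev)])^2)
  df <- n - g
  msw <- ssw / df
  n0 <- ni[control]

  tstat <- vapply(treatments, function(tr)
    (mi[tr] - mi[control]) / sqrt(msw * (1 / ni[tr] + 1 / n0)), numeric(1))
  lambda <- sqrt(ni[treatments] / (ni[treatments] + n0))
  k <- length(treatments)
  corr <- outer(lambda, lambda)
  diag(corr) <- 1

  pAdj <- vapply(seq_len(k), function(i) {
    q <- abs(tstat[i])
    if (!is.finite(q)) return(0)
    pr <- if (k == 1L) {
      stats::pt(q, df) - stats::pt(-q, df)
    } else {
      withSeed(mcSeed, as.numeric(mvtnorm::pmvt(
        lower = rep(-q, k), upper = rep(q, k), df = as.integer(df),
        corr = corr, algorithm = mvtnorm::GenzBretz(abseps = 1e-4))))
    }
    min(1, max(0, 1 - pr))
  }, numeric(1))
  pUn <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  out <- data.frame(
    comparison = paste(treatments, "-", control),
    estimate = unname(mi[treatments] - mi[control]),
    t = unname(tstat), df = df,
    p_unadjusted = unname(pUn),
    p_adjusted = unname(pmax(pAdj, pUn)),
    significant = unname(pmax(pAdj, pUn) < alpha)
  )
  rownames(out) <- NULL
  out
}
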
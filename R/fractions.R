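#' Fragmented fraction per condition and replicate
#'
#' Summarizes a classified object table into the fraction of fragmented
#' mitochondria, by two methods: \emph{count} (number of fragmented objects
#' over all objects) and \emph{mass} (summed area of fragmented objects over
#' total object area). Fractions are computed per condition x replicate,
#' then averaged across replicates with a standard error.
#'
#' @param features object-feature data.frame containing \code{area_px} plus
#'   the grouping columns.
#' @param assignment data.frame from \code{\link{assignClasses}}, row-aligned
#'   with \code{features} and carrying a \code{class} column.
#' @param condition name of the condition column (default "condition").
#' @param replicate name of the replicate column (default "replicate").
#' @return list with \code{perReplicate} (condition, replicate, n_objects,
#'   fraction_by_count, fraction_by_mass) and \code{summary} (per condition:
#'   replicate count, mean and SE of both fractions).
#' @examples
#' f <- data.frame(area_px = c(10, 10, 10, 70),
#'                 condition = "c", replicate = 1)
#' a <- data.frame(class = c("fragmented", "fragmented", "fragmented",
#'                           "fused"))
#' fractionFragmented(f, a)$perReplicate
#' @export
fractionFragmented <- function(features, assignment,
                               condition = "condition",
                               replicate = "replicate") {
  if (nrow(features) != nrow(assignment))
    stop("features and assignment must be row-aligned")
  if (!"class" %in% names(assignment))
    stop("assignment must carry a 'class' column (see assignClasses)")
  df <- data.frame(
    condition = if (condition %in% names(features))
      features[[condition]] else "all",
    replicate = if (replicate %in% names(features))
      features[[replicate]] else 1L,
    area = features$area_px,
    fragmented = assignment$class == "fragmented"
  )
  if (nrow(df) == 0) stop("empty object table")

  per <- do.call(rbind, lapply(
    split(df, list(df$condition, df$replicate), drop = TRUE),
    function(g) data.frame(
      condition = g$condition[1], replicate = g$replicate[1],
      n_objects = nrow(g),
      fraction_by_count = mean(g$fragmented),
      fraction_by_mass = sum(g$area[g$fragmented]) / sum(g$area)
    )))
  per <- per[order(per$condition, per$replicate), , drop = FALSE]
  rownames(per) <- NULL

  summ <- do.call(rbind, lapply(split(per, per$condition), function(g)
    data.frame(
      condition = g$condition[1], n_replicates = nrow(g),
      n_objects = sum(g$n_objects),
      mean_fraction_by_count = mean(g$fraction_by_count),
      se_fraction_by_count = if (nrow(g) > 1) se(g$fraction_by_count) else NA_real_,
      mean_fraction_by_mass = mean(g$fraction_by_mass),
      se_fraction_by_mass = if (nrow(g) > 1) se(g$fraction_by_mass) else NA_real_
    )))
  rownames(summ) <- NULL
  list(perReplicate = per, summary = summ)
}
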
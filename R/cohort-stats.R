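#' Sex-stratified Z-score
#'
#' `(value - mean) / sd` against the same-sex reference population; used
#' whenever men and women appear on one axis, because male muscle carnosine
#' runs systematically higher.
#'
#' @param value concentration(s), mM.
#' @param ref a [ReferenceStats-class].
#' @return dimensionless Z-score(s).
#' @examples
#' zScore(6.37, ReferenceStats("male", 4.94, 1.43, 47))  # 1
#' @export
zScore <- function(value, ref) {
  stopifnot(is(ref, "ReferenceStats"))
  validObject(ref)
  (value - ref@mean) / ref@sd
}

#' Reference statistics from a cohort table
#'
#' Per-sex mean/SD/n of `carnosine_mean_mM` in the rows of the given group
#' (the untrained controls by default).
#'
#' @param cohort a cohort data.frame (see [simulateCohort()] or
#'   [readCohortTable()]).
#' @param group group used as reference population.
#' @return named list of [ReferenceStats-class], one per sex present.
#' @export
referenceStatsFromCohort <- function(cohort, group = "control") {
  sub <- cohort[cohort$group == group, , drop = FALSE]
  if (!nrow(sub)) stop("no rows in reference group '", group, "'")
  out <- lapply(split(sub, sub$sex), function(d) {
    if (nrow(d) < 2L) stop("reference group needs >= 2 subjects per sex")
    ReferenceStats(d$sex[1], mean(d$carnosine_mean_mM),
                   stats::sd(d$carnosine_mean_mM), nrow(d))
  })
  out[lengths(out) > 0]
}

#' Append sex-stratified Z-scores to a cohort table
#'
#' @param cohort a cohort data.frame.
#' @param refs named list of [ReferenceStats-class] per sex, e.g. from
#'   [referenceStatsFromCohort()].
#' @return the cohort with a `z_score` column.
#' @export
addZScores <- function(cohort, refs) {
  miss <- setdiff(unique(cohort$sex), names(refs))
  if (length(miss))
    stop("no reference statistics for sex: ", paste(miss, collapse = ", "))
  cohort$z_score <- vapply(seq_len(nrow(cohort)), function(i)
    zScore(cohort$carnosine_mean_mM[i], refs[[cohort$sex[i]]]), numeric(1))
  cohort
}

#' Two-sample t-test from summary statistics
#'
#' Textbook independent-sample t-test computed from per-group n, mean and
#' SD — the form needed to recompute published contrasts from printed
#' summaries. The pooled-variance variant (df = n1 + n2 - 2) is the default;
#' Welch's unequal-variance test with Satterthwaite df is available.
#' Two-sided p-values throughout.
#'
#' @param n1,mean1,sd1 first group summary (n1 >= 2, sd1 > 0).
#' @param n2,mean2,sd2 second group summary.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p_value`, `mean_difference` and `variant`.
#' @examples
#' # former sprint vs endurance athletes, printed summaries:
#' summaryTTest(7, 5.11, 1.07, 7, 3.61, 0.81)$p_value   # ~0.0119
#' @export
summaryTTest <- function(n1, mean1, sd1, n2, mean2, sd2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  for (n in c(n1, n2))
    if (is.na(n) || n < 2 || n != round(n)) stop("group sizes must be integers >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be > 0")
  d <- mean1 - mean2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- d / se
  list(t = tval, df = df, p_value = 2 * stats::pt(-abs(tval), df),
       mean_difference = d, variant = variant)
}

#' Stratified cohort summaries
#'
#' One row per stratum of the given keys: n, mean, SD (absent for single
#' subjects), median and quartiles by linear interpolation
#' (`quantile(type = 7)`), in deterministic (sorted) stratum order.
#'
#' @param cohort a cohort data.frame.
#' @param stratify character vector of column names to stratify by.
#' @param value column to summarize (default `carnosine_mean_mM`).
#' @return a data.frame of summaries.
#' @export
groupSummaries <- function(cohort, stratify = c("group", "category"),
                           value = "carnosine_mean_mM") {
  if (!nrow(cohort)) stop("empty cohort")
  bad <- setdiff(c(stratify, value), names(cohort))
  if (length(bad))
    stop("unknown column(s): ", paste(bad, collapse = ", "))
  keys <- cohort[stratify]
  ord <- do.call(order, keys)
  cohort <- cohort[ord, , drop = FALSE]
  keys <- cohort[stratify]
  splitId <- interaction(keys, drop = TRUE, lex.order = TRUE)
  parts <- split(cohort, splitId)
  out <- do.call(rbind, lapply(parts, function(d) {
    v <- d[[value]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    cbind(d[1, stratify, drop = FALSE],
          data.frame(n = length(v), mean = mean(v),
                     sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                     q1 = q[1], median = q[2], q3 = q[3]))
  }))
  rownames(out) <- NULL
  out
}

#' Percent difference of a group mean from a reference mean
#'
#' @param groupMean,referenceMean means in mM (`referenceMean > 0`).
#' @return signed percent difference,
#'   `100 * (groupMean - referenceMean) / referenceMean`.
#' @examples
#' percentDifference(6.58, 4.94)   # +33.2 %
#' percentDifference(3.75, 4.94)   # -24.1 %
#' @export
percentDifference <- function(groupMean, referenceMean) {
  if (any(is.na(referenceMean)) || any(referenceMean <= 0))
    stop("'referenceMean' must be > 0")
  100 * (groupMean - referenceMean) / referenceMean
}

#' Fold change between two group means
#'
#' @param meanA,meanB means in mM (`meanB > 0`).
#' @return `meanA / meanB`.
#' @export
foldChange <- function(meanA, meanB) {
  if (any(is.na(meanB)) || any(meanB <= 0)) stop("'meanB' must be > 0")
  meanA / meanB
}
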
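# The statistical battery: median-based effect size, rank tests, and
# group-summary tables.

#' Median-based Hedge's g with pooled SD
#'
#' Effect size defined as the difference between group medians divided by
#' the pooled standard deviation
#' `s* = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' This is deliberately the median-based variant used for skewed
#' morphometric data; the conventional mean-based g is available via
#' `conventional = TRUE` (supply means in place of medians).
#'
#' @param median1,median2 group medians (or means with
#'   `conventional = TRUE`).
#' @param sd1,sd2 group standard deviations (n-1 denominator), not both 0.
#' @param n1,n2 group sizes (>= 2).
#' @param conventional flag recording that means were supplied.
#' @return list: `g` (magnitude), `g_signed` (sign of median1 - median2),
#'   `pooled_sd`, `n1`, `n2`.
#' @export
hedges_g <- function(median1, sd1, n1, median2, sd2, n2,
                     conventional = FALSE) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    stop("both SDs are zero: effect size undefined", call. = FALSE)
  }
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  gs <- (median1 - median2) / s_pooled
  list(g = abs(gs), g_signed = gs, pooled_sd = s_pooled, n1 = n1, n2 = n2,
       basis = if (conventional) "mean" else "median")
}

#' Two-tailed Wilcoxon rank-sum test
#'
#' Exact two-tailed p-value when the combined sample size is at most 25 and
#' there are no ties; tie-corrected normal approximation with continuity
#' correction otherwise (the exact distribution is unavailable under ties).
#' The branch actually used is recorded in the result.
#'
#' @param x,y numeric samples (nonempty).
#' @return list: `statistic` (rank-sum W of `x`), `p`, `method`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Spearman rank correlation with t-test p-value
#'
#' Rank correlation using average ranks for ties; the two-tailed p-value
#' comes from `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom. For |rho| = 1 the p-value is reported as 0.
#'
#' @param x,y numeric vectors, length >= 5, neither constant.
#' @return named vector `c(rho, p)`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 5L) stop("need n >= 5 for the rank correlation", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  c(rho = rho, p = p)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic against a normal distribution with the sample's
#' own mean and SD, with the asymptotic p-value. Because the reference
#' parameters are estimated from the sample, the test is conservative as a
#' rejection device (a Lilliefors correction is not applied); it is used as
#' a screen before rank-based testing, where this bias is harmless.
#'
#' @param x numeric sample, n >= 5, nonzero variance.
#' @return list: `statistic`, `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5L) stop("need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance: normality screen undefined",
                              call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x)))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Group summaries and pairwise contrasts for a measurement table
#'
#' Builds the standard reporting table: for each metric and group, n,
#' median, SD (n-1), and range; and for each requested contrast, the
#' two-tailed Wilcoxon rank-sum p-value and the median-based Hedge's g.
#' Groups with fewer than 2 values get `sd = NA` (flagged, not dropped);
#' contrasts against an empty group are skipped with a reason.
#'
#' @param data data.frame with one row per analysis unit (ribbons count per
#'   ribbon, so double-ribbon synapses contribute one row per ribbon).
#' @param metrics character vector of metric column names.
#' @param group name of the grouping column (e.g., `"mp_group"`).
#' @param contrasts list of 2-vectors of group levels to compare; default:
#'   all pairs.
#' @return list with `summary` and `comparisons` data.frames.
#' @export
group_table <- function(data, metrics, group, contrasts = NULL) {
  if (!group %in% names(data)) stop("grouping column not found",
                                    call. = FALSE)
  levels <- sort(unique(stats::na.omit(data[[group]])))
  if (is.null(contrasts) && length(levels) >= 2L) {
    contrasts <- utils::combn(levels, 2L, simplify = FALSE)
  }
  summaries <- list()
  comparisons <- list()
  for (m in metrics) {
    for (g in levels) {
      v <- data[[m]][data[[group]] == g]
      v <- v[!is.na(v)]
      summaries[[length(summaries) + 1L]] <- data.frame(
        metric = m, group = g, n = length(v),
        median = if (length(v)) stats::median(v) else NA_real_,
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
    for (ct in contrasts) {
      v1 <- data[[m]][data[[group]] == ct[1]]
      v2 <- data[[m]][data[[group]] == ct[2]]
      v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
      if (length(v1) < 2L || length(v2) < 2L) {
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          metric = m, group1 = ct[1], group2 = ct[2],
          statistic = NA_real_, p = NA_real_, g = NA_real_,
          g_signed = NA_real_,
          note = "skipped: group with n < 2", stringsAsFactors = FALSE)
        next
      }
      wt <- wilcoxon_ranksum(v1, v2)
      both_const <- stats::sd(v1) == 0 && stats::sd(v2) == 0
      eg <- if (both_const) list(g = NA_real_, g_signed = NA_real_)
            else hedges_g(stats::median(v1), stats::sd(v1), length(v1),
                          stats::median(v2), stats::sd(v2), length(v2))
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        metric = m, group1 = ct[1], group2 = ct[2],
        statistic = wt$statistic, p = wt$p, g = eg$g,
        g_signed = eg$g_signed, note = wt$method,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summaries),
       comparisons = do.call(rbind, comparisons))
}
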
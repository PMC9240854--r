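#' Two-sample t test from summary statistics
#'
#' Pooled-variance two-sample t by default (Welch optional), computed from
#' group means, SDs and sizes — the form needed to check published demographic
#' comparisons where only summaries are available. The statistic is
#' `(mean1 - mean2) / se`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' t_from_summary(26.04, 7.66, 75, 30.92, 7.42, 108)
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (sd1 <= 0 || sd2 <= 0) stop("t_from_summary: sds must be > 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("t_from_summary: ns must be >= 2", call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' No continuity correction by default (optional), matching how published
#' group-by-category comparisons are typically reported.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param correct Apply Yates continuity correction?
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) {
    stop("chi_square_2x2: counts must be 2x2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("chi_square_2x2: counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi_square_2x2: zero marginal total", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Paired t test on before/after vectors
#'
#' Complete-case paired t on the differences. A zero-variance difference (all
#' subjects change identically) is degenerate: flagged, with `t` of 0 when the
#' mean difference is also 0 and `NA` otherwise.
#'
#' @param before,after Paired numeric vectors.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`, `degenerate`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) {
    stop("paired_t: unequal lengths", call. = FALSE)
  }
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  n <- length(d)
  if (n < 2) stop("paired_t: need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else NA_real_
    return(list(t = t, df = n - 1,
                p = if (!is.na(t) && t == 0) 1 else NA_real_,
                mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  res <- stats::t.test(after[ok], before[ok], paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_diff = mean(d), n = n, degenerate = FALSE)
}
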
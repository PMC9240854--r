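#' Fit a regression-based reliable change model for one group and measure
#'
#' Ordinary least squares of observed change (follow-up minus baseline) on the
#' baseline score, fitted within a single group. The model corrects individual
#' change for both practice effects (through the group mean change
#' \eqn{\bar{Y}}) and regression to the mean (through the slope *B* on
#' baseline). In centred form the prediction is
#'
#' \deqn{\hat{\Delta}(x) = \bar{Y} + B (x - \bar{X})}
#'
#' with \eqn{\bar{X}} the group baseline mean. The residual standard error of
#' this regression (`see`) scales the reliable-change limits.
#'
#' @param baseline,followup Paired score vectors for one group and measure
#'   (same subjects, same order); pairs with a missing value are dropped.
#' @param ci_level Two-sided confidence level for the RCI limits.
#' @param z_crit Standard-normal quantile used for the limits; default
#'   `qnorm(1 - (1 - ci_level) / 2)` (1.645 at the 0.90 level).
#' @return An `rci_model`: list with `mean_change`, `baseline_mean`, `slope`,
#'   `see`, `ci_level`, `z_crit`, `n`.
#' @export
#' @examples
#' m <- fit_rci_model(baseline = c(-1, 0, 1), followup = c(-0.6, 0.3, 1.2))
#' rci_limits(m, baseline = 1)
fit_rci_model <- function(baseline, followup, ci_level = 0.90, z_crit = NULL) {
  if (length(baseline) != length(followup)) {
    stop("fit_rci_model: baseline and followup must be the same length",
         call. = FALSE)
  }
  if (ci_level <= 0 || ci_level >= 1) {
    stop("fit_rci_model: ci_level must be in (0, 1)", call. = FALSE)
  }
  ok <- !is.na(baseline) & !is.na(followup)
  baseline <- baseline[ok]; followup <- followup[ok]
  n <- length(baseline)
  if (n < 3) {
    stop("fit_rci_model: need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(baseline) == 0) {
    stop("fit_rci_model: zero baseline variance", call. = FALSE)
  }
  change <- followup - baseline
  fit <- stats::lm(change ~ baseline)
  see <- stats::sigma(fit)
  # a perfectly linear change pattern leaves only float dust in the residuals;
  # snap it to the exactly-degenerate model
  if (see < 1e-10) see <- 0
  structure(list(
    mean_change = mean(change),
    baseline_mean = mean(baseline),
    slope = unname(stats::coef(fit)["baseline"]),
    see = see,
    ci_level = ci_level,
    z_crit = if (is.null(z_crit)) stats::qnorm(1 - (1 - ci_level) / 2)
             else z_crit,
    n = n
  ), class = "rci_model")
}

#' Reliable-change limits for given baseline scores
#'
#' Predicted change is `mean_change + slope * (baseline - baseline_mean)`;
#' lower/upper limits are the prediction minus/plus `z_crit * see`. A
#' degenerate model (`see == 0`) collapses the limits onto the prediction and
#' is flagged via the `degenerate` attribute.
#'
#' @param model An `rci_model`.
#' @param baseline Numeric vector of baseline scores.
#' @return Data frame with columns `baseline`, `predicted`, `lower`, `upper`.
#' @export
rci_limits <- function(model, baseline) {
  stopifnot(inherits(model, "rci_model"))
  predicted <- model$mean_change + model$slope * (baseline - model$baseline_mean)
  half <- model$z_crit * model$see
  out <- data.frame(baseline = baseline, predicted = predicted,
                    lower = predicted - half, upper = predicted + half)
  attr(out, "degenerate") <- model$see == 0
  out
}

#' Classify observed changes against reliable-change limits
#'
#' Strict inequalities: `decrease` iff observed < lower, `increase` iff
#' observed > upper, otherwise `stable`; an observation exactly on a limit is
#' stable (conservative). Missing observed changes classify as `NA`.
#'
#' @param observed Observed change scores.
#' @param limits Data frame from [rci_limits()] (or anything with `lower` and
#'   `upper` columns of matching length).
#' @return Character vector in `{decrease, stable, increase}` with `NA` for
#'   missing changes.
#' @export
classify_change <- function(observed, limits) {
  if (nrow(limits) != length(observed)) {
    stop("classify_change: observed and limits lengths differ", call. = FALSE)
  }
  out <- rep(NA_character_, length(observed))
  ok <- !is.na(observed)
  out[ok] <- "stable"
  out[ok & observed < limits$lower] <- "decrease"
  out[ok & observed > limits$upper] <- "increase"
  out
}

# wide baseline/follow-up pairs for one measure: one row per subject having a
# time-0 record; followup is the latest time > 0 record if any
paired_scores <- function(domain_scores, measure) {
  b <- domain_scores[domain_scores$time_years == 0, , drop = FALSE]
  f <- domain_scores[domain_scores$time_years > 0, , drop = FALSE]
  f <- f[order(f$subject_id, -f$time_years), , drop = FALSE]
  f <- f[!duplicated(f$subject_id), , drop = FALSE]
  i <- match(b$subject_id, f$subject_id)
  data.frame(
    subject_id = b$subject_id, group = b$group,
    baseline = b[[measure]], followup = f[[measure]][i],
    stringsAsFactors = FALSE
  )
}

#' Fit RCI models and classify every subject, per group and measure
#'
#' For each group crossed with each measure, fits [fit_rci_model()] on the
#' complete baseline/follow-up pairs and classifies each pair's observed change
#' against its individual limits. Each group gets its own model, so group
#' differences in practice effects are respected. Subjects missing either wave
#' are excluded and counted, never silently dropped.
#'
#' @param domain_scores Scored cohort (see [score_cohort()]).
#' @param measures Measure columns; default all domains plus the composite.
#' @inheritParams fit_rci_model
#' @return An `rci_classification`: data frame with `subject_id`, `group`,
#'   `measure`, `baseline`, `observed_change`, `predicted_change`, `lower`,
#'   `upper`, `category`; attributes `models` (named list of `rci_model`s,
#'   `group.measure`) and `n_excluded` (incomplete pairs per group × measure).
#' @export
classify_rci <- function(domain_scores,
                         measures = c(names(attr(domain_scores, "domains")),
                                      "composite"),
                         ci_level = 0.90, z_crit = NULL) {
  assert_cohort(domain_scores, "classify_rci")
  groups <- sort(unique(domain_scores$group))
  rows <- list(); models <- list(); excluded <- list()
  for (g in groups) {
    dg <- domain_scores[domain_scores$group == g, , drop = FALSE]
    for (m in measures) {
      p <- paired_scores(dg, m)
      complete <- !is.na(p$baseline) & !is.na(p$followup)
      excluded[[paste(g, m, sep = ".")]] <- sum(!complete)
      pc <- p[complete, , drop = FALSE]
      mod <- fit_rci_model(pc$baseline, pc$followup, ci_level = ci_level,
                           z_crit = z_crit)
      models[[paste(g, m, sep = ".")]] <- mod
      lim <- rci_limits(mod, pc$baseline)
      change <- pc$followup - pc$baseline
      rows[[paste(g, m, sep = ".")]] <- data.frame(
        subject_id = pc$subject_id, group = g, measure = m,
        baseline = pc$baseline, observed_change = change,
        predicted_change = lim$predicted, lower = lim$lower, upper = lim$upper,
        category = classify_change(change, lim),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, models = models, n_excluded = unlist(excluded),
            class = c("rci_classification", "data.frame"))
}

#' Summarise reliable-change classifications per group and measure
#'
#' One row per group × measure: the model's mean change and slope, the
#' percentage of complete cases classified as decrease and as increase, and
#' the stability percentage (100 minus the other two, computed before
#' rounding). Percentages are reported to one decimal.
#'
#' @param classifications An `rci_classification` from [classify_rci()].
#' @return Data frame with `group`, `measure`, `n`, `mean_change`, `slope`,
#'   `pct_decrease`, `pct_increase`, `pct_stable`.
#' @export
summarize_rci <- function(classifications) {
  stopifnot(inherits(classifications, "rci_classification"))
  models <- attr(classifications, "models")
  keys <- unique(classifications[, c("group", "measure")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    g <- keys$group[i]; m <- keys$measure[i]
    cl <- classifications$category[classifications$group == g &
                                     classifications$measure == m]
    cl <- cl[!is.na(cl)]
    n <- length(cl)
    dec <- 100 * sum(cl == "decrease") / n
    inc <- 100 * sum(cl == "increase") / n
    mod <- models[[paste(g, m, sep = ".")]]
    data.frame(group = g, measure = m, n = n,
               mean_change = mod$mean_change, slope = mod$slope,
               pct_decrease = round(dec, 1), pct_increase = round(inc, 1),
               pct_stable = round(100 - dec - inc, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
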
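#' Fit the random-intercept linear growth model for one measure
#'
#' Fits, by maximum likelihood, the two-group growth model
#'
#' \deqn{Y_{ij} = \beta_1 + b_{1j} + \beta_2 t + \beta_3 g + \beta_4 a +
#'   \beta_5 t g + \beta_6 t a + e_{ij}}
#'
#' where *t* is years since baseline, *g* codes group (0 = control,
#' 1 = patient), *a* is baseline age mean-centred on the analysis sample, and
#' \eqn{b_{1j}} is a subject-level random intercept with a single variance
#' component (scaled-identity covariance). With `include_group_terms = FALSE`
#' the group main effect and time-by-group interaction are dropped — the
#' per-group growth-curve model.
#'
#' Inference on the fixed effects uses Wald t statistics. Degrees of freedom
#' are the residual df (`n_obs` minus the number of fixed effects) by default;
#' `df_method = "satterthwaite"` uses lmerTest's Satterthwaite approximation
#' when that package is available.
#'
#' @param domain_scores Output of [compute_domain_scores()] /
#'   [score_cohort()].
#' @param response Column to model: a domain name or `"composite"`.
#' @param include_group_terms Keep the group main effect and time-by-group
#'   interaction?
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return A `growth_fit`: list with `coefficients` (term, estimate, se, t, df,
#'   p), `random_intercept_var`, `residual_var`, `vcov`, `n_subjects`, `n_obs`,
#'   `converged`, `singular`, `age_center` (the sample mean age used for
#'   centring), `time_range`, `response`, `include_group_terms`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patient = 40, n_control = 40, seed = 2))
#' scores <- score_cohort(cohort)
#' fit <- fit_growth_model(scores, "composite")
#' fit$coefficients
fit_growth_model <- function(domain_scores, response,
                             include_group_terms = TRUE,
                             df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  assert_cohort(domain_scores, "fit_growth_model")
  if (!response %in% names(domain_scores)) {
    stop(sprintf("fit_growth_model: response '%s' not found", response),
         call. = FALSE)
  }
  d <- domain_scores[!is.na(domain_scores[[response]]), , drop = FALSE]
  if (include_group_terms && length(unique(d$group)) < 2) {
    stop("fit_growth_model: group terms requested but only one group present",
         call. = FALSE)
  }
  dat <- data.frame(
    y = d[[response]],
    time = d$time_years,
    group01 = as.integer(d$group == "patient"),
    subject_id = d$subject_id
  )
  age_center <- mean(d$baseline_age)
  dat$age_c <- d$baseline_age - age_center

  form <- if (include_group_terms) {
    y ~ time + group01 + age_c + time:group01 + time:age_c + (1 | subject_id)
  } else {
    y ~ time + age_c + time:age_c + (1 | subject_id)
  }

  warned <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = FALSE,
               # permit degenerate designs (e.g. one observation per subject,
               # where the intercept variance is unidentified but the ML fixed
               # effects are still the OLS solution)
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore")),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  tval <- beta / se
  n_obs <- nrow(dat)
  if (df_method == "satterthwaite" &&
      requireNamespace("lmerTest", quietly = TRUE)) {
    lt <- lmerTest::as_lmerModLmerTest(fit)
    cs <- stats::coef(summary(lt))
    dfree <- cs[, "df"]
  } else {
    dfree <- rep(n_obs - length(beta), length(beta))
  }
  pval <- 2 * stats::pt(-abs(tval), df = dfree)

  vc <- lme4::VarCorr(fit)
  conv_fail <- any(grepl("failed to converge|unable to evaluate", warned))

  structure(list(
    coefficients = data.frame(
      term = names(beta), estimate = unname(beta), se = unname(se),
      t = unname(tval), df = unname(dfree), p = unname(pval),
      stringsAsFactors = FALSE),
    random_intercept_var = as.numeric(vc$subject_id[1, 1]),
    residual_var = stats::sigma(fit)^2,
    vcov = V,
    n_subjects = length(unique(dat$subject_id)),
    n_obs = n_obs,
    converged = !conv_fail,
    singular = lme4::isSingular(fit),
    age_center = age_center,
    time_range = range(dat$time),
    response = response,
    include_group_terms = include_group_terms
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth model for '%s' (%s group terms)\n", x$response,
              if (x$include_group_terms) "with" else "without"))
  cat(sprintf("  %d observations from %d subjects; ML fit%s\n", x$n_obs,
              x$n_subjects,
              if (!x$converged) " [convergence flagged]" else ""))
  cat(sprintf("  random intercept var %.4f, residual var %.4f\n",
              x$random_intercept_var, x$residual_var))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-group growth curves
#'
#' Fits the growth-curve model (no group terms) separately within each group.
#'
#' @inheritParams fit_growth_model
#' @return Named list of `growth_fit`s, one per group present.
#' @export
fit_group_growth_curves <- function(domain_scores, response,
                                    df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  groups <- sort(unique(domain_scores$group))
  fits <- lapply(groups, function(g) {
    fit_growth_model(domain_scores[domain_scores$group == g, , drop = FALSE],
                     response, include_group_terms = FALSE,
                     df_method = df_method)
  })
  stats::setNames(fits, groups)
}

#' Estimated marginal mean from a growth fit
#'
#' Linear combination of the fixed effects at the requested group, time and
#' baseline age. With `age = NULL` the sample mean age is used (the centred age
#' term is zero), so for the reference group at time 0 the EMM equals the
#' intercept.
#'
#' @param fit A `growth_fit`.
#' @param group `"patient"` or `"control"` (ignored for group-free fits).
#' @param time Years since baseline; values outside the observed range warn.
#' @param age Baseline age in years, or `NULL` for the sample mean.
#' @return List with `estimate` and `se`.
#' @export
estimated_marginal_means <- function(fit, group = "control", time = 0,
                                     age = NULL) {
  if (!fit$converged) {
    warning("estimated_marginal_means: fit had convergence problems")
  }
  if (time < fit$time_range[1] || time > fit$time_range[2]) {
    warning(sprintf(
      "estimated_marginal_means: time %g outside the observed range [%g, %g]",
      time, fit$time_range[1], fit$time_range[2]))
  }
  age_c <- if (is.null(age)) 0 else age - fit$age_center
  g01 <- as.integer(group == "patient")
  terms <- fit$coefficients$term
  x <- stats::setNames(numeric(length(terms)), terms)
  x["(Intercept)"] <- 1
  x["time"] <- time
  x["age_c"] <- age_c
  x["time:age_c"] <- time * age_c
  if (fit$include_group_terms) {
    x["group01"] <- g01
    x["time:group01"] <- time * g01
  }
  est <- sum(x * fit$coefficients$estimate)
  se <- sqrt(drop(t(x) %*% fit$vcov %*% x))
  list(estimate = est, se = se)
}

#' Tidy fixed-effect table across measures
#'
#' Fits the group model for each requested measure and stacks the fixed-effect
#' estimates into one exportable table.
#'
#' @param domain_scores Scored cohort.
#' @param measures Response columns; default all domains plus the composite.
#' @inheritParams fit_growth_model
#' @return Data frame with columns `measure`, `term`, `estimate`, `se`, `t`,
#'   `df`, `p`, `converged`.
#' @export
growth_table <- function(domain_scores,
                         measures = c(names(attr(domain_scores, "domains")),
                                      "composite"),
                         df_method = c("residual", "satterthwaite")) {
  df_method <- match.arg(df_method)
  do.call(rbind, lapply(measures, function(m) {
    f <- fit_growth_model(domain_scores, m, df_method = df_method)
    cbind(measure = m, f$coefficients, converged = f$converged)
  }))
}
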
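# deterministic scored data with known fixed effects on a tiny battery:
# y = b1 + b2*time + b3*group + b4*age_c + b5*time*group (+ optional noise)
make_known_scores <- function(n_per_group = 20, b1 = 0.2, b2 = 0.03,
                              b3 = -1.0, b4 = -0.01, b5 = -0.04,
                              sd_resid = 0, sd_int = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  ids <- sprintf("S%03d", seq_len(n))
  grp <- rep(c("control", "patient"), each = n_per_group)
  age <- rnorm(n, 28, 7)
  u <- rnorm(n, 0, sd_int)
  d <- data.frame(
    subject_id = rep(ids, each = 2), group = rep(grp, each = 2),
    baseline_age = rep(age, each = 2), sex = "F",
    time_years = rep(c(0, 10), n), stringsAsFactors = FALSE
  )
  age_c <- d$baseline_age - mean(age)
  g01 <- as.integer(d$group == "patient")
  d$y <- b1 + b2 * d$time_years + b3 * g01 + b4 * age_c +
    b5 * d$time_years * g01 + rep(u, each = 2) +
    rnorm(nrow(d), 0, sd_resid)
  d
}

test_that("noise-free data recover the generating fixed effects exactly", {
  d <- make_known_scores()
  fit <- fit_growth_model(d, "y")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], 0.2, tolerance = 1e-6)
  expect_equal(est[["time"]], 0.03, tolerance = 1e-6)
  expect_equal(est[["group01"]], -1.0, tolerance = 1e-6)
  expect_equal(est[["age_c"]], -0.01, tolerance = 1e-6)
  expect_equal(est[["time:group01"]], -0.04, tolerance = 1e-6)
  expect_equal(est[["time:age_c"]], 0, tolerance = 1e-6)
})

test_that("fixed effects are recovered within 3 SE on a noisy cohort", {
  # config-scale norms make the z scale coincide with the generating scale,
  # so generator parameters are the true fixed effects
  bat <- default_battery()
  cfg <- sim_config(n_patient = 200, n_control = 200, battery = bat,
                    residual_sd = 0.5, random_intercept_sd = 0.8,
                    impaired_fraction = 0, seed = 77)
  cohort <- generate_cohort(cfg)
  scores <- score_cohort(cohort, norms = norms_from_config(cfg))
  fit <- fit_growth_model(scores, "attention")
  co <- fit$coefficients
  est <- setNames(co$estimate, co$term); se <- setNames(co$se, co$term)
  truth <- c(
    "time" = bat$practice_control[5],
    "group01" = -bat$group_deficit[5],
    "age_c" = bat$age_slope[5],
    "time:group01" = bat$practice_patient[5] - bat$practice_control[5],
    "time:age_c" = 0,
    "(Intercept)" = bat$age_slope[5] *
      (mean(scores$baseline_age[scores$time_years == 0]) - cfg$age_center)
  )
  for (term in names(truth)) {
    expect_lt(abs(est[[term]] - truth[[term]]), 3 * se[[term]])
  }
  expect_true(fit$converged)
  expect_gte(fit$random_intercept_var, 0)
})

test_that("estimates are invariant to row order; shifts move only the intercept", {
  d <- make_known_scores(sd_resid = 0.4, sd_int = 0.6, seed = 2)
  f1 <- fit_growth_model(d, "y")
  f2 <- fit_growth_model(d[sample(nrow(d)), ], "y")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  shifted <- d; shifted$y <- shifted$y + 3
  f3 <- fit_growth_model(shifted, "y")
  expect_equal(f3$coefficients$estimate[f3$coefficients$term == "(Intercept)"],
               f1$coefficients$estimate[f1$coefficients$term == "(Intercept)"] + 3,
               tolerance = 1e-5)
  expect_equal(f3$coefficients$estimate[-1], f1$coefficients$estimate[-1],
               tolerance = 1e-5)
})

test_that("Wald t equals estimate/se and one-group data with group terms errors", {
  d <- make_known_scores(sd_resid = 0.4, seed = 3)
  fit <- fit_growth_model(d, "y")
  expect_equal(fit$coefficients$t,
               fit$coefficients$estimate / fit$coefficients$se)
  ctrl <- d[d$group == "control", ]
  expect_error(fit_growth_model(ctrl, "y", include_group_terms = TRUE),
               "one group")
  expect_s3_class(fit_growth_model(ctrl, "y", include_group_terms = FALSE),
                  "growth_fit")
})

test_that("with one observation per subject ML fixed effects match OLS", {
  d <- make_known_scores(sd_resid = 0.5, seed = 4)
  single <- d[d$time_years == 0, ]
  fit <- fit_growth_model(single, "y")
  ols <- lm(y ~ group01 + age_c,
            data = data.frame(y = single$y,
                              group01 = as.integer(single$group == "patient"),
                              age_c = single$baseline_age -
                                mean(single$baseline_age)))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], unname(coef(ols)[1]), tolerance = 1e-5)
  expect_equal(est[["group01"]], unname(coef(ols)["group01"]), tolerance = 1e-5)
  expect_equal(est[["age_c"]], unname(coef(ols)["age_c"]), tolerance = 1e-5)
})

test_that("per-group growth curves are separated and equal under equal slopes", {
  d <- make_known_scores(b3 = -1, b5 = 0)  # equal time slopes, no noise
  fits <- fit_group_growth_curves(d, "y")
  slope <- function(f) f$coefficients$estimate[f$coefficients$term == "time"]
  expect_equal(slope(fits$control), slope(fits$patient), tolerance = 1e-6)

  # each group's fit ignores the other group's rows entirely
  ctrl_only <- fit_growth_model(d[d$group == "control", ], "y",
                                include_group_terms = FALSE)
  expect_equal(ctrl_only$coefficients$estimate,
               fits$control$coefficients$estimate, tolerance = 1e-8)
})

test_that("control-only growth curve detects a generated practice effect", {
  cfg <- sim_config(n_patient = 2, n_control = 400, impaired_fraction = 0,
                    seed = 55)
  cohort <- generate_cohort(cfg)
  scores <- score_cohort(cohort)
  ctrl <- scores[scores$group == "control", ]
  fit <- fit_growth_model(ctrl, "composite", include_group_terms = FALSE)
  co <- fit$coefficients
  t_time <- co$t[co$term == "time"]
  expect_gt(co$estimate[co$term == "time"], 0)
  expect_gt(t_time, 2)   # positive and significant at n = 400
})

test_that("EMMs reproduce intercept, group gap and slope identities", {
  d <- make_known_scores(sd_resid = 0.3, sd_int = 0.5, seed = 6)
  fit <- fit_growth_model(d, "y")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  emm_c0 <- estimated_marginal_means(fit, "control", time = 0)
  expect_equal(emm_c0$estimate, est[["(Intercept)"]], tolerance = 1e-10)
  emm_p0 <- estimated_marginal_means(fit, "patient", time = 0)
  expect_equal(emm_p0$estimate - emm_c0$estimate, est[["group01"]],
               tolerance = 1e-10)
  # 10-year patient change at mean age = 10*(b2 + b5)
  emm_p10 <- estimated_marginal_means(fit, "patient", time = 10)
  expect_equal(emm_p10$estimate - emm_p0$estimate,
               10 * (est[["time"]] + est[["time:group01"]]), tolerance = 1e-10)
  expect_warning(estimated_marginal_means(fit, "control", time = 25),
                 "outside the observed range")
})
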
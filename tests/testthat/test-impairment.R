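test_that("domain flags use a strict cut-off and propagate missingness", {
  cfg <- classifier_config()
  expect_identical(flag_impairment(c(-1.5, -1.51, 0, NA), cfg),
                   c(FALSE, TRUE, FALSE, NA))
  expect_error(classifier_config(cutoff = 0.5), "negative")
  expect_error(classifier_config(min_domains = 9), "min_domains")
})

# build a one-row scored frame from a named domain z-vector
profile_row <- function(z, time = 0, id = "S1") {
  out <- data.frame(subject_id = id, group = "patient", baseline_age = 25,
                    sex = "M", time_years = time, stringsAsFactors = FALSE)
  for (d in names(z)) out[[d]] <- z[[d]]
  out
}

domz <- function(...) {
  z <- setNames(rep(0, 8), names(default_domains()))
  over <- list(...)
  z[names(over)] <- unlist(over)
  z
}

test_that("clinical impairment requires at least min_domains impaired domains", {
  cc <- classifier_config()
  two <- classify_impairment(
    profile_row(domz(learning = -1.6, memory = -1.7)), cc)
  expect_equal(two$n_impaired, 2)
  expect_true(two$clinically_impaired)

  one_severe <- classify_impairment(profile_row(domz(attention = -3.0)), cc)
  expect_equal(one_severe$n_impaired, 1)
  expect_false(one_severe$clinically_impaired)

  all8 <- classify_impairment(
    profile_row(setNames(rep(-1.6, 8), names(default_domains()))), cc)
  expect_equal(all8$n_impaired, 8)
  expect_true(all8$clinically_impaired)

  # too few observed domains for a verdict -> missing status, counted
  sparse <- profile_row(domz())
  for (d in names(default_domains())[-1]) sparse[[d]] <- NA_real_
  res <- classify_impairment(sparse, cc)
  expect_true(is.na(res$clinically_impaired))
  expect_equal(res$n_domains_missing, 7)
})

test_that("prevalence reports percentage and denominator per group and wave", {
  rows <- do.call(rbind, lapply(1:16, function(i) {
    z <- if (i <= 11) domz(learning = -2, memory = -2) else domz()
    profile_row(z, id = sprintf("S%02d", i))
  }))
  prev <- impairment_prevalence(classify_impairment(rows))
  expect_equal(prev$n, 16)
  expect_equal(prev$n_impaired, 11)
  expect_equal(round(prev$pct, 1), 68.8)  # 11/16
  expect_error(impairment_prevalence(classify_impairment(rows)[0, ]), "empty")
})

test_that("prevalence tracks an injected impaired subgroup at large n", {
  cfg <- sim_config(n_patient = 600, n_control = 600, impaired_fraction = 0.5,
                    impaired_extra_deficit = 2.0, seed = 17)
  cohort <- generate_cohort(cfg)
  truth <- attr(cohort, "truth")
  scores <- score_cohort(cohort)
  prof <- classify_impairment(scores)
  base <- prof[prof$time_years == 0 & prof$group == "patient", ]
  # subjects generated with the extra 2 SD deficit are essentially all flagged
  inj <- base$subject_id %in% truth$subject_id[truth$impaired_subgroup]
  expect_gt(mean(base$clinically_impaired[inj]), 0.95)
  # overall prevalence decomposes exactly into injected and base-rate strata
  prev <- impairment_prevalence(base)
  expect_gt(prev$pct, 100 * 0.95 * mean(inj))
  inj_rate <- mean(base$clinically_impaired[inj])
  base_rate <- mean(base$clinically_impaired[!inj])
  expected <- 100 * (mean(inj) * inj_rate + (1 - mean(inj)) * base_rate)
  expect_lt(abs(prev$pct - expected), 1e-9)
  # and the base rate itself is a minority phenomenon
  expect_lt(base_rate, inj_rate)
})

test_that("domain-level transitions reconcile with subject-level strata", {
  cc <- classifier_config()
  rows <- rbind(
    # impaired on {learning, memory} -> only learning: improved on one domain,
    # no longer clinically impaired (1 < 2)
    profile_row(domz(learning = -2, memory = -2), 0, "A"),
    profile_row(domz(learning = -2), 10, "A"),
    # unimpaired -> impaired on 2 domains: declined + became impaired
    profile_row(domz(), 0, "B"),
    profile_row(domz(attention = -2, memory = -2), 10, "B"),
    # stable unimpaired
    profile_row(domz(), 0, "C"),
    profile_row(domz(), 10, "C"),
    # impaired, gains an additional domain, all 8 at follow-up
    profile_row(domz(learning = -2, memory = -2, attention = -2), 0, "D"),
    profile_row(setNames(rep(-2, 8), names(default_domains())), 10, "D")
  )
  tr <- transition_analysis(classify_impairment(rows, cc))
  expect_equal(tr$impaired$n, 2)
  expect_equal(tr$impaired$pct_improved_any_domain, 50)   # A only
  expect_equal(tr$impaired$pct_no_longer_impaired, 50)    # A only
  expect_equal(tr$impaired$pct_additional_domains, 50)    # D only
  expect_equal(tr$impaired$pct_all_domains_at_follow_up, 50)
  expect_equal(tr$unimpaired$n, 2)
  expect_equal(tr$unimpaired$pct_improved, 0)
  expect_equal(tr$unimpaired$pct_declined, 50)            # B only
  expect_equal(tr$unimpaired$pct_became_impaired, 50)
  expect_equal(tr$n_excluded, 0)

  # identical flags at both waves -> all transition percentages zero
  stable <- rbind(profile_row(domz(learning = -2, memory = -2), 0, "E"),
                  profile_row(domz(learning = -2, memory = -2), 10, "E"))
  tr0 <- transition_analysis(classify_impairment(stable, cc))
  expect_equal(tr0$impaired$pct_improved_any_domain, 0)
  expect_equal(tr0$impaired$pct_additional_domains, 0)
  expect_equal(tr0$impaired$pct_no_longer_impaired, 0)
})

test_that("subjects missing a wave are excluded and counted", {
  cc <- classifier_config()
  rows <- rbind(
    profile_row(domz(learning = -2, memory = -2), 0, "A"),
    profile_row(domz(), 10, "A"),
    profile_row(domz(), 0, "B")  # no follow-up
  )
  tr <- transition_analysis(classify_impairment(rows, cc))
  expect_equal(tr$n_excluded, 1)
  expect_equal(tr$impaired$n, 1)
})

test_that("classifier is monotone in cutoff and min_domains", {
  scores <- score_cohort(small_cohort(seed = 19))
  n_imp <- function(cutoff) {
    classify_impairment(scores, classifier_config(cutoff = cutoff))$n_impaired
  }
  for (cuts in list(c(-1.0, -1.5), c(-1.5, -2.0), c(-0.5, -3.0))) {
    expect_true(all(n_imp(cuts[2]) <= n_imp(cuts[1])))
  }
  prev_at <- function(md) {
    p <- classify_impairment(scores, classifier_config(min_domains = md))
    impairment_prevalence(p)$pct
  }
  expect_true(all(prev_at(1) >= prev_at(2)))
  expect_true(all(prev_at(2) >= prev_at(4)))
})
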
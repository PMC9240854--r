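#' Simulation configuration for a two-group, two-wave cohort
#'
#' Bundles every generative parameter for [generate_cohort()]. Defaults emulate
#' a first-episode schizophrenia follow-up design: 75 patients and 108
#' controls, patients younger (mean 26.0 vs 30.9 years), a roughly 1 SD global
#' cognitive deficit, a 10-year retest interval with modest practice gains, and
#' an impaired patient subgroup carrying an extra global deficit.
#'
#' Scores are generated on the control-baseline z scale and mapped to raw
#' units via each subtest's `control_mean`/`control_sd` and direction, so a
#' positive deficit always means worse performance regardless of whether the
#' subtest is scored higher-better or lower-better (timed).
#'
#' @param n_patient,n_control Subjects per group (each at least 2).
#' @param age_mean_patient,age_sd_patient,age_mean_control,age_sd_control
#'   Baseline-age distributions, years.
#' @param prop_male_patient,prop_male_control Proportion of males per group.
#' @param battery Subtest definition table, see [default_battery()]. Must have
#'   columns `subtest`, `direction`, `control_mean`, `control_sd`,
#'   `group_deficit`, `practice_control`, `practice_patient`, `age_slope`.
#' @param follow_up_years Retest interval, years.
#' @param random_intercept_sd SD of the shared subject-level ability intercept
#'   (z units). Together with `residual_sd` this sets the within-subject
#'   correlation across waves.
#' @param residual_sd Per-subtest, per-wave residual SD (z units).
#' @param impaired_fraction Proportion of patients drawn with an extra global
#'   deficit.
#' @param impaired_extra_deficit Size of that extra deficit (z units).
#' @param attrition_rate Named numeric, wave-2 dropout proportion per group,
#'   e.g. `c(patient = 0.2, control = 0.1)`.
#' @param attrition_mechanism `"random"` or `"worst_baseline"` (drops the
#'   lowest baseline-composite subjects first).
#' @param mcar_rate Per-cell missing-completely-at-random rate for subtest
#'   scores (0 = off).
#' @param age_center Age (years) at which the generative age effect is zero;
#'   default is the group-size-weighted mean of the two age means.
#' @param seed Integer RNG seed; may also be supplied at generation time.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patient = 10, n_control = 10, seed = 1)
#' cohort <- generate_cohort(cfg)
sim_config <- function(n_patient = 75,
                       n_control = 108,
                       age_mean_patient = 26.04, age_sd_patient = 7.66,
                       age_mean_control = 30.92, age_sd_control = 7.42,
                       prop_male_patient = 0.526, prop_male_control = 0.575,
                       battery = default_battery(),
                       follow_up_years = 10,
                       random_intercept_sd = 0.8,
                       residual_sd = 0.5,
                       impaired_fraction = 0.3,
                       impaired_extra_deficit = 1.0,
                       attrition_rate = c(patient = 0, control = 0),
                       attrition_mechanism = "random",
                       mcar_rate = 0,
                       age_center = NULL,
                       seed = NULL) {
  if (is.null(age_center)) {
    age_center <- (n_patient * age_mean_patient + n_control * age_mean_control) /
      (n_patient + n_control)
  }
  cfg <- structure(list(
    n_patient = n_patient, n_control = n_control,
    age_mean_patient = age_mean_patient, age_sd_patient = age_sd_patient,
    age_mean_control = age_mean_control, age_sd_control = age_sd_control,
    prop_male_patient = prop_male_patient,
    prop_male_control = prop_male_control,
    battery = battery,
    follow_up_years = follow_up_years,
    random_intercept_sd = random_intercept_sd,
    residual_sd = residual_sd,
    impaired_fraction = impaired_fraction,
    impaired_extra_deficit = impaired_extra_deficit,
    attrition_rate = attrition_rate,
    attrition_mechanism = attrition_mechanism,
    mcar_rate = mcar_rate,
    age_center = age_center,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("sim_config: invalid '%s' (%s)", field, msg),
                  call. = FALSE)
  }
  chk(is.numeric(cfg$n_patient) && cfg$n_patient >= 2, "n_patient", ">= 2 required")
  chk(is.numeric(cfg$n_control) && cfg$n_control >= 2, "n_control", ">= 2 required")
  chk(cfg$age_sd_patient >= 0, "age_sd_patient", "must be >= 0")
  chk(cfg$age_sd_control >= 0, "age_sd_control", "must be >= 0")
  for (f in c("prop_male_patient", "prop_male_control", "impaired_fraction",
              "mcar_rate")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
  }
  chk(all(cfg$attrition_rate >= 0 & cfg$attrition_rate <= 1),
      "attrition_rate", "rates must be in [0, 1]")
  chk(cfg$attrition_mechanism %in% c("random", "worst_baseline"),
      "attrition_mechanism", "must be 'random' or 'worst_baseline'")
  for (f in c("follow_up_years", "random_intercept_sd", "residual_sd",
              "impaired_extra_deficit")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] >= 0, f, "must be >= 0")
  }
  need <- c("subtest", "direction", "control_mean", "control_sd",
            "group_deficit", "practice_control", "practice_patient",
            "age_slope")
  miss <- setdiff(need, names(cfg$battery))
  chk(!length(miss), "battery",
      paste("missing column(s):", paste(miss, collapse = ", ")))
  chk(!anyDuplicated(cfg$battery$subtest), "battery", "duplicate subtest names")
  chk(all(cfg$battery$direction %in% c("higher_better", "lower_better")),
      "battery", "direction must be higher_better/lower_better")
  chk(all(cfg$battery$control_sd > 0), "battery", "control_sd must be > 0")
  invisible(cfg)
}

#' Generate a seeded synthetic two-wave cohort
#'
#' Draws `n_patient + n_control` subjects, each assessed at baseline (time 0)
#' and follow-up (`follow_up_years`). For subtest *k* of subject *s* in group
#' *g* at time *t* the latent ability on the control-baseline z scale is
#'
#' \deqn{z = -\delta_k 1[g=\mathrm{pat}] - \gamma 1[\mathrm{impaired}] + u_s +
#'   \alpha_k (a_s - a_0) + \pi_{kg} t + \varepsilon}
#'
#' with deficit \eqn{\delta_k}, impaired-subgroup shift \eqn{\gamma}, shared
#' subject intercept \eqn{u_s}, baseline-age slope \eqn{\alpha_k} around centre
#' \eqn{a_0}, per-group practice slope \eqn{\pi_{kg}} (SD units/year) and
#' residual \eqn{\varepsilon}. The raw score is `control_mean + s_k * z *
#' control_sd` where `s_k` is +1 for higher-better and -1 for lower-better
#' subtests, so a deficit worsens performance in both cases.
#'
#' The returned data frame carries a `truth` attribute (one row per subject:
#' random intercept and impaired-subgroup flag) for use as a simulation oracle.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; overrides `config$seed`. The same (config, seed)
#'   pair always yields a bit-identical cohort.
#' @return Long-format data frame with columns `subject_id`, `group`,
#'   `baseline_age`, `sex`, `time_years`, then one raw-score column per
#'   subtest.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  bat <- config$battery
  n_p <- config$n_patient
  n_c <- config$n_control
  n <- n_p + n_c

  subj <- data.frame(
    subject_id = c(sprintf("P%03d", seq_len(n_p)), sprintf("C%03d", seq_len(n_c))),
    group = rep(c("patient", "control"), c(n_p, n_c)),
    stringsAsFactors = FALSE
  )
  subj$baseline_age <- c(
    stats::rnorm(n_p, config$age_mean_patient, config$age_sd_patient),
    stats::rnorm(n_c, config$age_mean_control, config$age_sd_control)
  )
  subj$sex <- ifelse(
    stats::runif(n) < ifelse(subj$group == "patient",
                             config$prop_male_patient,
                             config$prop_male_control),
    "M", "F")
  subj$impaired_subgroup <- subj$group == "patient" &
    stats::runif(n) < config$impaired_fraction
  subj$random_intercept <- stats::rnorm(n, 0, config$random_intercept_sd)

  waves <- c(0, config$follow_up_years)
  rows <- subj[rep(seq_len(n), each = length(waves)),
               c("subject_id", "group", "baseline_age", "sex")]
  rows$time_years <- rep(waves, times = n)
  rownames(rows) <- NULL

  is_pat <- rows$group == "patient"
  u <- rep(subj$random_intercept, each = length(waves))
  imp <- rep(subj$impaired_subgroup, each = length(waves))
  age_dev <- rows$baseline_age - config$age_center

  for (k in seq_len(nrow(bat))) {
    practice <- ifelse(is_pat, bat$practice_patient[k], bat$practice_control[k])
    z <- -bat$group_deficit[k] * is_pat -
      config$impaired_extra_deficit * imp +
      u +
      bat$age_slope[k] * age_dev +
      practice * rows$time_years +
      stats::rnorm(nrow(rows), 0, config$residual_sd)
    rows[[bat$subtest[k]]] <-
      bat$control_mean[k] + direction_sign(bat$direction[k]) * z * bat$control_sd[k]
  }

  if (config$mcar_rate > 0) {
    for (k in bat$subtest) {
      drop <- stats::runif(nrow(rows)) < config$mcar_rate
      rows[[k]][drop] <- NA_real_
    }
  }

  if (any(config$attrition_rate > 0)) {
    rows <- apply_attrition(rows, config$attrition_rate,
                            mechanism = config$attrition_mechanism,
                            seed = NULL)
  }

  attr(rows, "truth") <- subj[, c("subject_id", "group", "impaired_subgroup",
                                  "random_intercept")]
  rows
}

#' Remove follow-up records to emulate study attrition
#'
#' Drops wave-2 (time > 0) records for a proportion of each group's subjects.
#' Baseline records are never removed. The `worst_baseline` mechanism removes
#' the subjects with the lowest baseline composite first, supporting
#' attrition-bias experiments where completers are systematically healthier.
#'
#' @param records Cohort data frame as produced by [generate_cohort()].
#' @param rate_by_group Named proportions, e.g. `c(patient = 0.3, control = 0.1)`.
#' @param mechanism `"random"` or `"worst_baseline"`.
#' @param seed Optional integer seed (used by the random mechanism).
#' @return The records with the selected subjects' follow-up rows removed.
#' @export
apply_attrition <- function(records, rate_by_group,
                            mechanism = c("random", "worst_baseline"),
                            seed = NULL) {
  assert_cohort(records, "apply_attrition")
  mechanism <- match.arg(mechanism)
  if (any(rate_by_group < 0 | rate_by_group > 1)) {
    stop("apply_attrition: rates must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  base <- records[records$time_years == 0, , drop = FALSE]
  drop_ids <- character(0)
  for (g in intersect(names(rate_by_group), c("patient", "control"))) {
    rate <- rate_by_group[[g]]
    ids <- base$subject_id[base$group == g]
    n_drop <- round(rate * length(ids))
    if (n_drop == 0) next
    if (mechanism == "random") {
      drop_ids <- c(drop_ids, sample(ids, n_drop))
    } else {
      comp <- baseline_composite_for_attrition(records, g)
      drop_ids <- c(drop_ids, names(sort(comp))[seq_len(n_drop)])
    }
  }
  keep <- !(records$subject_id %in% drop_ids & records$time_years > 0)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- attr(records, "truth")
  out
}

# mean baseline z across subtests (control-baseline norms), named by subject;
# used only to rank subjects for worst_baseline attrition
baseline_composite_for_attrition <- function(records, group) {
  norms <- build_norms(records)
  z <- zscore_records(records, norms)
  zb <- z[z$time_years == 0 & z$group == group, , drop = FALSE]
  sub_cols <- norms$subtest
  comp <- rowMeans(as.matrix(zb[, sub_cols, drop = FALSE]), na.rm = TRUE)
  stats::setNames(comp, zb$subject_id)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields use the [sim_config()] argument names; an optional `battery`
#' entry is a list of per-subtest records overriding [default_battery()].
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$battery)) {
    raw$battery <- do.call(rbind, lapply(raw$battery, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_sim_config: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, raw)
}

#' Norms implied by a simulation configuration
#'
#' Converts the configured control-baseline means and SDs into a
#' [build_norms()]-shaped reference table. Useful when the generating scale
#' itself — rather than an empirical control sample — should define the z
#' scores, e.g. in parameter-recovery studies.
#'
#' @param config A [sim_config()].
#' @return A `norm_reference` data frame (`subtest`, `mean`, `sd`, `direction`,
#'   `n_norm`; `n_norm` is `NA` since the norms are not sample-based).
#' @export
norms_from_config <- function(config) {
  validate_sim_config(config)
  bat <- config$battery
  structure(data.frame(
    subtest = bat$subtest,
    mean = bat$control_mean,
    sd = bat$control_sd,
    direction = bat$direction,
    n_norm = NA_integer_,
    stringsAsFactors = FALSE
  ), class = c("norm_reference", "data.frame"))
}

#' Write / read the canonical long-format cohort CSV
#'
#' One row per subject and wave: `subject_id`, `group`, `baseline_age`, `sex`,
#' `time_years`, then one column per subtest.
#'
#' @param records Cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns the validated cohort data frame.
#' @export
write_cohort <- function(records, path) {
  assert_cohort(records, "write_cohort")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cohort(records, "read_cohort")
  records
}
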
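#' Default neuropsychological test battery
#'
#' The battery of 14 subtests used throughout the package: verbal learning and
#' memory (CVLT-II, Logical Memory), attention and working memory (Digit Span,
#' Letter-Number Sequencing), psychomotor speed (Digit-Symbol Coding), timed
#' colour-word measures (colour naming, reading, interference, switching) and
#' verbal fluency (FAS, categories, switching). Timed completion-time measures
#' are `lower_better`: a faster (smaller) raw score is better performance.
#'
#' Besides the scoring metadata (`subtest`, `direction`) the table carries the
#' generative parameters used by [generate_cohort()]: the control-baseline raw
#' mean and SD, the patient deficit in control-SD units, per-group practice
#' slopes and the baseline-age slope (both in SD units per year). The raw means
#' and SDs are synthetic plausible values — normative raw-score distributions
#' are battery- and language-specific — and only anchor the raw scale; all
#' downstream analysis happens on the control-baseline z scale.
#'
#' @return A data frame with one row per subtest and columns `subtest`,
#'   `direction` (`"higher_better"` or `"lower_better"`), `control_mean`,
#'   `control_sd`, `group_deficit`, `practice_control`, `practice_patient`,
#'   `age_slope`.
#' @seealso [default_domains()], [sim_config()]
#' @export
#' @examples
#' default_battery()
default_battery <- function() {
  b <- data.frame(
    subtest = c("cvlt_a_total", "lm_trial1", "cvlt_delay", "lm_trial2",
                "digit_span", "digit_symbol", "cowat_color_naming",
                "cowat_reading", "letter_number_seq", "vf_fas",
                "vf_categories", "vf_switching", "cowat_interference",
                "cowat_switching"),
    direction = c("higher_better", "higher_better", "higher_better",
                  "higher_better", "higher_better", "higher_better",
                  "lower_better", "lower_better", "higher_better",
                  "higher_better", "higher_better", "higher_better",
                  "lower_better", "lower_better"),
    control_mean = c(55, 28, 12, 26, 17, 80, 29, 22, 11, 42, 44, 14, 55, 62),
    control_sd   = c(10,  6,  3, 6.5, 4, 15,  5,  4,  3, 11, 10,  3, 12, 14),
    stringsAsFactors = FALSE
  )
  b$group_deficit    <- 1.0
  b$practice_control <- 0.03
  b$practice_patient <- 0.015
  b$age_slope        <- -0.01
  b
}

#' Default theory-based cognitive domains
#'
#' Eight domains, each the mean of its member subtests' z-scores. Single-test
#' domains (attention, psychomotor speed, working memory) equal that test's
#' z-score.
#'
#' @return A named list mapping domain name to a character vector of member
#'   subtests.
#' @seealso [compute_domain_scores()]
#' @export
default_domains <- function() {
  list(
    learning          = c("cvlt_a_total", "lm_trial1"),
    memory            = c("cvlt_delay", "lm_trial2"),
    attention         = "digit_span",
    psychomotor_speed = "digit_symbol",
    mental_speed      = c("cowat_color_naming", "cowat_reading"),
    working_memory    = "letter_number_seq",
    verbal_fluency    = c("vf_fas", "vf_categories", "vf_switching"),
    cognitive_control = c("cowat_interference", "cowat_switching")
  )
}

# columns every cohort table must carry ahead of the subtest columns
cohort_id_cols <- function() {
  c("subject_id", "group", "baseline_age", "sex", "time_years")
}

# signed direction multiplier: +1 higher_better, -1 lower_better
direction_sign <- function(direction) {
  ifelse(direction == "higher_better", 1, -1)
}

assert_cohort <- function(data, call_name) {
  missing <- setdiff(cohort_id_cols(), names(data))
  if (length(missing)) {
    stop(sprintf("%s: input is missing required column(s): %s",
                 call_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(data$group), c("patient", "control"))
  if (length(bad)) {
    stop(sprintf("%s: group must be 'patient' or 'control', found: %s",
                 call_name, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}
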
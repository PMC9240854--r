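# shared fixture builders — everything is generated in code, no stored data

# deterministic config: no noise, no deficits, no practice; every control's raw
# score equals the configured control mean at both waves
zero_noise_config <- function(n_patient = 4, n_control = 6, ...) {
  bat <- default_battery()
  bat$group_deficit <- 0
  bat$practice_control <- 0
  bat$practice_patient <- 0
  bat$age_slope <- 0
  sim_config(n_patient = n_patient, n_control = n_control, battery = bat,
             random_intercept_sd = 0, residual_sd = 0,
             impaired_fraction = 0, ...)
}

# small noisy cohort for generic plumbing tests
small_cohort <- function(seed = 42, n_patient = 20, n_control = 25, ...) {
  generate_cohort(sim_config(n_patient = n_patient, n_control = n_control,
                             seed = seed, ...))
}

# hand-built two-subject cohort with known raw values on a 2-subtest battery
tiny_battery <- function() {
  data.frame(subtest = c("hb", "lb"),
             direction = c("higher_better", "lower_better"),
             control_mean = c(0, 0), control_sd = c(1, 1),
             group_deficit = 0, practice_control = 0, practice_patient = 0,
             age_slope = 0, stringsAsFactors = FALSE)
}

tiny_cohort <- function(hb = c(4, 6), lb = c(10, 20)) {
  data.frame(
    subject_id = c("C1", "C2"), group = "control", baseline_age = 30,
    sex = "F", time_years = 0, hb = hb, lb = lb,
    stringsAsFactors = FALSE
  )
}
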
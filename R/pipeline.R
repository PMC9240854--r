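#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `input` (path to a long-format cohort CSV) or `sim`
#' (a [sim_config()]) must be supplied.
#'
#' @param input Path to a cohort CSV, or `NULL`.
#' @param sim A [sim_config()], or `NULL`.
#' @param domains Domain definitions; see [default_domains()].
#' @param ci_level RCI confidence level.
#' @param classifier A [classifier_config()].
#' @param df_method Degrees-of-freedom method for growth-model p-values.
#' @param seed Integer seed for the simulation stage.
#' @param verbose Log stage progress and case counts to the console?
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, sim = NULL, domains = default_domains(),
                       ci_level = 0.90, classifier = classifier_config(),
                       df_method = "residual", seed = NULL, verbose = FALSE) {
  if (is.null(input) == is.null(sim)) {
    stop("run_config: supply exactly one of 'input' or 'sim'", call. = FALSE)
  }
  structure(list(input = input, sim = sim, domains = domains,
                 ci_level = ci_level, classifier = classifier,
                 df_method = df_method, seed = seed, verbose = verbose),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) the cohort, build control-baseline norms and domain
#' scores, fit the growth models and per-group growth curves, classify
#' reliable change, classify impairment with prevalence, per-domain and
#' transition summaries, and bundle every table with run metadata. Any stage
#' failure aborts with an error naming the stage.
#'
#' @param config A [run_config()].
#' @return A `report_bundle`: list with `cohort`, `norms`, `domain_scores`,
#'   `growth`, `group_growth`, `rci_classifications`, `rci_summary`,
#'   `prevalence`, `domain_impairment`, `transitions`, `metadata`.
#' @export
#' @examples
#' cfg <- run_config(sim = sim_config(n_patient = 30, n_control = 30), seed = 1)
#' bundle <- run_pipeline(cfg)
#' bundle$prevalence
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(stage, fmt, ...) {
    if (isTRUE(config$verbose)) {
      message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    }
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_stage(name, "done in %.2fs", as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  cohort <- stage("input", {
    if (!is.null(config$sim)) {
      generate_cohort(config$sim, seed = config$seed)
    } else {
      read_cohort(config$input)
    }
  })
  log_stage("input", "%d records, %d subjects", nrow(cohort),
            length(unique(cohort$subject_id)))

  norms <- stage("norms", build_norms(cohort))
  scores <- stage("scoring",
                  score_cohort(cohort, norms = norms, domains = config$domains))
  log_stage("scoring", "%d complete-composite records",
            sum(!is.na(scores$composite)))

  measures <- c(names(config$domains), "composite")
  growth <- stage("growth",
                  growth_table(scores, measures, df_method = config$df_method))
  group_growth <- stage("growth_curves", {
    fits <- lapply(measures, function(m)
      fit_group_growth_curves(scores, m, df_method = config$df_method))
    stats::setNames(fits, measures)
  })

  rci_cls <- stage("rci", classify_rci(scores, measures,
                                       ci_level = config$ci_level))
  log_stage("rci", "%d complete pairs classified, %d excluded",
            nrow(rci_cls), sum(attr(rci_cls, "n_excluded")))
  rci_summary <- stage("rci", summarize_rci(rci_cls))

  profiles <- stage("impairment", classify_impairment(scores, config$classifier))
  prevalence <- stage("impairment", impairment_prevalence(profiles))
  domain_imp <- stage("impairment", domain_impairment_table(profiles))
  transitions <- stage("impairment", {
    pat <- profiles[profiles$group == "patient", , drop = FALSE]
    attr(pat, "config") <- attr(profiles, "config")
    transition_analysis(pat)
  })

  structure(list(
    cohort = cohort, norms = norms, domain_scores = scores,
    growth = growth, group_growth = group_growth,
    rci_classifications = rci_cls, rci_summary = rci_summary,
    impairment_profiles = profiles, prevalence = prevalence,
    domain_impairment = domain_imp, transitions = transitions,
    metadata = list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("cogcourse")),
      ci_level = config$ci_level,
      cutoff = config$classifier$cutoff,
      min_domains = config$classifier$min_domains,
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "report_bundle")
}

#' Write a report bundle to a directory of CSV files
#'
#' Emits `norms.csv`, `domain_scores.csv`, `growth.csv`, `rci_summary.csv`,
#' `prevalence.csv`, `domain_impairment.csv`, `transitions.csv` and a
#' `metadata.json` file.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(as.data.frame(bundle$norms), "norms.csv")
  w(bundle$domain_scores, "domain_scores.csv")
  w(bundle$growth, "growth.csv")
  w(bundle$rci_summary, "rci_summary.csv")
  w(bundle$prevalence, "prevalence.csv")
  w(bundle$domain_impairment, "domain_impairment.csv")
  tr <- bundle$transitions
  w(data.frame(
    stratum = c(rep("baseline_impaired", 4), rep("baseline_unimpaired", 3)),
    quantity = c("pct_improved_any_domain", "pct_no_longer_impaired",
                 "pct_additional_domains", "pct_all_domains_at_follow_up",
                 "pct_improved", "pct_declined", "pct_became_impaired"),
    value = c(tr$impaired$pct_improved_any_domain,
              tr$impaired$pct_no_longer_impaired,
              tr$impaired$pct_additional_domains,
              tr$impaired$pct_all_domains_at_follow_up,
              tr$unimpaired$pct_improved, tr$unimpaired$pct_declined,
              tr$unimpaired$pct_became_impaired)
  ), "transitions.csv")
  jsonlite::write_json(bundle$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
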
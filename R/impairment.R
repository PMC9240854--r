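#' Configuration for clinically significant impairment classification
#'
#' Domain-level impairment is a z-score strictly below `cutoff` (default
#' -1.5 SD on the control-baseline scale); a subject is clinically impaired
#' when at least `min_domains` (default 2) of the considered domains are
#' impaired. The composite is excluded from the count by default — it averages
#' the domains and would double-weight them.
#'
#' @param cutoff Impairment cut-off in z units; must be negative.
#' @param min_domains Minimum impaired domains for clinically significant
#'   impairment.
#' @param domains Character vector of domains considered.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(cutoff = -1.5, min_domains = 2,
                              domains = names(default_domains())) {
  if (!is.numeric(cutoff) || cutoff >= 0) {
    stop("classifier_config: cutoff must be negative", call. = FALSE)
  }
  if (min_domains < 1 || min_domains > length(domains)) {
    stop("classifier_config: min_domains must be in [1, length(domains)]",
         call. = FALSE)
  }
  structure(list(cutoff = cutoff, min_domains = min_domains,
                 domains = domains), class = "classifier_config")
}

#' Flag domain-level impairment
#'
#' Strictly below the cut-off: a score exactly at the cut-off is not impaired.
#' Missing z-scores give a missing flag.
#'
#' @param z Numeric vector of domain z-scores (control-baseline scale).
#' @param config A [classifier_config()].
#' @return Logical vector (with `NA` for missing scores).
#' @export
flag_impairment <- function(z, config = classifier_config()) {
  z < config$cutoff
}

#' Classify clinically significant impairment per subject and wave
#'
#' Applies [flag_impairment()] to every considered domain of every record,
#' counts impaired domains (missing domains are excluded from the count and
#' tallied in `n_domains_missing`), and sets `clinically_impaired` when the
#' count reaches `min_domains`. Records with fewer observed domains than
#' `min_domains` cannot be ruled impaired or unimpaired and get a missing
#' status.
#'
#' @param domain_scores Scored cohort (see [score_cohort()]).
#' @param config A [classifier_config()].
#' @return Data frame with the id columns, one logical `imp_<domain>` column
#'   per considered domain, `n_impaired`, `n_domains_observed`,
#'   `n_domains_missing` and `clinically_impaired`.
#' @export
classify_impairment <- function(domain_scores, config = classifier_config()) {
  assert_cohort(domain_scores, "classify_impairment")
  miss <- setdiff(config$domains, names(domain_scores))
  if (length(miss)) {
    stop("classify_impairment: domain(s) not in scores: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- domain_scores[, cohort_id_cols()]
  flags <- sapply(config$domains, function(d)
    flag_impairment(domain_scores[[d]], config))
  flags <- matrix(flags, nrow = nrow(out),
                  dimnames = list(NULL, config$domains))
  colnames(flags) <- paste0("imp_", config$domains)
  out <- cbind(out, as.data.frame(flags))
  out$n_impaired <- rowSums(flags, na.rm = TRUE)
  out$n_domains_observed <- rowSums(!is.na(flags))
  out$n_domains_missing <- length(config$domains) - out$n_domains_observed
  out$clinically_impaired <- out$n_impaired >= config$min_domains
  # too few observed domains to support either verdict
  out$clinically_impaired[out$n_domains_observed < config$min_domains &
                            !out$clinically_impaired] <- NA
  attr(out, "config") <- config
  out
}

#' Prevalence of clinically significant impairment
#'
#' Percent of classifiable subjects with `clinically_impaired = TRUE`, per
#' group and wave. Subjects with a missing status are excluded from the
#' denominator, which is reported.
#'
#' @param profiles Output of [classify_impairment()].
#' @return Data frame with `group`, `time_years`, `n`, `n_impaired`, `pct`.
#' @export
impairment_prevalence <- function(profiles) {
  if (!nrow(profiles)) {
    stop("impairment_prevalence: empty input", call. = FALSE)
  }
  keys <- unique(profiles[, c("group", "time_years")])
  keys <- keys[order(keys$group, keys$time_years), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    s <- profiles$clinically_impaired[profiles$group == keys$group[i] &
                                        profiles$time_years == keys$time_years[i]]
    s <- s[!is.na(s)]
    data.frame(group = keys$group[i], time_years = keys$time_years[i],
               n = length(s), n_impaired = sum(s),
               pct = 100 * sum(s) / length(s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-domain impairment percentages
#'
#' Percent of subjects impaired on each domain, per group and wave — the shape
#' of a per-domain impairment bar chart.
#'
#' @param profiles Output of [classify_impairment()].
#' @return Data frame with `group`, `time_years`, `domain`, `n`, `pct_impaired`.
#' @export
domain_impairment_table <- function(profiles) {
  config <- attr(profiles, "config")
  keys <- unique(profiles[, c("group", "time_years")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- profiles[profiles$group == keys$group[i] &
                      profiles$time_years == keys$time_years[i], , drop = FALSE]
    do.call(rbind, lapply(config$domains, function(d) {
      f <- sub[[paste0("imp_", d)]]
      f <- f[!is.na(f)]
      data.frame(group = keys$group[i], time_years = keys$time_years[i],
                 domain = d, n = length(f),
                 pct_impaired = 100 * mean(f), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Baseline-to-follow-up impairment transition analysis
#'
#' Strata are defined by baseline clinical-impairment status; percentages are
#' of the respective baseline stratum, over complete two-wave cases only
#' (subjects missing a wave or a status are excluded and counted).
#'
#' Within the baseline-impaired stratum: the percentage improving beyond
#' threshold on at least one domain (impaired on it at baseline, not at
#' follow-up), the percentage no longer clinically impaired at follow-up, the
#' percentage reaching criteria on at least one additional domain, and the
#' percentage impaired on all considered domains at follow-up. Within the
#' baseline-unimpaired stratum: the percentage improving on at least one
#' domain, declining on at least one domain (newly impaired on it), and
#' becoming clinically impaired. A subject can contribute to several
#' categories (e.g. improve on one domain and decline on another).
#'
#' @param profiles Output of [classify_impairment()] covering both waves.
#' @param baseline_time,followup_time Wave times; default 0 and the largest
#'   time present.
#' @return A `transition_summary` list with `impaired` and `unimpaired`
#'   strata (counts and percentages) and `n_excluded`.
#' @export
transition_analysis <- function(profiles, baseline_time = 0,
                                followup_time = max(profiles$time_years)) {
  config <- attr(profiles, "config")
  fcols <- paste0("imp_", config$domains)
  b <- profiles[profiles$time_years == baseline_time, , drop = FALSE]
  f <- profiles[profiles$time_years == followup_time, , drop = FALSE]
  i <- match(b$subject_id, f$subject_id)
  has_fu <- !is.na(i)
  complete <- has_fu & !is.na(b$clinically_impaired) &
    !is.na(f$clinically_impaired[i])
  n_excluded <- sum(!complete)
  b <- b[complete, , drop = FALSE]
  f <- f[i[complete], , drop = FALSE]

  bf <- as.matrix(b[, fcols, drop = FALSE])
  ff <- as.matrix(f[, fcols, drop = FALSE])
  # per-subject domain transitions; NA-safe: only domains observed both waves
  improved_any <- rowSums(bf & !ff, na.rm = TRUE) > 0
  declined_any <- rowSums(!bf & ff, na.rm = TRUE) > 0
  all_impaired_fu <- rowSums(ff, na.rm = TRUE) == length(config$domains)

  imp0 <- b$clinically_impaired
  pct <- function(x, denom) if (denom == 0) NA_real_ else 100 * sum(x) / denom
  n_imp <- sum(imp0); n_unimp <- sum(!imp0)

  structure(list(
    impaired = list(
      n = n_imp,
      pct_improved_any_domain = pct(improved_any[imp0], n_imp),
      pct_no_longer_impaired = pct(!f$clinically_impaired[imp0], n_imp),
      pct_additional_domains = pct(declined_any[imp0], n_imp),
      pct_all_domains_at_follow_up = pct(all_impaired_fu[imp0], n_imp)
    ),
    unimpaired = list(
      n = n_unimp,
      pct_improved = pct(improved_any[!imp0], n_unimp),
      pct_declined = pct(declined_any[!imp0], n_unimp),
      pct_became_impaired = pct(f$clinically_impaired[!imp0], n_unimp)
    ),
    n_excluded = n_excluded
  ), class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", v))
  cat(sprintf("Baseline-impaired stratum (n = %d):\n", x$impaired$n))
  cat(sprintf("  improved on >=1 domain: %s\n",
              fmt(x$impaired$pct_improved_any_domain)))
  cat(sprintf("  no longer clinically impaired: %s\n",
              fmt(x$impaired$pct_no_longer_impaired)))
  cat(sprintf("  reached criteria on additional domain(s): %s\n",
              fmt(x$impaired$pct_additional_domains)))
  cat(sprintf("  impaired on all domains at follow-up: %s\n",
              fmt(x$impaired$pct_all_domains_at_follow_up)))
  cat(sprintf("Baseline-unimpaired stratum (n = %d):\n", x$unimpaired$n))
  cat(sprintf("  improved on >=1 domain: %s\n", fmt(x$unimpaired$pct_improved)))
  cat(sprintf("  declined on >=1 domain: %s\n", fmt(x$unimpaired$pct_declined)))
  cat(sprintf("  became clinically impaired: %s\n",
              fmt(x$unimpaired$pct_became_impaired)))
  cat(sprintf("Excluded (incomplete waves/status): %d\n", x$n_excluded))
  invisible(x)
}
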
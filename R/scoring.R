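#' Build control-baseline norms for a battery
#'
#' Per-subtest normative mean and SD computed over the control group's baseline
#' (time 0) records only — follow-up scores are later standardised against
#' these same baseline norms, which keeps change interpretable on one scale
#' across the full follow-up interval. The SD uses the n - 1 denominator.
#'
#' @param records Long-format cohort data frame.
#' @param battery Data frame with `subtest` and `direction` columns naming the
#'   battery; defaults to the subtest columns present in `records` with
#'   directions from [default_battery()].
#' @param norm_group,norm_time Which records define the norm sample.
#' @return A `norm_reference` data frame: `subtest`, `mean`, `sd`, `direction`,
#'   `n_norm`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patient = 5, n_control = 20, seed = 1))
#' build_norms(cohort)
build_norms <- function(records, battery = NULL,
                        norm_group = "control", norm_time = 0) {
  assert_cohort(records, "build_norms")
  if (is.null(battery)) {
    present <- setdiff(names(records), cohort_id_cols())
    def <- default_battery()
    battery <- data.frame(subtest = present, stringsAsFactors = FALSE)
    battery$direction <- ifelse(
      present %in% def$subtest,
      def$direction[match(present, def$subtest)],
      "higher_better")
  }
  norm <- records[records$group == norm_group &
                    records$time_years == norm_time, , drop = FALSE]
  out <- battery[, c("subtest", "direction")]
  out$mean <- NA_real_; out$sd <- NA_real_; out$n_norm <- NA_integer_
  for (i in seq_len(nrow(out))) {
    st <- out$subtest[i]
    if (!st %in% names(norm)) {
      stop(sprintf("build_norms: subtest '%s' not present in records", st),
           call. = FALSE)
    }
    x <- norm[[st]][!is.na(norm[[st]])]
    if (length(x) < 2) {
      stop(sprintf("build_norms: subtest '%s' has fewer than 2 norm observations", st),
           call. = FALSE)
    }
    s <- stats::sd(x)
    if (s == 0) {
      stop(sprintf("build_norms: subtest '%s' has zero variance in the norm sample", st),
           call. = FALSE)
    }
    out$mean[i] <- mean(x); out$sd[i] <- s; out$n_norm[i] <- length(x)
  }
  structure(out[, c("subtest", "mean", "sd", "direction", "n_norm")],
            class = c("norm_reference", "data.frame"))
}

#' Export / import a normative reference table as CSV
#'
#' Columns `subtest`, `mean`, `sd`, `direction`, `n_norm`, so external
#' normative tables can be substituted for sample-based norms.
#'
#' @param norms A `norm_reference`.
#' @param path File path.
#' @return `read_norms()` returns a validated `norm_reference`.
#' @export
write_norms <- function(norms, path) {
  utils::write.csv(as.data.frame(norms), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  n <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subtest", "mean", "sd", "direction", "n_norm")
  miss <- setdiff(need, names(n))
  if (length(miss)) {
    stop("read_norms: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(n$sd <= 0)) stop("read_norms: all sd must be > 0", call. = FALSE)
  structure(n[, need], class = c("norm_reference", "data.frame"))
}

#' Convert raw subtest scores to control-baseline z-scores
#'
#' For higher-better subtests `z = (raw - mean) / sd`; for lower-better (timed)
#' subtests the sign is flipped, `z = (mean - raw) / sd`, so a higher z always
#' means better performance. Missing raw scores stay missing.
#'
#' @param records Long-format cohort data frame with raw scores.
#' @param norms A `norm_reference` covering every subtest column in `records`.
#' @return The records with each subtest column replaced by its z-score.
#' @export
zscore_records <- function(records, norms) {
  assert_cohort(records, "zscore_records")
  sub_cols <- setdiff(names(records), cohort_id_cols())
  uncovered <- setdiff(sub_cols, norms$subtest)
  if (length(uncovered)) {
    stop("zscore_records: no norms for subtest(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  out <- records
  for (st in sub_cols) {
    i <- match(st, norms$subtest)
    sgn <- direction_sign(norms$direction[i])
    out[[st]] <- sgn * (records[[st]] - norms$mean[i]) / norms$sd[i]
  }
  out
}

#' Domain scores and cognitive composite from z-scored records
#'
#' Each domain score is the mean of its member subtests' z-scores (members
#' missing for a record are dropped from that mean; a domain with all members
#' missing is missing, not zero). The composite is the mean of the available
#' domain scores, by default required to be complete: with fewer than
#' `min_domains` observed domains the composite is missing.
#'
#' @param zrecords Z-scored cohort (from [zscore_records()]).
#' @param domains Named list of member subtests per domain; see
#'   [default_domains()].
#' @param min_domains Minimum observed domains for a non-missing composite;
#'   defaults to all of them.
#' @return Data frame with the id columns, one column per domain, `composite`
#'   and `n_domains_observed`.
#' @export
compute_domain_scores <- function(zrecords, domains = default_domains(),
                                  min_domains = length(domains)) {
  assert_cohort(zrecords, "compute_domain_scores")
  if (!length(domains)) {
    stop("compute_domain_scores: empty domain definition", call. = FALSE)
  }
  for (d in names(domains)) {
    if (!length(domains[[d]])) {
      stop(sprintf("compute_domain_scores: domain '%s' has no member subtests", d),
           call. = FALSE)
    }
    miss <- setdiff(domains[[d]], names(zrecords))
    if (length(miss)) {
      stop(sprintf("compute_domain_scores: domain '%s' references missing subtest(s): %s",
                   d, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  out <- zrecords[, cohort_id_cols()]
  for (d in names(domains)) {
    m <- as.matrix(zrecords[, domains[[d]], drop = FALSE])
    v <- rowMeans(m, na.rm = TRUE)
    v[rowSums(!is.na(m)) == 0] <- NA_real_
    out[[d]] <- v
  }
  dm <- as.matrix(out[, names(domains), drop = FALSE])
  out$n_domains_observed <- rowSums(!is.na(dm))
  out$composite <- rowMeans(dm, na.rm = TRUE)
  out$composite[out$n_domains_observed == 0 |
                  out$n_domains_observed < min_domains] <- NA_real_
  attr(out, "domains") <- domains
  out
}

#' Score a raw cohort end to end
#'
#' Convenience wrapper: build (or accept) norms, z-score, and compute domain
#' scores in one call.
#'
#' @param records Raw cohort data frame.
#' @param norms Optional pre-built `norm_reference`; default builds
#'   control-baseline norms from `records`.
#' @inheritParams compute_domain_scores
#' @return As [compute_domain_scores()], with the norms attached as attribute
#'   `norms`.
#' @export
score_cohort <- function(records, norms = NULL, domains = default_domains(),
                         min_domains = length(domains)) {
  if (is.null(norms)) norms <- build_norms(records)
  z <- zscore_records(records, norms)
  scores <- compute_domain_scores(z, domains, min_domains)
  attr(scores, "norms") <- norms
  scores
}
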
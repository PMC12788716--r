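#' Mortality hazard ratios for inconsistent PA patterns
#'
#' Multivariable Cox models of mortality on the consistency labels: the
#' binary contrast (inconsistent vs consistent) and the three-level
#' contrast (`inconsistent_mvpa` and `inconsistent_lpa` vs `consistent`),
#' adjusted for the supplied covariates. The adjustment set deliberately
#' excludes the observed PA pattern itself: the exposure label is a
#' deterministic function of pattern and covariates, and conditioning on
#' the pattern would absorb the contrast of interest.
#'
#' @param data data.frame with `time`, `event`, the label columns produced
#'   by [consistency_labels()] (`inconsistent`, `label`), and covariates.
#' @param adjust character vector of adjustment covariates.
#' @param outcome_tag tag recorded on the results (e.g. `"all_cause"`).
#' @param subgroup_tag tag recorded on the results.
#' @param conf CI level.
#' @return data.frame of class `association_result`: `contrast`, `hr`,
#'   `lo`, `hi`, `p`, `n`, `events`, `outcome`, `subgroup`, `significant`.
#' @export
fit_inconsistency_cox <- function(data, adjust, outcome_tag = "all_cause",
                                  subgroup_tag = "full", conf = 0.95) {
  stopifnot(all(c("inconsistent", "label", "time", "event") %in% names(data)))
  if (sum(data$event) < 10) stop("fewer than 10 events")
  tab <- table(data$label)
  if (tab["consistent"] == 0) stop("empty reference (consistent) stratum")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  row_from <- function(fit, coef_name, contrast) {
    b <- stats::coef(fit)[coef_name]
    se <- sqrt(diag(stats::vcov(fit))[coef_name])
    data.frame(contrast = contrast, hr = exp(b), lo = exp(b - z * se),
               hi = exp(b + z * se),
               p = 2 * stats::pnorm(-abs(b / se)),
               n = fit$n, events = fit$nevent,
               outcome = outcome_tag, subgroup = subgroup_tag,
               row.names = NULL)
  }
  fml2 <- stats::reformulate(c("inconsistent", adjust),
                             response = "survival::Surv(time, event)")
  fit2 <- survival::coxph(fml2, data = data)
  out <- row_from(fit2, "inconsistent", "inconsistent_vs_consistent")
  lab_present <- names(tab)[tab > 0]
  if (length(lab_present) > 1) {
    fml3 <- stats::reformulate(c("label", adjust),
                               response = "survival::Surv(time, event)")
    fit3 <- survival::coxph(fml3, data = droplevels(data))
    for (lv in setdiff(lab_present, "consistent")) {
      out <- rbind(out, row_from(fit3, paste0("label", lv),
                                 paste0(lv, "_vs_consistent")))
    }
  }
  out$significant <- out$lo > 1 | out$hi < 1
  class(out) <- c("association_result", "data.frame")
  out
}

#' Inconsistency association within the observed nonbaseline subgroup
#'
#' Refits the three-level inconsistency Cox model after restricting to
#' participants whose *observed* pattern is not `baseline`.
#'
#' @param data as in [fit_inconsistency_cox()], plus the observed `pattern`
#'   column.
#' @inheritParams fit_inconsistency_cox
#' @return an `association_result` data.frame tagged
#'   `subgroup = "nonbaseline"`.
#' @export
subgroup_analysis <- function(data, adjust, outcome_tag = "all_cause",
                              conf = 0.95) {
  sub <- data[data$pattern != "baseline", , drop = FALSE]
  if (!nrow(sub)) stop("empty nonbaseline subgroup")
  fit_inconsistency_cox(sub, adjust, outcome_tag = outcome_tag,
                        subgroup_tag = "nonbaseline", conf = conf)
}

#' Sensitivity-analysis harness
#'
#' Re-runs the inconsistency Cox analyses under prespecified scenarios:
#' `alternate` (an alternative cohort, e.g. an external one),
#' `cause_specific` (cause-specific mortality, competing causes treated as
#' censored), `truncated` (follow-up administratively truncated at
#' `truncate_at` years), and `internal_test` (the analysis restricted to
#' the internal test-set ids). Scenarios whose required inputs are missing
#' are skipped with a recorded reason.
#'
#' @param data main analytic data (with labels, covariates, outcome and a
#'   `cause` column holding cause-of-death strings for deaths).
#' @param adjust adjustment covariates.
#' @param scenarios subset of
#'   `c("alternate", "cause_specific", "truncated", "internal_test")`.
#' @param alternate optional alternative cohort data.frame.
#' @param causes cause labels to analyse cause-specifically.
#' @param truncate_at truncation horizon in years.
#' @param test_ids ids of the internal test split.
#' @return named list: each scenario holds either an `association_result`
#'   (or list of them) or a `skipped` reason string.
#' @export
sensitivity_suite <- function(data, adjust,
                              scenarios = c("alternate", "cause_specific",
                                            "truncated", "internal_test"),
                              alternate = NULL, causes = c("cvd", "cancer"),
                              truncate_at = NULL, test_ids = NULL) {
  out <- list()
  if ("alternate" %in% scenarios) {
    out$alternate <- if (is.null(alternate)) {
      list(skipped = "no alternate cohort supplied")
    } else fit_inconsistency_cox(alternate, adjust, subgroup_tag = "alternate")
  }
  if ("cause_specific" %in% scenarios) {
    out$cause_specific <- if (!"cause" %in% names(data)) {
      list(skipped = "no cause-of-death column")
    } else {
      lapply(stats::setNames(causes, causes), function(cs) {
        d <- data
        d$event <- as.integer(d$event == 1 & !is.na(d$cause) & d$cause == cs)
        fit_inconsistency_cox(d, adjust, outcome_tag = paste0(cs, "_specific"))
      })
    }
  }
  if ("truncated" %in% scenarios) {
    out$truncated <- if (is.null(truncate_at)) {
      list(skipped = "no truncation horizon supplied")
    } else {
      d <- data
      d$event <- as.integer(d$event == 1 & d$time <= truncate_at)
      d$time <- pmin(d$time, truncate_at)
      fit_inconsistency_cox(d, adjust, outcome_tag = "all_cause",
                            subgroup_tag = paste0("truncated_", truncate_at, "y"))
    }
  }
  if ("internal_test" %in% scenarios) {
    out$internal_test <- if (is.null(test_ids)) {
      list(skipped = "no internal test ids supplied")
    } else {
      fit_inconsistency_cox(data[data$id %in% test_ids, , drop = FALSE],
                            adjust, subgroup_tag = "internal_test")
    }
  }
  out
}

#' Sort association results for forest-plot presentation
#'
#' @param results an `association_result` data.frame (or rbind of several).
#' @return the rows sorted by decreasing hazard ratio.
#' @export
sort_by_hr <- function(results) {
  results[order(-results$hr), , drop = FALSE]
}
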
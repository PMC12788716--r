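#' Classify blood-pressure status
#'
#' High blood pressure is defined as any of: systolic BP >= 120 mm Hg,
#' diastolic BP >= 70 mm Hg, a hospitalization record, or use of
#' antihypertensive medication. Among high-BP participants, those with SBP
#' 120-139 mm Hg or DBP 70-89 mm Hg who are not on antihypertensive
#' medication (and are below the 140/90 hypertension line) are classified
#' as `elevated`; all others as `hypertension`.
#'
#' @param sbp,dbp systolic / diastolic blood pressure in mm Hg (may be `NA`).
#' @param meds logical, antihypertensive medication use.
#' @param hospitalization logical, hypertension-related hospitalization
#'   record.
#' @return data.frame with columns `high_bp` (logical, `NA` when
#'   unclassifiable) and `bp_class` (factor `elevated`/`hypertension`, `NA`
#'   when not high-BP or unclassifiable). Vectorized over its inputs.
#' @export
classify_bp <- function(sbp, dbp, meds = FALSE, hospitalization = FALSE) {
  n <- max(length(sbp), length(dbp), length(meds), length(hospitalization))
  sbp <- rep_len(sbp, n); dbp <- rep_len(dbp, n)
  meds <- rep_len(as.logical(meds), n)
  hospitalization <- rep_len(as.logical(hospitalization), n)
  if (any(!is.na(sbp) & !is.na(dbp) & sbp <= dbp)) {
    stop("require sbp > dbp where both are observed")
  }
  bp_known <- !is.na(sbp) & !is.na(dbp)
  flag <- (meds | hospitalization)
  high <- ifelse(bp_known, sbp >= 120 | dbp >= 70 | flag,
                 ifelse(flag, TRUE, NA))
  elevated <- bp_known & !meds &
    ((sbp >= 120 & sbp <= 139) | (dbp >= 70 & dbp <= 89)) &
    sbp < 140 & dbp < 90
  cls <- ifelse(!is.na(high) & high,
                ifelse(elevated, "elevated", "hypertension"), NA)
  data.frame(high_bp = high,
             bp_class = factor(cls, levels = c("elevated", "hypertension")))
}

#' Apply the study inclusion/exclusion flow
#'
#' Removes participants in the study-flow order — (1) poor device
#' calibration, (2) inadequate wear time, (3) not high blood pressure,
#' (4) missing outcome or covariate values — counting each participant once
#' at the first failing step. The ledger counts plus the retained count
#' always sum to the input count, and the operation is idempotent.
#'
#' @param cohort data.frame with logical `calibration_ok` and `wear_ok`
#'   columns, a high-BP indicator (see `high_bp_col`), outcome columns
#'   `time`/`event`, and covariates.
#' @param covariate_cols covariate columns checked for missingness
#'   (default: every column not otherwise accounted for).
#' @param high_bp_col name of the logical high-BP column; if absent every
#'   row is assumed high-BP (as when the generator samples high-BP adults
#'   directly).
#' @return list with `cohort` (retained rows) and `ledger` (named integer
#'   vector: `poor_calibration`, `inadequate_wear`, `not_high_bp`,
#'   `missing_values`, `retained`).
#' @export
apply_inclusion <- function(cohort, covariate_cols = NULL,
                            high_bp_col = "high_bp") {
  n0 <- nrow(cohort)
  alive <- rep(TRUE, n0)
  step <- function(fail) {
    k <- sum(alive & fail)
    alive <<- alive & !fail
    k
  }
  bad_cal <- if ("calibration_ok" %in% names(cohort)) !cohort$calibration_ok else FALSE
  bad_wear <- if ("wear_ok" %in% names(cohort)) !cohort$wear_ok else FALSE
  not_bp <- if (high_bp_col %in% names(cohort)) {
    !cohort[[high_bp_col]] | is.na(cohort[[high_bp_col]])
  } else FALSE
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(cohort),
                              c("id", "participant_id", "calibration_ok",
                                "wear_ok", high_bp_col, "cause"))
  }
  miss <- rowSums(is.na(cohort[, intersect(covariate_cols, names(cohort)),
                               drop = FALSE])) > 0
  ledger <- c(poor_calibration = step(rep_len(bad_cal, n0)),
              inadequate_wear = step(rep_len(bad_wear, n0)),
              not_high_bp = step(rep_len(not_bp, n0)),
              missing_values = step(rep_len(miss, n0)))
  ledger <- c(ledger, retained = sum(alive))
  list(cohort = cohort[alive, , drop = FALSE], ledger = ledger)
}

#' Intraclass correlation coefficient for repeated continuous measurements
#'
#' ICC(2,1): two-way random-effects, single-measure, absolute-agreement
#' form, computed from the ANOVA mean squares of the subjects-by-raters
#' layout:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater
#' (between-occasion) and \eqn{MS_E} the residual mean square.
#'
#' @param x matrix or data.frame, one row per subject, one column per
#'   measurement occasion (complete cases used).
#' @return list of class `reliability_result`: `variable`, `statistic`
#'   (`"ICC"`), `estimate`, `n`.
#' @param variable label carried through to the result.
#' @export
icc_agreement <- function(x, variable = deparse(substitute(x))) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need at least 2 complete measurement pairs")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) stop("zero variance in all ratings; ICC undefined")
  structure(list(variable = variable, statistic = "ICC",
                 estimate = (msr - mse) / denom, n = n),
            class = "reliability_result")
}

#' Cohen's kappa for a K x K agreement table
#'
#' Unweighted kappa \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o}
#' the observed diagonal agreement proportion and \eqn{p_e} the chance
#' agreement implied by the marginals.
#'
#' @param tab square contingency matrix of counts (rater 1 in rows,
#'   rater 2 in columns), or a 2-column matrix/data.frame of paired
#'   categorical ratings.
#' @param variable label carried through to the result.
#' @return list of class `reliability_result`: `variable`, `statistic`
#'   (`"kappa"`), `estimate`, `n`.
#' @export
cohens_kappa <- function(tab, variable = deparse(substitute(tab))) {
  if (!is.matrix(tab) || nrow(tab) != ncol(tab)) {
    m <- as.data.frame(tab)
    if (ncol(m) != 2L) stop("supply a square count matrix or 2 rating columns")
    lev <- sort(unique(c(as.character(m[[1]]), as.character(m[[2]]))))
    tab <- table(factor(m[[1]], lev), factor(m[[2]], lev))
  }
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("negative counts")
  n <- sum(tab)
  if (n == 0) stop("empty table")
  p <- tab / n
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  if (1 - pe < .Machine$double.eps) stop("degenerate marginals: p_e = 1")
  structure(list(variable = variable, statistic = "kappa",
                 estimate = (po - pe) / (1 - pe), n = n),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.4f  [n = %d]\n", x$statistic, x$variable,
              x$estimate, x$n))
  invisible(x)
}
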
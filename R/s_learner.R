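#' Counterfactual survival profile under the four PA patterns
#'
#' The S-learner step: evaluates the interaction Cox base learner four
#' times per participant, varying only the PA-pattern input, and returns
#' the four predicted survival probabilities at the decision horizon, the
#' optimal pattern (the survival argmax, ties broken toward the lower-MVPA
#' pattern), and the margin (best minus second-best survival — small
#' margins flag recommendations that may lack clinical significance;
#' no margin threshold is imposed).
#'
#' @param model a `cox_interaction_model`.
#' @param newdata data.frame of covariates (the `pattern` column, if any,
#'   is ignored).
#' @param t decision horizon in years.
#' @return data.frame of class `counterfactual_profile`: `id` (if present
#'   in `newdata`), `surv_<pattern>` for the four patterns, `optimal`,
#'   `margin`, `t`.
#' @export
counterfactual_profile <- function(model, newdata, t = 10) {
  S <- sapply(pa_patterns(), function(k) {
    predict_survival(model, newdata, pattern = k, t = t)
  })
  if (is.null(dim(S))) S <- matrix(S, nrow = 1, dimnames = list(NULL, pa_patterns()))
  sorted <- t(apply(S, 1, sort, decreasing = TRUE))
  out <- data.frame(id = newdata$id %||% seq_len(nrow(newdata)))
  for (k in pa_patterns()) out[[paste0("surv_", k)]] <- S[, k]
  out$optimal <- pattern_argmax(S)
  out$margin <- sorted[, 1] - sorted[, 2]
  out$t <- t
  class(out) <- c("counterfactual_profile", "data.frame")
  out
}

#' Heterogeneous survival difference between two patterns
#'
#' \eqn{S_A(t) - S_B(t)} from a counterfactual profile; antisymmetric in
#' its arguments.
#'
#' @param profile a `counterfactual_profile`.
#' @param pattern_a,pattern_b pattern labels.
#' @return numeric vector of survival differences.
#' @export
heterogeneous_effect <- function(profile, pattern_a, pattern_b) {
  stopifnot(pattern_a %in% pa_patterns(), pattern_b %in% pa_patterns())
  profile[[paste0("surv_", pattern_a)]] - profile[[paste0("surv_", pattern_b)]]
}

#' Consistency of observed and predicted-optimal PA patterns
#'
#' Labels each participant `consistent` when the observed pattern equals
#' the predicted optimal pattern; otherwise `inconsistent_mvpa` when the
#' predicted optimum is an MVPA-demanding pattern (`active_regular` or
#' `active_ww`), and `inconsistent_lpa` when the predicted optimum is
#' LPA-primary (`active_lpa`, and also `baseline` — the low-activity
#' optimum is grouped with the LPA-primary side of the two-way split).
#'
#' @param observed factor/character of observed patterns.
#' @param optimal factor/character of predicted optimal patterns (e.g.
#'   `counterfactual_profile()$optimal`).
#' @return data.frame: `inconsistent` (0/1) and `label` (factor
#'   `consistent`, `inconsistent_mvpa`, `inconsistent_lpa`).
#' @export
consistency_labels <- function(observed, optimal) {
  observed <- pa_pattern_factor(as.character(observed))
  optimal <- pa_pattern_factor(as.character(optimal))
  stopifnot(length(observed) == length(optimal))
  same <- observed == optimal
  lab <- ifelse(same, "consistent",
         ifelse(optimal %in% c("active_regular", "active_ww"),
                "inconsistent_mvpa", "inconsistent_lpa"))
  data.frame(
    inconsistent = as.integer(!same),
    label = factor(lab, levels = c("consistent", "inconsistent_mvpa",
                                   "inconsistent_lpa"))
  )
}
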
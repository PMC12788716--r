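#' Run the full individualized-PA analysis pipeline on a cohort
#'
#' Chains the stages of the analysis on a participant table: 80/20 split,
#' LASSO-Cox covariate selection (pattern forced), interaction Cox fit with
#' backward elimination, IPCW evaluation (Brier, time-dependent AUC) on the
#' internal test set, counterfactual profiles and the optimal-pattern
#' argmax at the decision horizon, consistency labels, and the
#' inconsistency Cox models (full cohort and nonbaseline subgroup).
#'
#' @param participants data.frame with `id`, covariates, `pattern`, `time`,
#'   `event`.
#' @param candidates candidate covariates for LASSO selection.
#' @param horizon decision horizon in years for the optimal pattern.
#' @param eval_horizons horizons at which Brier/AUC are computed.
#' @param split_fraction training fraction.
#' @param do_lasso run LASSO selection (otherwise all candidates are used).
#' @param eliminate criterion for [backward_eliminate()] (`"AIC"`, `"p"`,
#'   or `NULL` to skip).
#' @param n_boot bootstrap replicates for metric CIs.
#' @param seed integer seed (split, folds, bootstrap).
#' @return list: `split` ids, `lasso`, `model`, `evaluation` (list per
#'   horizon of `brier` and `auc`), `profiles`, `labels`, `association`,
#'   `association_subgroup`, `selected`.
#' @export
run_pipeline <- function(participants, candidates, horizon = 10,
                         eval_horizons = c(5, 10), split_fraction = 0.8,
                         do_lasso = TRUE, eliminate = "AIC", n_boot = 0L,
                         seed = 1L) {
  sp <- split_cohort(participants, split_fraction, seed = seed)
  selected <- candidates
  lasso <- NULL
  if (do_lasso) {
    lasso <- select_covariates_lasso(sp$train, candidates, seed = seed)
    selected <- lasso$selected
  }
  model <- fit_interaction_cox(sp$train, selected)
  if (!is.null(eliminate)) {
    model <- backward_eliminate(model, sp$train, criterion = eliminate)
  }
  evaluation <- lapply(stats::setNames(eval_horizons, paste0("t", eval_horizons)),
    function(t0) {
      ps <- predict_survival(model, sp$test, t = t0)
      list(brier = brier_score(ps, sp$test$time, sp$test$event, t0,
                               n_boot = n_boot, seed = seed),
           auc = time_dependent_auc(1 - ps, sp$test$time, sp$test$event, t0,
                                    n_boot = n_boot, seed = seed))
    })
  profiles <- counterfactual_profile(model, participants, t = horizon)
  labels <- consistency_labels(participants$pattern, profiles$optimal)
  adat <- cbind(participants, labels)
  adjust <- model$covariates
  association <- fit_inconsistency_cox(adat, adjust)
  association_subgroup <- subgroup_analysis(adat, adjust)
  list(split = list(train_ids = sp$train$id, test_ids = sp$test$id),
       lasso = lasso, model = model, evaluation = evaluation,
       profiles = profiles, labels = labels, data = adat,
       association = association,
       association_subgroup = association_subgroup,
       selected = selected, horizon = horizon, seed = seed)
}
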
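#!/usr/bin/env Rscript

# Stage 3 — fit and evaluate the survival base learner.
#
# 80/20 split, LASSO-Cox covariate selection with the PA-pattern dummies
# forced, the interaction Cox model (all pattern-by-covariate second-order
# interactions), backward elimination, and IPCW evaluation (Brier score and
# time-dependent AUC at 5 and 10 years) on the internal test set.

library(paoptim)

seed <- 20240903
cohort <- read_participants_csv("results/cohort.csv")

sp <- split_cohort(cohort, 0.8, seed = seed)
cat("Split: train", nrow(sp$train), "/ test", nrow(sp$test), "\n")

lasso <- select_covariates_lasso(sp$train, names(default_covariates()),
                                 folds = 10, seed = seed)
cat("LASSO (lambda =", signif(lasso$lambda_chosen, 3), ") selected:\n  ",
    paste(lasso$selected, collapse = ", "), "\n")

model <- fit_interaction_cox(sp$train, lasso$selected)
model <- backward_eliminate(model, sp$train, criterion = "AIC")
cat("Backward elimination removed:",
    if (nrow(model$trace)) paste(model$trace$term, collapse = ", ")
    else "(nothing)", "\n")
print(model)
write_model_json(model, "results/model.json")

metrics <- list()
for (t0 in c(5, 10)) {
  ps <- predict_survival(model, sp$test, t = t0)
  b <- brier_score(ps, sp$test$time, sp$test$event, t0, n_boot = 200,
                   seed = seed)
  a <- time_dependent_auc(1 - ps, sp$test$time, sp$test$event, t0,
                          n_boot = 200, seed = seed)
  cat(sprintf("t = %2d y: Brier %.1f%% (%.1f-%.1f), AUC %.1f%% (%.1f-%.1f)\n",
              t0, 100 * b$estimate, 100 * b$ci[1], 100 * b$ci[2],
              100 * a$estimate, 100 * a$ci[1], 100 * a$ci[2]))
  metrics[[paste0("t", t0)]] <- data.frame(
    horizon = t0, brier = b$estimate, brier_lo = b$ci[1], brier_hi = b$ci[2],
    auc = a$estimate, auc_lo = a$ci[1], auc_hi = a$ci[2])
  cal <- calibration_curve(ps, sp$test$time, sp$test$event, t0)
  write.csv(cal, sprintf("results/calibration_%dy.csv", t0),
            row.names = FALSE)
}
write.csv(do.call(rbind, metrics), "results/model_metrics.csv",
          row.names = FALSE)
writeLines(as.character(sp$train$id), "results/train_ids.txt")
writeLines(as.character(sp$test$id), "results/test_ids.txt")
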
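# paoptim — individualized physical-activity patterns for adults with high blood pressure

Physical activity is first-line, non-pharmacological management for high
blood pressure, but the survival benefit of a given weekly activity
*pattern* — weekend warrior, regular, light-activity, or low-activity
baseline — plausibly differs by a person's characteristics. `paoptim`
implements an S-learner pipeline that predicts, for each adult with high
blood pressure, the counterfactual survival under each of the four
accelerometer-derived patterns, recommends the pattern with the highest
predicted survival, characterizes who benefits from what with a
conditional inference tree, and estimates the mortality hazard associated
with *not* following one's predicted optimal pattern. Because the cohorts
such analyses run on are access-restricted, the package ships a
synthetic-cohort generator with known ground truth; every stage is
validated against that truth.

## The model

One Cox model serves as the S-learner's base learner, with the PA pattern
as a covariate and all second-order pattern-by-covariate interactions:

λ(t | x, k) = λ₀(t) · exp(βᵀx + α_k + γ_kᵀ x),   k ∈ {baseline, active_lpa, active_regular, active_ww}

Counterfactual survival comes from toggling only the pattern input,
S(t | x, k) = exp{−H₀(t) e^lp(x,k)} with the Breslow baseline hazard H₀;
the individually optimal pattern is the survival argmax at 10 years, ties
broken toward the lower-MVPA pattern. Model building: 80/20 split,
LASSO-Cox covariate selection (10-fold CV, pattern forced), backward
elimination with interaction-before-main hierarchy, IPCW Brier score and
time-dependent AUC on the test set. Observed-vs-optimal consistency
labels then enter multivariable Cox models (binary and three-level
contrasts, `consistent` as reference).

## Layout

- `R/` — the package: synthetic cohorts (`truth_config`,
  `generate_cohort`, `generate_activity_week`), accelerometry
  (`classify_minutes`, `wear_valid`, `summarize_week`, `classify_pattern`,
  `lpa_dose_response`), cohort building (`classify_bp`, `apply_inclusion`,
  `icc_agreement`, `cohens_kappa`), the survival base learner
  (`select_covariates_lasso`, `fit_interaction_cox`, `backward_eliminate`,
  `predict_survival`, `brier_score`, `time_dependent_auc`), the S-learner
  (`counterfactual_profile`, `consistency_labels`), the conditional
  inference tree (`cit_association_test`, `grow_cit`, `cit_predict`), and
  the association stage (`fit_inconsistency_cox`, `subgroup_analysis`,
  `sensitivity_suite`).
- `analysis/01…06_*.R` — the numbered analysis workflow (simulate →
  classify activity → fit/evaluate → counterfactuals → tree →
  associations), each a thin driver over the package that prints what it
  found and writes tables under `results/`.
- `vignettes/individualized-pa-patterns.Rmd` — the methods vignette:
  model, assumptions, defaults, synthetic-data design, limitations.
- `tests/testthat/` — unit, property and acceptance tests.
- `scripts/acceptance.R` — recomputes the headline quantities from
  scratch (below).

## Worked example

```r
library(paoptim)

cfg <- truth_config(n = 20000, seed = 1)     # default heterogeneous truth
cohort <- generate_cohort(cfg)
out <- run_pipeline(cohort$participants,
                    candidates = names(default_covariates()), seed = 1)

round(100 * prop.table(table(out$profiles$optimal)), 1)
#> baseline  active_lpa  active_regular  active_ww
#>      1.0        39.6            37.3       22.1

out$evaluation$t10$auc$estimate    # 0.750  — 10-year AUC, internal test set
out$evaluation$t10$brier$estimate  # 0.107  — 10-year IPCW Brier

subset(out$association, contrast == "inconsistent_vs_consistent")$hr
#> 1.68   — adjusted mortality HR, observed pattern != predicted optimal
```

Under the default truth roughly 37% of participants are predicted to
benefit most from regular activity, 40% from light activity, 22% from the
weekend-warrior pattern and ~1% from baseline activity; only ~27% already
follow their predicted optimal pattern, and those who do not carry a
substantially elevated adjusted mortality hazard — the qualitative
structure the pipeline is designed to detect. Run the numbered scripts in
`analysis/` for the full narrative, including the dose-response curve
behind the 1900 min/week light-activity threshold and the heterogeneity
tree.

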
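---
title: "Individualized physical-activity patterns for adults with high blood pressure: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized physical-activity patterns: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Guidelines recommend physical activity (PA) to adults with high blood
pressure as a population average, but the survival benefit of a given
weekly activity *pattern* plausibly depends on who you are: a stroke
survivor, an older man, a younger woman with elevated (unmedicated) blood
pressure. `paoptim` implements a pipeline that assigns each person an
individually optimal PA pattern by counterfactual survival prediction, and
then asks whether *not* following one's predicted optimal pattern is
associated with higher mortality.

Weekly accelerometer wear is reduced to one of four mutually exclusive
patterns:

* `active_ww` — "weekend warrior": ≥150 min/week of moderate-to-vigorous
  PA (MVPA) with ≥50% of it accumulated in the two highest-MVPA calendar
  days;
* `active_regular` — ≥150 min/week MVPA spread more evenly;
* `active_lpa` — <150 min/week MVPA but ≥1900 min/week of light PA (LPA);
* `baseline` — <150 MVPA and <1900 LPA min/week (low activity, not
  necessarily sedentary).

All thresholds are inclusive on the printed "≥" side. The 1900 min/week
LPA threshold sits on the plateau of a restricted-cubic-spline Cox
dose-response of LPA on mortality (`lpa_dose_response()`), which the
analysis scripts reproduce on synthetic data.

## The S-learner and its base learner

The method is an S-learner for survival outcomes: a *single* Cox model is
fitted with the PA pattern as an ordinary covariate, together with all
second-order pattern-by-covariate interactions,

$$\lambda(t \mid x, k) = \lambda_0(t)\,
  \exp\big(\beta^\top x + \alpha_k + \gamma_k^\top x\big),$$

where $k$ indexes the pattern (reference: `baseline`) and the
interactions $\gamma_k$ carry all effect heterogeneity. Counterfactual
survival is obtained by toggling only the pattern input:

$$\hat S(t \mid x, k) = \exp\{-\hat H_0(t)\, e^{\hat{lp}(x,k)}\},$$

with $\hat H_0$ the Breslow baseline cumulative hazard. The individually
optimal pattern is the argmax of $\hat S(10\,\text{y} \mid x, k)$ over the
four patterns; ties resolve toward the lower-MVPA pattern
(`baseline` < `active_lpa` < `active_regular` < `active_ww`), the more
conservative recommendation. Each profile retains a *margin* (best minus
second-best survival) so that recommendations resting on a clinically
negligible difference can be flagged; no margin threshold is imposed.

Model building follows the epidemiological convention: an 80/20
train/test split; covariate selection by LASSO-penalized Cox regression
with the pattern dummies forced in unpenalized (the base learner must
always predict under all four patterns), the penalty chosen by 10-fold
cross-validated partial-likelihood deviance at the deviance-minimizing
lambda; then the full interaction model with stepwise backward
elimination. Where the convention leaves choices open we fixed them as
follows:

* **Ties** — Efron approximation (better behaved than Breslow under
  event-time ties; configurable).
* **Lambda rule** — `lambda.min`; the one-standard-error rule is exposed
  as an option.
* **Elimination criterion** — AIC by default, judged per term by its Wald
  chi-square against twice its degrees of freedom (an optional Wald
  p > 0.05 rule is provided). Interaction terms are removable at any time;
  a main effect only after its interaction has gone (hierarchy); the
  pattern dummies never. The elimination trace is kept on the model.
* **Prediction outside training support** — warn, do not refuse; a
  recommendation tool faces open-ended inputs.

Model fit is assessed with the inverse-probability-of-censoring-weighted
(IPCW) Brier score and the cumulative/dynamic time-dependent AUC at 5 and
10 years, both implemented in the package with Kaplan–Meier censoring
weights and validated in the tests against direct-sum $O(n^2)$ oracles to
$10^{-8}$; calibration curves use deciles of predicted risk against
Kaplan–Meier observed risk.

## Consistency labels and the mortality association

A participant is *consistent* when the observed pattern equals the
predicted optimal one. Inconsistent participants split by what the
optimum demanded: `inconsistent_mvpa` when the predicted optimum is
`active_regular` or `active_ww`, `inconsistent_lpa` when it is
`active_lpa` — or `baseline`, a cell the two-way wording leaves open;
we group the low-activity optimum with the LPA-primary side and note that
it affects under ~1% of participants under the default truth.

Multivariable Cox models then estimate hazard ratios for the binary and
three-level contrasts (reference: consistent), adjusted for the
LASSO-selected covariates. The adjustment set deliberately **excludes the
observed pattern itself**: the label is a deterministic function of
pattern and covariates, and conditioning on the pattern would absorb the
contrast of interest. A subgroup analysis refits the three-level model in
the observed nonbaseline group, and a sensitivity harness re-runs the
labeling + Cox stage on an alternate cohort, on cause-specific outcomes
(competing causes censored — cause-specific, not subdistribution,
hazards), on administratively truncated follow-up, and on the internal
test split.

## The heterogeneity tree

Who gets which recommendation is summarized by a conditional inference
tree with the predicted optimal pattern (unordered multinomial) as the
outcome and all covariates as predictors. At each node every predictor is
tested against the outcome with a permutation-framework independence
test: the linear statistic of the covariate transformation (identity for
ordered, indicators for categorical) against the class indicators is
standardized by its conditional mean and covariance, and the quadratic
form is referred to its asymptotic chi-squared distribution with
degrees of freedom equal to the covariance rank (Moore–Penrose inverse);
a seeded Monte-Carlo permutation p-value is available for small nodes.
P-values are Bonferroni-adjusted across the predictors tested and the
node stops when the smallest adjusted p exceeds α. Selection among
extremely strong associations is done on the log-p scale, where double
precision would otherwise underflow to an arbitrary tie. Splitting takes
the cutpoint (observed values; level subsets for categorical predictors)
maximizing the standardized two-sample statistic. Defaults: α = 0.05,
minimum split size 200, minimum child size 20, maximum depth 5 — a
shallow, readable tree; all exposed.

## The synthetic cohort generator

Every stage is validated on cohorts with known truth, generated by
`generate_cohort()` from a `truth_config()`:

* **Covariates** — the 14-variable input space of the model (pattern plus
  age, sex, sedentary time, smoking, antihypertensive medication, cancer,
  diabetes, myocardial infarction, stroke, BP class, waist circumference,
  glucose, HbA1c), with independent marginals chosen to resemble a
  middle-aged-to-older high-BP cohort. The joint distribution of the real
  cohorts is not published; we make no fidelity claim beyond the
  marginals, and the generator treats the covariates as independent.
* **Observed patterns** — a multinomial logit on (centred) covariates;
  default intercepts give shares near 18/18/21/43% with mild confounding
  (men and older adults toward weekend-warrior, women toward light
  activity, stroke away from the MVPA patterns).
* **Event times** — inverse-transform draws from a Weibull
  proportional-hazards model (shape 1.3, scale 48.6 years; ~15–16%
  events by the 12-year administrative horizon), so the truth lies
  exactly in the model family the Cox stage assumes. Censoring is
  min(administrative 12 y, Uniform(2, 40) dropout). Among deaths, causes
  are allocated multinomially (CVD/cancer/other), independent of
  covariates, so every cause-specific hazard is proportional to the
  all-cause one.
* **Heterogeneity** — default interactions make stroke push the optimum
  to low-intensity activity, age erode the benefit of regular activity in
  favour of the weekend-warrior pattern (more so in men), diabetes favour
  light activity, and light activity help most in women with elevated BP.
  Under the defaults the true optimal shares are roughly 1/34/36/29%
  (baseline/light/regular/weekend-warrior), qualitatively matching the
  heterogeneous world the pipeline is meant to recover.
* **Truth object** — the generator returns, per participant, the four
  true linear predictors, the true survival at the 10-year horizon under
  each pattern, and the true optimal pattern (argmax with the same
  tie-break), so downstream argmax recovery can be scored exactly.

The per-minute generator `generate_activity_week()` emits 7×1440-minute
weeks whose classification under the stated cut-points reproduces target
weekly MVPA/LPA minutes exactly, with a requested share of MVPA on the
two weekend days; wear flags can be made to fail either protocol's
validity rule. Sedentary worn minutes carry small nonzero values so the
NHANES zero-run calibration rule is not tripped by construction. What the
generator does *not* emulate: raw 100 Hz waveforms, device noise,
non-proportional-hazards truths, within-person pattern drift over
follow-up. Tests passing on this synthetic world therefore certify the
pipeline's statistical machinery, not the epidemiology of any real
cohort.

Two device dialects are supported: waist counts/min with the adult
cut-points (<100 sedentary, 100–2020 LPA, ≥2020 MVPA) and a wrist
milligravity dialect with user-configurable cut-points (defaults
30/100 mg, common in the wrist literature). The wrist pipeline that this
package's configurable cut-points replace used a machine-learned activity
classifier; no packaged mg thresholds are presented as equivalent to it,
and the cut-point configuration is carried in the returned object so it
can be reported with results. Wear validity: the UKB-style rule needs
≥72 h of wear covering all 24 clock hours (pooled over days); the
NHANES-style rule needs one calendar day with ≥600 worn minutes, after
runs of >60 consecutive worn zero-count minutes are set to nonwear. The
top-2-day share uses calendar days in device-local time (a rolling 48-h
window is a documented alternative the sources leave open); partial
first/last days count toward totals.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen so the full validation suite states something
meaningful at desk scale: parameter recovery and argmax recovery use
cohorts of n = 20,000 with ~15% events (100 replicates for coefficient
coverage); the deviation-world end-to-end check uses n = 20,000 with a
~22% event rate over 100 replicates; tree calibration uses 1,000 null
simulations at n = 500 and 200 null-tree replicates; stroke-root recovery
uses 50 replicates at n = 20,000. Unit tests exercise the same operations
at smaller n. The acceptance script regenerates a default-truth cohort of
n = 20,000, runs the complete pipeline (split, LASSO, interaction Cox,
elimination, evaluation, profiles, labels, tree, association), and
additionally recovers a known 1.30 deviation hazard ratio in a world
where deviating from the true optimum multiplies the hazard by 1.30 —
constructed exactly as pattern main effects plus pattern×BP-class
interactions, so the fitted model family contains the truth.

Numerical choices worth knowing: the Breslow baseline hazard is stored at
zero covariate values and evaluated as a right-continuous step function
with $H_0(0)=0$; survival predictions at $t=0$ are exactly 1; the
censoring Kaplan–Meier is evaluated left-continuously for event weights
($G(T^-)$) and right-continuously at the horizon; IPCW weights are
undefined (error) when the censoring survival hits zero before the
horizon; the CIT cutpoint search respects the minimum child size and
breaks adjusted-p ties by predictor order.

## Known limitations

* The generator's covariates are independent given the assignment model;
  real cohorts have correlated risk factors, so selection behaviour
  (LASSO, elimination) on real data may differ.
* The final interaction model is unregularized; with many selected
  covariates and rare patterns, sparse cells can separate (the fit then
  errors rather than silently returning unstable estimates).
* The inconsistency association is observational by construction — the
  label is derived from the same covariates the Cox model adjusts for,
  and no causal identification is claimed.
* Backward elimination under the AIC rule retains a null interaction with
  roughly 11% probability per term; homogeneity degeneracy is therefore a
  property of the no-interaction model, not a guaranteed endpoint of
  elimination on null data.
* The ICC is fixed to the two-way absolute-agreement single-measure form
  ICC(2,1), and kappa is unweighted; both are stated in the output
  metadata.
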
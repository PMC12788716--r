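# Small truth configurations used across tests: few covariates so Cox fits
# stay fast, event rate near 15% under the 12-year administrative horizon.

tiny_covariates <- function() {
  list(
    age             = list(type = "continuous", mean = 62, sd = 8),
    sex_male        = list(type = "binary", p = 0.48),
    stroke          = list(type = "binary", p = 0.10),
    bp_hypertension = list(type = "binary", p = 0.50),
    diabetes        = list(type = "binary", p = 0.15)
  )
}

tiny_beta_covariate <- function() {
  c(age = 0.06, sex_male = 0.40, stroke = 0.50, bp_hypertension = 0.20,
    diabetes = 0.35)
}

tiny_assignment <- function(confounded = TRUE) {
  covs <- c("(Intercept)", "age", "sex_male", "stroke")
  m <- matrix(0, 4, length(covs), dimnames = list(pa_patterns(), covs))
  m[, "(Intercept)"] <- c(0, 0.3, 0.4, 0.8)
  if (confounded) {
    m["active_ww", "age"] <- 0.02
    m["active_lpa", "sex_male"] <- -0.6
    m[c("active_regular", "active_ww"), "stroke"] <- -1.0
  }
  m
}

tiny_config <- function(n, seed = 1L, interactions = list(),
                        confounded = TRUE,
                        baseline_hazard = list(shape = 1.3, scale = 48.6),
                        ...) {
  truth_config(
    n = n,
    covariates = tiny_covariates(),
    beta_covariate = tiny_beta_covariate(),
    beta_interaction = interactions,
    pattern_assignment = tiny_assignment(confounded),
    baseline_hazard = baseline_hazard,
    seed = seed,
    ...
  )
}

# strong, binary-modifier interaction structure (all |log-HR| >= 0.5)
strong_interactions <- function() {
  list(
    active_lpa     = c(stroke = 0.6, bp_hypertension = 0.9),
    active_regular = c(stroke = 1.2, bp_hypertension = -0.5),
    active_ww      = c(stroke = 1.2, diabetes = 0.8)
  )
}

# independent re-implementation of the four printed pattern rules,
# deliberately written as plain nested conditions (test oracle)
brute_force_pattern <- function(mvpa, lpa, top2) {
  if (mvpa >= 150) {
    if (top2 >= 0.5) "active_ww" else "active_regular"
  } else {
    if (lpa >= 1900) "active_lpa" else "baseline"
  }
}

# brute-force per-participant argmax of the four true Weibull survival
# curves, recomputed from scratch from the config (test oracle)
brute_force_optimal <- function(participants, config) {
  covs <- config$covariates
  shp <- config$baseline_hazard$shape
  scl <- config$baseline_hazard$scale
  out <- character(nrow(participants))
  for (i in seq_len(nrow(participants))) {
    s_best <- -Inf
    k_best <- NA_character_
    for (k in pa_patterns()) {
      lp <- 0
      for (v in names(covs)) {
        x <- participants[[v]][i]
        if (identical(covs[[v]]$type, "continuous")) x <- x - covs[[v]]$mean
        b <- config$beta_covariate[v]
        if (!is.na(b)) lp <- lp + b * x
        g <- config$beta_interaction[[k]][v]
        if (!is.null(g) && !is.na(g)) lp <- lp + g * x
      }
      if (k != "baseline") {
        a <- config$beta_pattern[k]
        if (!is.na(a)) lp <- lp + a
      }
      s <- exp(-(config$horizon / scl)^shp * exp(lp))
      if (s > s_best + 1e-15) {  # strict improvement: first max wins ties
        s_best <- s
        k_best <- k
      }
    }
    out[i] <- k_best
  }
  out
}

# a cox_interaction_model carrying the TRUE generator coefficients and the
# true Weibull baseline hazard; expects newdata with centred continuous
# covariates (see centre_cohort)
true_coef_model <- function(config, t_grid = c(5, 10, 15),
                            interaction_covs = NULL) {
  covs <- names(config$covariates)
  inter_covs <- if (is.null(interaction_covs)) {
    unique(unlist(lapply(config$beta_interaction, names)))
  } else interaction_covs
  beta <- c()
  for (k in pa_patterns()[-1]) {
    beta[paste0("pattern", k)] <-
      if (!is.na(config$beta_pattern[k])) config$beta_pattern[k] else 0
  }
  for (v in covs) {
    b <- config$beta_covariate[v]
    beta[v] <- if (!is.na(b)) b else 0
  }
  for (v in inter_covs) {
    for (k in pa_patterns()[-1]) {
      g <- config$beta_interaction[[k]][v]
      beta[paste0("pattern", k, ":", v)] <- if (!is.null(g) && !is.na(g)) g else 0
    }
  }
  bh <- config$baseline_hazard
  rhs <- c("pattern", covs, paste0("pattern:", inter_covs))
  structure(list(
    formula = paste("~", paste(rhs, collapse = " + ")),
    coef = beta,
    vcov = NULL,
    basehaz = data.frame(time = t_grid,
                         hazard = (t_grid / bh$scale)^bh$shape),
    xlevels = list(pattern = pa_patterns()),
    ranges = list(),
    ties = "exact-truth",
    covariates = covs,
    interactions = inter_covs,
    fit = NULL
  ), class = "cox_interaction_model")
}

# a synthetic world in which deviating from the true optimal pattern
# multiplies the hazard by a known factor. The optimum is active_regular
# for elevated BP and active_lpa for hypertension; the penalty for
# deviating is `penalty_mvpa` when the optimum is the MVPA-demanding
# regular pattern and `penalty_lpa` when it is the LPA-primary pattern.
# This hazard is exactly representable by pattern main effects plus
# pattern x bp_hypertension interactions.
deviation_world <- function(n, penalty_mvpa = 1.30, penalty_lpa = 1.30,
                            seed = 1L) {
  c1 <- log(penalty_mvpa)
  c2 <- log(penalty_lpa)
  bc <- tiny_beta_covariate()
  bc["bp_hypertension"] <- bc["bp_hypertension"] + (c2 - c1)
  truth_config(
    n = n,
    covariates = tiny_covariates(),
    beta_pattern = c(active_lpa = 0, active_regular = -c1, active_ww = 0),
    beta_covariate = bc,
    beta_interaction = list(active_lpa = c(bp_hypertension = -c2),
                            active_regular = c(bp_hypertension = c1)),
    pattern_assignment = tiny_assignment(TRUE),
    baseline_hazard = list(shape = 1.3, scale = 31),
    seed = seed
  )
}

# fit -> S-learner -> labels -> inconsistency Cox, on one generated cohort
run_deviation_pipeline <- function(cfg, eliminate = TRUE) {
  ch <- generate_cohort(cfg)
  p <- ch$participants
  covs <- names(cfg$covariates)
  m <- fit_interaction_cox(p, covs)
  if (eliminate) m <- backward_eliminate(m, p, criterion = "AIC")
  pr <- counterfactual_profile(m, p, t = cfg$horizon)
  lab <- consistency_labels(p$pattern, pr$optimal)
  res <- fit_inconsistency_cox(cbind(p, lab), adjust = covs)
  list(cohort = ch, model = m, profiles = pr, labels = lab, result = res)
}

centre_cohort <- function(participants, config) {
  for (v in names(config$covariates)) {
    cv <- config$covariates[[v]]
    if (identical(cv$type, "continuous")) {
      participants[[v]] <- participants[[v]] - cv$mean
    }
  }
  participants
}
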
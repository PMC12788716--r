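#' Specify the data-generating truth for a synthetic high-blood-pressure cohort
#'
#' A `truth_config` fully determines a synthetic cohort: covariate
#' distributions, the (possibly confounded) assignment of observed PA
#' patterns, a Weibull proportional-hazards mortality model with PA-pattern
#' main effects and pattern-by-covariate interactions, and independent
#' right-censoring. Everything downstream (the Cox base learner, the
#' S-learner argmax, the inconsistency Cox models) can then be validated
#' against the known truth.
#'
#' The log-hazard for participant i observed under pattern k is
#' \deqn{lp_i(k) = \sum_j \beta_j z_{ij} + \alpha_k + \sum_j \gamma_{kj} z_{ij}}
#' with `baseline` the reference pattern (\eqn{\alpha_{baseline} = 0}),
#' where continuous covariates enter centred at their specified mean
#' (centring only reparameterizes the model; predictions and the survival
#' argmax are unchanged). Event times follow
#' \eqn{S(t \mid lp) = \exp\{-(t/\lambda)^{\kappa} e^{lp}\}} (Weibull shape
#' \eqn{\kappa}, scale \eqn{\lambda}, time in years), drawn by inverse
#' transform so the truth is exactly proportional hazards — the model family
#' the downstream Cox fit assumes. Censoring is the minimum of an
#' administrative horizon and a uniform dropout time.
#'
#' @param n number of participants.
#' @param covariates named list describing each covariate:
#'   `list(type = "binary", p = prevalence)` or
#'   `list(type = "continuous", mean =, sd =)`.
#' @param beta_pattern named numeric: log-hazard main effect of each
#'   non-reference pattern (`active_lpa`, `active_regular`, `active_ww`)
#'   relative to `baseline`.
#' @param beta_covariate named numeric log-hazard effects per covariate
#'   (per unit for binaries, per unit of the centred value for continuous).
#' @param beta_interaction named list mapping a non-reference pattern to a
#'   named numeric vector of pattern-by-covariate interaction log-hazards,
#'   e.g. `list(active_ww = c(stroke = 0.9))`. Missing entries are 0.
#' @param pattern_assignment matrix (4 x (1 + n_covariates)) of multinomial
#'   logit coefficients (column `"(Intercept)"` plus covariate columns;
#'   missing columns are 0) mapping covariates to observed-pattern
#'   probabilities. Row order must be `pa_patterns()`. The default mixes
#'   realistic marginal shares with mild confounding.
#' @param baseline_hazard `list(shape =, scale =)` of the Weibull baseline
#'   (time unit: years).
#' @param censoring `list(admin =, dropout = c(lo, hi))`; `dropout = NULL`
#'   disables random dropout. `admin = Inf` disables administrative
#'   censoring.
#' @param cause_split named numeric summing to 1; among deaths, causes are
#'   allocated multinomially with these probabilities (independent of
#'   covariates, so every cause-specific hazard is proportional to the
#'   all-cause hazard).
#' @param horizon evaluation horizon in years for the true optimal pattern.
#' @param seed integer seed.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(n,
                         covariates = default_covariates(),
                         beta_pattern = c(active_lpa = -1.30,
                                          active_regular = -0.74,
                                          active_ww = -0.62),
                         beta_covariate = default_beta_covariate(),
                         beta_interaction = default_beta_interaction(),
                         pattern_assignment = default_pattern_assignment(),
                         baseline_hazard = list(shape = 1.3, scale = 48.6),
                         censoring = list(admin = 12, dropout = c(2, 40)),
                         cause_split = c(cvd = 0.35, cancer = 0.40, other = 0.25),
                         horizon = 10,
                         seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (identical(cv$type, "binary")) {
      if (cv$p < 0 || cv$p > 1) stop("prevalence outside [0,1] for ", nm)
    } else if (identical(cv$type, "continuous")) {
      if (cv$sd < 0) stop("negative sd for ", nm)
    } else stop("covariate type must be 'binary' or 'continuous': ", nm)
  }
  if (baseline_hazard$shape <= 0 || baseline_hazard$scale <= 0) {
    stop("Weibull shape and scale must be positive")
  }
  bad_b <- setdiff(names(beta_covariate), names(covariates))
  if (length(bad_b)) stop("beta_covariate names not in covariates: ",
                          paste(bad_b, collapse = ", "))
  if (!all(names(beta_pattern) %in% pa_patterns()[-1])) {
    stop("beta_pattern must be named by non-reference patterns")
  }
  for (k in names(beta_interaction)) {
    if (!k %in% pa_patterns()[-1]) stop("interaction pattern unknown: ", k)
    bad <- setdiff(names(beta_interaction[[k]]), names(covariates))
    if (length(bad)) stop("interaction covariate unknown: ",
                          paste(bad, collapse = ", "))
  }
  if (abs(sum(cause_split) - 1) > 1e-8) stop("cause_split must sum to 1")
  bad_pa <- setdiff(colnames(pattern_assignment),
                    c("(Intercept)", names(covariates)))
  if (length(bad_pa)) {
    stop("pattern_assignment columns not in covariates: ",
         paste(bad_pa, collapse = ", "))
  }
  cfg <- list(n = n, covariates = covariates, beta_pattern = beta_pattern,
              beta_covariate = beta_covariate,
              beta_interaction = beta_interaction,
              pattern_assignment = pattern_assignment,
              baseline_hazard = baseline_hazard, censoring = censoring,
              cause_split = cause_split, horizon = horizon,
              seed = as.integer(seed))
  class(cfg) <- "truth_config"
  cfg
}

#' @rdname truth_config
#' @details `default_covariates()` returns the 14-variable input space of the
#'   prediction model (observed PA pattern plus the 13 covariates below),
#'   with marginals chosen to resemble a middle-aged to older high-BP cohort:
#'   age (years), male sex, daily sedentary time (min/day), current smoking,
#'   antihypertensive medication, cancer, diabetes, myocardial infarction,
#'   stroke, hypertension (vs elevated BP), waist circumference (cm),
#'   glucose (mmol/L) and HbA1c (mmol/mol).
#' @export
default_covariates <- function() {
  list(
    age              = list(type = "continuous", mean = 62,  sd = 8),
    sex_male         = list(type = "binary", p = 0.48),
    sedentary_min_day = list(type = "continuous", mean = 550, sd = 90),
    smoking_current  = list(type = "binary", p = 0.09),
    antihyper_med    = list(type = "binary", p = 0.25),
    cancer           = list(type = "binary", p = 0.08),
    diabetes         = list(type = "binary", p = 0.06),
    mi               = list(type = "binary", p = 0.03),
    stroke           = list(type = "binary", p = 0.02),
    bp_hypertension  = list(type = "binary", p = 0.60),
    waist_cm         = list(type = "continuous", mean = 90,  sd = 12),
    glucose          = list(type = "continuous", mean = 5.0, sd = 0.8),
    hba1c            = list(type = "continuous", mean = 35.3, sd = 4.0)
  )
}

#' @rdname truth_config
#' @export
default_beta_covariate <- function() {
  c(age = 0.07, sex_male = 0.45, sedentary_min_day = 0.001,
    smoking_current = 0.60, antihyper_med = 0.25, cancer = 0.60,
    diabetes = 0.40, mi = 0.45, stroke = 0.50, bp_hypertension = 0.20,
    waist_cm = 0.010, glucose = 0.08, hba1c = 0.02)
}

#' @rdname truth_config
#' @details `default_beta_interaction()` encodes the default heterogeneity
#'   structure: stroke strongly penalizes the MVPA-demanding patterns
#'   (optimum shifts to light activity or the low-activity baseline),
#'   increasing age erodes the benefit of regular activity while favouring
#'   the weekend-warrior pattern (slightly more so in men), diabetes
#'   favours light activity, and light activity helps most in women with
#'   elevated (rather than medicated/hypertensive) blood pressure. Under
#'   the default main effects this yields true-optimal shares of roughly
#'   1/34/36/29% (baseline / light / regular / weekend warrior).
#' @export
default_beta_interaction <- function() {
  list(
    active_lpa     = c(stroke = 0.5, sex_male = 0.45, bp_hypertension = 0.75,
                       diabetes = -0.30, age = -0.004),
    active_regular = c(stroke = 1.0, age = 0.028, diabetes = 0.50),
    active_ww      = c(stroke = 1.0, age = -0.006, sex_male = -0.15,
                       diabetes = 0.50, antihyper_med = -0.10)
  )
}

#' @rdname truth_config
#' @export
default_pattern_assignment <- function() {
  # intercepts reproduce observed-pattern shares near 18/18/21/43%,
  # with mild confounding: men and older adults toward weekend-warrior,
  # women toward light activity, stroke away from the MVPA patterns
  covs <- c("(Intercept)", "age", "sex_male", "stroke", "antihyper_med")
  m <- matrix(0, nrow = 4, ncol = length(covs),
              dimnames = list(pa_patterns(), covs))
  m[, "(Intercept)"] <- c(0, 0.40, 0.18, 0.90)
  m["active_lpa", "sex_male"] <- -0.8
  m["active_ww", "sex_male"] <- 0.3
  m["active_ww", "age"] <- 0.02        # per year, centred
  m[c("active_regular", "active_ww"), "stroke"] <- -1.5
  m["active_ww", "antihyper_med"] <- 0.2
  m
}

# centred covariate matrix used in every linear predictor
centred_covariates <- function(df, covariates) {
  z <- as.matrix(df[, names(covariates), drop = FALSE])
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (identical(cv$type, "continuous")) z[, nm] <- z[, nm] - cv$mean
  }
  z
}

# n x 4 matrix of true linear predictors (one column per pattern)
true_lp_matrix <- function(df, config) {
  z <- centred_covariates(df, config$covariates)
  base <- drop(z %*% ifelse(is.na(config$beta_covariate[colnames(z)]), 0,
                            config$beta_covariate[colnames(z)]))
  lp <- matrix(base, nrow = nrow(z), ncol = 4,
               dimnames = list(NULL, pa_patterns()))
  for (k in pa_patterns()[-1]) {
    lp[, k] <- lp[, k] + ifelse(is.na(config$beta_pattern[k]), 0,
                                config$beta_pattern[k])
    gam <- config$beta_interaction[[k]]
    if (length(gam)) lp[, k] <- lp[, k] + drop(z[, names(gam), drop = FALSE] %*% gam)
  }
  lp
}

# Weibull PH survival and inverse transform
weibull_ph_surv <- function(t, shape, scale, lp) {
  exp(-(t / scale)^shape * exp(lp))
}

#' Draw event times from a Weibull proportional-hazards model
#'
#' Inverse-transform sampling from
#' \eqn{S(t) = \exp\{-(t/\lambda)^\kappa e^{lp}\}}.
#'
#' @param u uniform(0,1) draws (one per subject).
#' @param shape,scale Weibull parameters.
#' @param lp linear predictor vector.
#' @return Event times in the scale's time unit.
#' @export
rweibull_ph <- function(u, shape, scale, lp) {
  scale * (-log(u) / exp(lp))^(1 / shape)
}

#' Generate a synthetic cohort with known truth
#'
#' Draws covariates, observed PA patterns, Weibull proportional-hazards
#' event times and independent censoring according to a [truth_config()],
#' and returns both the participant table and the generating truth (the
#' four true linear predictors, the true survival at the evaluation horizon
#' under each pattern, and the true optimal pattern — the survival argmax
#' with ties broken toward the lower-MVPA pattern). Output is reproducible
#' bit-for-bit from `config` (the config's seed is used unless `seed`
#' overrides it).
#'
#' @param config a [truth_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return A list of class `synthetic_cohort` with elements
#'   `participants` (data.frame: `id`, covariates, `pattern`, `time`,
#'   `event`, `cause`, and the bookkeeping flags `calibration_ok`,
#'   `wear_ok` used by [apply_inclusion()]), `truth` (data.frame: `id`,
#'   `lp_<pattern>`, `surv_<pattern>`, `true_optimal`) and `config`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n

  df <- data.frame(id = seq_len(n))
  for (nm in names(config$covariates)) {
    cv <- config$covariates[[nm]]
    df[[nm]] <- if (identical(cv$type, "binary")) {
      rbinom(n, 1L, cv$p)
    } else {
      rnorm(n, cv$mean, cv$sd)
    }
  }

  # observed pattern via multinomial logit on centred covariates
  z <- centred_covariates(df, config$covariates)
  pa <- config$pattern_assignment
  xcols <- setdiff(colnames(pa), "(Intercept)")
  eta <- matrix(rep(pa[, "(Intercept)"], each = n), nrow = n)
  if (length(xcols)) {
    eta <- eta + z[, xcols, drop = FALSE] %*% t(pa[, xcols, drop = FALSE])
  }
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  cum <- t(apply(pr, 1, cumsum))
  u_pat <- runif(n)
  pat_idx <- rowSums(u_pat > cum) + 1L
  df$pattern <- pa_pattern_factor(pa_patterns()[pat_idx])

  # true linear predictors and event times under the observed pattern
  lp <- true_lp_matrix(df, config)
  lp_obs <- lp[cbind(seq_len(n), pat_idx)]
  bh <- config$baseline_hazard
  t_event <- rweibull_ph(runif(n), bh$shape, bh$scale, lp_obs)

  cens <- rep(config$censoring$admin %||% Inf, n)
  dw <- config$censoring$dropout
  if (!is.null(dw)) cens <- pmin(cens, runif(n, dw[1], dw[2]))
  df$time <- pmin(t_event, cens)
  df$event <- as.integer(t_event <= cens)
  df$cause <- NA_character_
  deaths <- which(df$event == 1L)
  if (length(deaths)) {
    df$cause[deaths] <- sample(names(config$cause_split), length(deaths),
                               replace = TRUE, prob = config$cause_split)
  }
  df$calibration_ok <- TRUE
  df$wear_ok <- TRUE

  sv <- weibull_ph_surv(config$horizon, bh$shape, bh$scale, lp)
  truth <- data.frame(id = df$id)
  for (k in pa_patterns()) truth[[paste0("lp_", k)]] <- lp[, k]
  for (k in pa_patterns()) truth[[paste0("surv_", k)]] <- sv[, k]
  truth$true_optimal <- pattern_argmax(sv)

  structure(list(participants = df, truth = truth, config = config),
            class = "synthetic_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$participants
  cat("synthetic high-BP cohort: n =", nrow(p),
      "| events =", sum(p$event),
      sprintf("(%.1f%%)", 100 * mean(p$event)), "\n")
  cat("observed patterns:",
      paste(sprintf("%s %.1f%%", levels(p$pattern),
                    100 * prop.table(table(p$pattern))), collapse = ", "), "\n")
  cat("true optimal:",
      paste(sprintf("%s %.1f%%", pa_patterns(),
                    100 * prop.table(table(x$truth$true_optimal))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Inject exclusion conditions into a synthetic participant table
#'
#' Flags a random subset of rows as failing device calibration or wear-time
#' requirements, and blanks covariate values in another subset, so the
#' inclusion/exclusion ledger of [apply_inclusion()] can be exercised on
#' synthetic data.
#'
#' @param participants participant data.frame from [generate_cohort()].
#' @param frac_bad_calibration,frac_short_wear,frac_missing fractions of rows
#'   to degrade (disjoint sets, drawn in this order).
#' @param missing_cols covariate columns eligible for blanking.
#' @param seed integer seed.
#' @return The participant table with degraded rows.
#' @export
inject_exclusions <- function(participants, frac_bad_calibration = 0.02,
                              frac_short_wear = 0.05, frac_missing = 0.03,
                              missing_cols = c("hba1c", "glucose", "waist_cm"),
                              seed = 1L) {
  set.seed(as.integer(seed))
  missing_cols <- intersect(missing_cols, names(participants))
  if (!length(missing_cols)) {
    missing_cols <- setdiff(names(participants),
                            c("id", "pattern", "time", "event", "cause",
                              "calibration_ok", "wear_ok"))
  }
  n <- nrow(participants)
  pool <- sample.int(n)
  take <- function(k) {
    k <- min(k, length(pool))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  bad_cal <- take(round(frac_bad_calibration * n))
  short_wear <- take(round(frac_short_wear * n))
  missing <- take(round(frac_missing * n))
  participants$calibration_ok[bad_cal] <- FALSE
  participants$wear_ok[short_wear] <- FALSE
  for (i in missing) {
    participants[i, sample(missing_cols, 1L)] <- NA
  }
  participants
}
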
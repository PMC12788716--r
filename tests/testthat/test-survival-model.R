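test_that("cohort splitting is disjoint, exhaustive and reproducible", {
  d <- data.frame(id = 1:10, x = rnorm(10))
  sp <- split_cohort(d, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), d$id)
  sp2 <- split_cohort(d, 0.8, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_cohort(d[1, , drop = FALSE], 0.5), "too small")
  # conservation on random sizes
  for (n in c(13, 57, 101)) {
    dd <- data.frame(id = seq_len(n))
    s <- split_cohort(dd, 0.8, seed = n)
    expect_setequal(c(s$train$id, s$test$id), dd$id)
  }
})

test_that("LASSO limits: full shrinkage keeps only forced terms, none keeps all", {
  cfg <- tiny_config(1500, seed = 2)
  p <- generate_cohort(cfg)$participants
  cand <- names(tiny_covariates())
  hi <- select_covariates_lasso(p, cand, seed = 1, lambda_fixed = 1e3)
  expect_length(hi$selected, 0)
  lo <- select_covariates_lasso(p, cand, seed = 1, lambda_fixed = 0)
  expect_setequal(lo$selected, cand)  # unpenalized support: all informative here
})

test_that("LASSO selection recovers the active covariate support", {
  # 3 active + 7 null candidates
  covs <- c(
    setNames(lapply(1:3, function(i) list(type = "binary", p = 0.4)),
             paste0("a", 1:3)),
    setNames(lapply(1:7, function(i) list(type = "continuous", mean = 0, sd = 1)),
             paste0("z", 1:7))
  )
  beta <- c(a1 = 0.8, a2 = -0.8, a3 = 0.8,
            setNames(rep(0, 7), paste0("z", 1:7)))
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- truth_config(
      n = 2000, covariates = covs, beta_covariate = beta,
      beta_interaction = list(),
      pattern_assignment = matrix(c(0, 0, 0, 0), 4, 1,
                                  dimnames = list(pa_patterns(), "(Intercept)")),
      seed = 100 + r
    )
    p <- generate_cohort(cfg)$participants
    sel <- select_covariates_lasso(p, names(covs), seed = r)$selected
    if (all(paste0("a", 1:3) %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("interaction Cox recovers truth coefficients within 3 SE", {
  cfg <- tiny_config(10000, seed = 31, interactions = strong_interactions())
  ch <- generate_cohort(cfg)
  # centring continuous covariates by the generator means aligns the fitted
  # parameterization with the truth betas
  p <- centre_cohort(ch$participants, cfg)
  m <- fit_interaction_cox(p, names(tiny_covariates()))
  truth <- true_coef_model(cfg, interaction_covs = names(tiny_covariates()))$coef
  common <- intersect(names(m$coef), names(truth))
  expect_equal(length(common), length(m$coef))
  se <- sqrt(diag(m$vcov))[common]
  frac_ok <- mean(abs(m$coef[common] - truth[common]) <= 3 * se)
  expect_gte(frac_ok, 0.95)
})

test_that("duplicating every row leaves the partial-likelihood estimate unchanged", {
  cfg <- tiny_config(800, seed = 17)
  p <- generate_cohort(cfg)$participants
  # Breslow ties: duplication doubles the log partial likelihood exactly
  # (Efron treats the duplication-induced ties differently by construction)
  m1 <- fit_interaction_cox(p, c("age", "sex_male"), ties = "breslow")
  m2 <- fit_interaction_cox(rbind(p, p), c("age", "sex_male"),
                            ties = "breslow")
  expect_equal(m1$coef, m2$coef, tolerance = 1e-6)
})

test_that("fitting refuses when events are fewer than model terms", {
  cfg <- tiny_config(300, seed = 5)
  p <- generate_cohort(cfg)$participants
  p$event[-(1:3)] <- 0
  expect_error(fit_interaction_cox(p, names(tiny_covariates())), "fewer events")
})

test_that("null coefficients reject at roughly the nominal 5% rate", {
  # all-null truth: z-statistics of covariate effects ~ N(0,1)
  rej <- 0L; tot <- 0L
  for (r in 1:10) {
    cfg <- truth_config(
      n = 1200,
      covariates = list(x1 = list(type = "binary", p = 0.5),
                        x2 = list(type = "continuous", mean = 0, sd = 1)),
      beta_pattern = c(active_lpa = 0, active_regular = 0, active_ww = 0),
      beta_covariate = c(x1 = 0, x2 = 0),
      beta_interaction = list(),
      pattern_assignment = matrix(0, 4, 1,
                                  dimnames = list(pa_patterns(), "(Intercept)")),
      seed = 500 + r
    )
    p <- generate_cohort(cfg)$participants
    m <- fit_interaction_cox(p, c("x1", "x2"), interactions = character(0))
    z <- m$coef / sqrt(diag(m$vcov))
    rej <- rej + sum(abs(z) > 1.96)
    tot <- tot + length(z)
  }
  expect_lt(abs(rej / tot - 0.05), 0.06)
})

test_that("backward elimination keeps real interactions, drops null ones, respects hierarchy", {
  real_kept <- 0L
  null_dropped <- 0L
  null_total <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    cfg <- tiny_config(4000, seed = 700 + r,
                       interactions = list(active_regular = c(stroke = 1.2),
                                           active_ww = c(stroke = 1.2)))
    p <- generate_cohort(cfg)$participants
    m <- fit_interaction_cox(p, names(tiny_covariates()))
    m2 <- backward_eliminate(m, p, criterion = "AIC")
    if ("stroke" %in% m2$interactions) real_kept <- real_kept + 1L
    nulls <- setdiff(names(tiny_covariates()), "stroke")
    null_total <- null_total + length(nulls)
    null_dropped <- null_dropped + sum(!nulls %in% m2$interactions)
    # hierarchy: no main effect removed while its interaction was still present
    tr <- m2$trace$term
    for (v in names(tiny_covariates())) {
      i_main <- match(v, tr)
      i_int <- match(paste0("pattern:", v), tr)
      if (!is.na(i_main) && !is.na(i_int)) expect_lt(i_int, i_main)
      if (!is.na(i_main)) expect_false(v %in% m2$covariates)
    }
  }
  expect_gte(real_kept / n_rep, 0.8)
  expect_gte(null_dropped / null_total, 0.7)
})

test_that("an already minimal model is a fixed point of elimination", {
  cfg <- tiny_config(3000, seed = 77,
                     interactions = list(active_regular = c(stroke = 1.5),
                                         active_ww = c(stroke = 1.5)))
  p <- generate_cohort(cfg)$participants
  m <- fit_interaction_cox(p, c("age", "stroke"), interactions = "stroke")
  m1 <- backward_eliminate(m, p, criterion = "AIC")
  m2 <- backward_eliminate(m1, p, criterion = "AIC")
  expect_identical(m1$covariates, m2$covariates)
  expect_identical(m1$interactions, m2$interactions)
  expect_equal(m1$coef, m2$coef)
  expect_equal(nrow(m2$trace), 0)
})

test_that("survival predictions: boundary values, baseline identity, monotonicity", {
  cfg <- tiny_config(2000, seed = 41)
  p <- generate_cohort(cfg)$participants
  m <- fit_interaction_cox(p, c("age", "stroke", "sex_male"))
  expect_equal(predict_survival(m, p[1:4, ], t = 0), rep(1, 4))
  # zero-covariate, reference-pattern subject has lp = 0: S = exp(-H0)
  base <- p[1, ]
  base$age <- 0; base$stroke <- 0; base$sex_male <- 0
  base$pattern <- "baseline"
  s10 <- suppressWarnings(predict_survival(m, base, t = 10))
  H10 <- stats::stepfun(m$basehaz$time, c(0, m$basehaz$hazard))(10)
  expect_equal(unname(s10), exp(-H10), tolerance = 1e-12)
  # monotone non-increasing in t
  ts <- seq(0, 12, by = 0.5)
  for (i in c(2, 10, 30)) {
    s <- predict_survival(m, p[i, ], t = ts)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  # out-of-support covariate warns but predicts
  far <- p[1, ]
  far$age <- 200
  expect_warning(predict_survival(m, far, t = 5), "outside training support")
})

test_that("predicted 10-year survival tracks the Weibull truth closely at scale", {
  cfg <- tiny_config(20000, seed = 51, interactions = strong_interactions())
  ch <- generate_cohort(cfg)
  p <- ch$participants
  m <- fit_interaction_cox(p, names(tiny_covariates()))
  ps <- predict_survival(m, p, t = 10)
  true_s <- vapply(seq_len(nrow(p)), function(i) {
    ch$truth[[paste0("surv_", as.character(p$pattern[i]))]][i]
  }, numeric(1))
  expect_lt(mean(abs(ps - true_s)), 0.02)
})

test_that("univariate Cox recovers a simulated binary-exposure hazard ratio", {
  set.seed(8)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  h <- 1.6
  t_ev <- rweibull_ph(runif(n), 1.3, 40, log(h) * x)
  cens <- runif(n, 2, 30)
  d <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
                  x = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
  expect_lt(abs(coef(fit) - log(h)), 3 * sqrt(vcov(fit)[1, 1]))
})

test_that("model JSON round trip preserves predictions", {
  cfg <- tiny_config(1500, seed = 61)
  p <- generate_cohort(cfg)$participants
  m <- fit_interaction_cox(p, c("age", "stroke"))
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  expect_equal(predict_survival(m2, p[1:20, ], t = c(5)),
               predict_survival(m, p[1:20, ], t = c(5)), tolerance = 1e-10)
  pr <- counterfactual_profile(m2, p[1:20, ], t = 10)
  pr1 <- counterfactual_profile(m, p[1:20, ], t = 10)
  expect_identical(as.character(pr$optimal), as.character(pr1$optimal))
  unlink(f)
})
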
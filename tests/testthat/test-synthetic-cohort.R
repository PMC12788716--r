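test_that("generation is deterministic given config + seed", {
  cfg <- tiny_config(500, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$participants$time, c2$participants$time))
})

test_that("covariate marginals match the configured distributions within 3 SE", {
  cfg <- truth_config(n = 10000, seed = 7)
  p <- generate_cohort(cfg)$participants
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    if (cv$type == "binary") {
      se <- sqrt(cv$p * (1 - cv$p) / cfg$n)
      expect_lt(abs(mean(p[[nm]]) - cv$p), 3 * se + 1e-12)
    } else {
      se <- cv$sd / sqrt(cfg$n)
      expect_lt(abs(mean(p[[nm]]) - cv$mean), 3 * se)
    }
  }
  expect_true(all(table(p$pattern) > 0))
})

test_that("null model survival at the Weibull median is 1/2", {
  cfg <- truth_config(
    n = 50000,
    covariates = list(x = list(type = "binary", p = 0.5)),
    beta_pattern = c(active_lpa = 0, active_regular = 0, active_ww = 0),
    beta_covariate = c(x = 0),
    beta_interaction = list(),
    pattern_assignment = matrix(0, 4, 1,
                                dimnames = list(pa_patterns(), "(Intercept)")),
    censoring = list(admin = Inf, dropout = NULL),
    seed = 5
  )
  ch <- generate_cohort(cfg)
  med <- cfg$baseline_hazard$scale * log(2)^(1 / cfg$baseline_hazard$shape)
  expect_lt(abs(mean(ch$participants$time > med) - 0.5), 0.01)
  expect_true(all(ch$participants$event == 1))
})

test_that("zero interactions force a single true optimal pattern", {
  cfg <- tiny_config(2000, seed = 3, interactions = list())
  ch <- generate_cohort(cfg)
  opt <- unique(as.character(ch$truth$true_optimal))
  expect_length(opt, 1)
  # the pattern with the most negative main effect
  expect_identical(opt, names(which.min(cfg$beta_pattern)))
})

test_that("a strong stroke penalty on MVPA patterns moves the stroke optimum to low-intensity", {
  cfg <- tiny_config(4000, seed = 9,
                     interactions = list(active_regular = c(stroke = 2),
                                         active_ww = c(stroke = 2)))
  ch <- generate_cohort(cfg)
  stroke_opt <- ch$truth$true_optimal[ch$participants$stroke == 1]
  expect_true(all(stroke_opt %in% c("baseline", "active_lpa")))
})

test_that("SimTruth optimal equals the brute-force argmax of the four survival curves", {
  cfg <- tiny_config(800, seed = 11, interactions = strong_interactions())
  ch <- generate_cohort(cfg)
  oracle <- brute_force_optimal(ch$participants, cfg)
  expect_identical(as.character(ch$truth$true_optimal), oracle)
})

test_that("event times follow the Weibull PH model for the observed pattern", {
  # empirical uncensored survival matches the analytic curve at the truth lp
  cfg <- tiny_config(30000, seed = 13, interactions = strong_interactions(),
                     censoring = list(admin = Inf, dropout = NULL))
  ch <- generate_cohort(cfg)
  p <- ch$participants
  lp_obs <- mapply(function(i, k) ch$truth[[paste0("lp_", k)]][i],
                   seq_len(500), as.character(p$pattern[seq_len(500)]))
  bh <- cfg$baseline_hazard
  s10 <- exp(-(10 / bh$scale)^bh$shape * exp(lp_obs))
  # grouped check: among subjects with similar lp, empirical P(T>10) ~ S(10)
  expect_equal(mean(p$time[seq_len(500)] > 10), mean(s10), tolerance = 0.06)
})

test_that("degenerate configurations are rejected", {
  expect_error(truth_config(0), "positive")
  expect_error(tiny_config(10, baseline_hazard = list(shape = -1, scale = 2)),
               "positive")
  expect_error(truth_config(
    10, covariates = list(x = list(type = "binary", p = 1.2))), "prevalence")
  expect_error(truth_config(
    10, covariates = list(x = list(type = "continuous", mean = 0, sd = -1))),
    "negative sd")
})

test_that("exclusion injection degrades the requested fractions", {
  cfg <- tiny_config(1000, seed = 21)
  p <- generate_cohort(cfg)$participants
  p2 <- inject_exclusions(p, 0.02, 0.05, 0.03, seed = 2)
  expect_equal(sum(!p2$calibration_ok), 20)
  expect_equal(sum(!p2$wear_ok), 50)
  covs <- setdiff(names(p2), "cause")  # cause is NA for survivors by design
  expect_equal(sum(rowSums(is.na(p2[covs])) > 0), 30)
})

test_that("participant CSV and config files round-trip", {
  cfg <- tiny_config(120, seed = 71)
  p <- generate_cohort(cfg)$participants
  f <- tempfile(fileext = ".csv")
  write_participants_csv(p, f)
  p2 <- read_participants_csv(f)
  expect_equal(p2$time, p$time, tolerance = 1e-9)
  expect_identical(as.character(p2$pattern), as.character(p$pattern))
  unlink(f)

  # JSON truth config reproduces the same cohort
  cj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    n = 120, seed = 71,
    covariates = lapply(tiny_covariates(), as.list),
    beta_pattern = as.list(cfg$beta_pattern),
    beta_covariate = as.list(tiny_beta_covariate()),
    pattern_assignment = list(
      active_lpa = list(intercept = 0.3, sex_male = -0.6),
      active_regular = list(intercept = 0.4, stroke = -1.0),
      active_ww = list(intercept = 0.8, age = 0.02, stroke = -1.0)
    ),
    baseline_hazard = list(shape = 1.3, scale = 48.6),
    censoring = list(admin = 12, dropout = c(2, 40)),
    horizon = 10
  ), cj, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_truth_config(cj)
  # assignment differs slightly in intercept layout from tiny_assignment;
  # check the config machinery itself is faithful
  expect_equal(cfg2$beta_pattern, cfg$beta_pattern)
  expect_equal(cfg2$covariates$age$mean, 62)
  ch <- generate_cohort(cfg2)
  expect_equal(nrow(ch$participants), 120)
  expect_true(is.numeric(ch$participants$time))
  unlink(cj)

  # YAML config (if available) parses equivalently
  if (requireNamespace("yaml", quietly = TRUE)) {
    cy <- tempfile(fileext = ".yaml")
    yaml::write_yaml(list(
      n = 50, seed = 3,
      covariates = lapply(tiny_covariates(), as.list),
      beta_covariate = as.list(tiny_beta_covariate())
    ), cy)
    cfg3 <- read_truth_config(cy)
    expect_equal(cfg3$n, 50L)
    unlink(cy)
  }
})
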
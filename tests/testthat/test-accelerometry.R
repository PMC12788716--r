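make_week <- function(values, wear = TRUE) {
  n <- length(values)
  data.frame(
    participant_id = 1L,
    timestamp = as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
      60 * (seq_len(n) - 1L),
    value = values,
    wear = rep_len(wear, n)
  )
}

test_that("minute classification respects the printed count thresholds", {
  cp <- pa_cutpoints("nhanes")
  wk <- make_week(c(0, 99, 100, 2019, 2020, 5000))
  lab <- classify_minutes(wk, cp)
  expect_equal(as.character(lab),
               c("sedentary", "sedentary", "lpa", "lpa", "mvpa", "mvpa"))
  wk$wear[1] <- FALSE
  expect_equal(as.character(classify_minutes(wk, cp))[1], "nonwear")
  expect_error(classify_minutes(make_week(-5), cp), "negative")
})

test_that("wrist-dialect boundaries hold for arbitrary configured cut-points", {
  for (cuts in list(c(30, 100), c(45.5, 93.2), c(10, 400))) {
    cp <- pa_cutpoints("wrist", lpa_lower = cuts[1], mvpa_lower = cuts[2])
    eps <- 1e-9
    wk <- make_week(c(cuts[1] - eps, cuts[1], cuts[2] - eps, cuts[2]))
    expect_equal(as.character(classify_minutes(wk, cp)),
                 c("sedentary", "lpa", "lpa", "mvpa"))
  }
  expect_error(pa_cutpoints("wrist", lpa_lower = 200, mvpa_lower = 100))
})

test_that("an all-zero worn week is entirely sedentary", {
  wk <- make_week(rep(0, 1440))
  expect_true(all(classify_minutes(wk, pa_cutpoints("nhanes")) == "sedentary"))
})

test_that("UKB wear rule needs 72 h and full clock-hour coverage", {
  full <- generate_activity_week(mvpa_min = 0, lpa_min = 0)
  expect_true(as.logical(wear_valid(full, "ukb")))

  # 71 h spread over all clock hours: 3 days of 1420 min each, first 20
  # minutes of each hour missing in part
  wk <- make_week(rep(10, 7 * 1440))
  wear <- rep(FALSE, 7 * 1440)
  wear[seq_len(71 * 60)] <- TRUE   # 71 h covering days 1-3 (all clock hours)
  wk$wear <- wear
  expect_false(as.logical(wear_valid(wk, "ukb")))

  # 72 h of wear missing one clock hour entirely
  wk2 <- make_week(rep(10, 7 * 1440))
  hrs <- (as.numeric(wk2$timestamp) %/% 3600) %% 24
  wk2$wear <- hrs != 3
  expect_true(sum(wk2$wear) >= 72 * 60)
  expect_false(as.logical(wear_valid(wk2, "ukb")))

  expect_error(wear_valid(full[0, ], "ukb"), "empty")
})

test_that("NHANES wear rule needs one 600-minute day, after zero-run removal", {
  one_day <- make_week(rep(50, 1440))
  one_day$wear <- c(rep(TRUE, 600), rep(FALSE, 840))
  expect_true(as.logical(wear_valid(one_day, "nhanes")))

  short <- make_week(rep(50, 1440))
  short$wear <- c(rep(TRUE, 599), rep(FALSE, 841))
  expect_false(as.logical(wear_valid(short, "nhanes")))

  # 600 worn minutes but 61+ of them a consecutive zero run -> invalid
  zr <- make_week(c(rep(50, 300), rep(0, 61), rep(50, 239), rep(0, 840)))
  zr$wear <- c(rep(TRUE, 600), rep(FALSE, 840))
  expect_false(as.logical(wear_valid(zr, "nhanes")))
  # a 60-minute zero run is tolerated
  zr60 <- make_week(c(rep(50, 300), rep(0, 60), rep(50, 240), rep(0, 840)))
  zr60$wear <- c(rep(TRUE, 600), rep(FALSE, 840))
  expect_true(as.logical(wear_valid(zr60, "nhanes")))
})

test_that("weekly summary arithmetic: totals, top-2 share, permutation invariance", {
  cp <- pa_cutpoints("nhanes")
  # MVPA minutes by day: 120, 60, 5, 5, 5, 5, 0
  by_day <- c(120, 60, 5, 5, 5, 5, 0)
  vals <- unlist(lapply(by_day, function(k) c(rep(3000, k), rep(10, 1440 - k))))
  wk <- make_week(vals)
  s <- summarize_week(wk, cp)
  expect_equal(s$mvpa_min_week, 200)
  expect_equal(s$top2_share, 0.90)
  expect_equal(s$days_observed, 7)

  # permuting minutes within days leaves the summary unchanged
  set.seed(1)
  idx <- unlist(lapply(0:6, function(d) d * 1440 + sample.int(1440)))
  wk2 <- wk
  wk2$value <- wk$value[idx]
  s2 <- summarize_week(wk2, cp)
  expect_equal(s2$mvpa_min_week, s$mvpa_min_week)
  expect_equal(s2$lpa_min_week, s$lpa_min_week)
  expect_equal(s2$top2_share, s$top2_share)

  # no MVPA -> share 0 by convention
  s0 <- summarize_week(make_week(rep(10, 1440)), cp)
  expect_equal(s0$top2_share, 0)
  expect_equal(s0$mvpa_min_week, 0)
})

test_that("pattern rules: printed examples and boundary behaviour", {
  mk <- function(m, l, s) list(mvpa_min_week = m, lpa_min_week = l,
                               top2_share = s, wear_valid = TRUE)
  expect_equal(as.character(classify_pattern(mk(200, 0, 0.90))), "active_ww")
  expect_equal(as.character(classify_pattern(mk(150, 0, 150 / 7 * 2 / 150))),
               "active_regular")
  expect_equal(as.character(classify_pattern(mk(140, 1900, 0))), "active_lpa")
  expect_equal(as.character(classify_pattern(mk(140, 1899, 0))), "baseline")
  expect_equal(as.character(classify_pattern(mk(0, 0, 0))), "baseline")
  # inclusive thresholds
  expect_equal(as.character(classify_pattern(mk(150, 0, 0.5))), "active_ww")
  expect_equal(as.character(classify_pattern(mk(150, 0, 0.499))), "active_regular")
  expect_equal(as.character(classify_pattern(mk(149, 1900, 1))), "active_lpa")
  # invalid wear refuses classification
  bad <- mk(200, 0, 0.9)
  bad$wear_valid <- FALSE
  expect_error(classify_pattern(bad), "excluded")
})

test_that("every valid summary receives exactly one pattern (exhaustive cases)", {
  for (m in c(0, 149, 150, 400)) {
    for (l in c(0, 1899, 1900, 2500)) {
      for (s in c(0, 0.3, 0.5, 1)) {
        lab <- classify_pattern(list(mvpa_min_week = m, lpa_min_week = l,
                                     top2_share = s, wear_valid = TRUE))
        expect_length(lab, 1)
        expect_false(is.na(lab))
      }
    }
  }
})

test_that("generated weeks round-trip through the summary exactly", {
  cp <- pa_cutpoints("nhanes")
  wk <- generate_activity_week(mvpa_min = 200, lpa_min = 300,
                               top2_share = 0.9, cutpoints = cp, seed = 2)
  s <- summarize_week(wk, cp)
  expect_equal(s$mvpa_min_week, 200)
  expect_equal(s$lpa_min_week, 300)
  expect_equal(s$top2_share, 0.9)
  expect_true(s$wear_valid)

  # zero targets: all worn minutes sedentary
  wk0 <- generate_activity_week(0, 0, cutpoints = cp)
  expect_true(all(classify_minutes(wk0, cp) == "sedentary"))

  # requested-invalid week fails the UKB 72 h rule
  bad <- generate_activity_week(0, 0, wear_valid_target = FALSE,
                                protocol = "ukb")
  expect_false(as.logical(wear_valid(bad, "ukb")))
  expect_lt(attr(wear_valid(bad, "ukb"), "worn_minutes"), 72 * 60)
  # and the NHANES variant fails the 600-minute-day rule
  badn <- generate_activity_week(0, 0, wear_valid_target = FALSE,
                                 protocol = "nhanes")
  expect_false(as.logical(wear_valid(badn, "nhanes")))

  # infeasible targets are refused
  expect_error(generate_activity_week(2000, 9000), "exceed")
  expect_error(generate_activity_week(700, 0, top2_share = 0.1), "infeasible")
})

test_that("activity CSV round trip preserves the minute records", {
  wk <- generate_activity_week(60, 120, top2_share = 0.5, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_activity_csv(wk, f)
  wk2 <- read_activity_csv(f)
  expect_equal(nrow(wk2), nrow(wk))
  expect_equal(wk2$wear, wk$wear)
  expect_equal(wk2$timestamp, wk$timestamp)
  expect_equal(wk2$value, wk$value, tolerance = 1e-6)
  unlink(f)
})
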
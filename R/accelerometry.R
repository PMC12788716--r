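#' Intensity cut-points for a device dialect
#'
#' Two dialects are supported. `"nhanes"`: waist-worn ActiGraph counts per
#' minute with the adult thresholds sedentary < 100 cpm, light PA
#' 100-2020 cpm, MVPA >= 2020 cpm. `"wrist"`: wrist-worn acceleration in
#' milligravity (mg) with user-configurable thresholds — the wrist pipeline
#' this package replaces used a machine-learned activity classifier, so no
#' packaged mg cut-points are presented as equivalent to it; the values used
#' (defaults 30/100 mg, common in the wrist-accelerometry literature) are
#' recorded in the returned object and should be reported with any results.
#'
#' @param dialect `"nhanes"` or `"wrist"`.
#' @param lpa_lower lower bound (inclusive) of light PA; minutes below are
#'   sedentary.
#' @param mvpa_lower lower bound (inclusive) of MVPA.
#' @return list of class `pa_cutpoints` with `dialect`, `lpa_lower`,
#'   `mvpa_lower`, `unit`.
#' @export
pa_cutpoints <- function(dialect = c("nhanes", "wrist"),
                         lpa_lower = NULL, mvpa_lower = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "nhanes") {
    lpa_lower <- lpa_lower %||% 100
    mvpa_lower <- mvpa_lower %||% 2020
    unit <- "counts/min"
  } else {
    lpa_lower <- lpa_lower %||% 30
    mvpa_lower <- mvpa_lower %||% 100
    unit <- "mg"
  }
  if (!(0 < lpa_lower && lpa_lower < mvpa_lower)) {
    stop("cut-points must satisfy 0 < lpa_lower < mvpa_lower")
  }
  structure(list(dialect = dialect, lpa_lower = lpa_lower,
                 mvpa_lower = mvpa_lower, unit = unit),
            class = "pa_cutpoints")
}

#' Classify per-minute activity intensity
#'
#' Assigns every minute of an activity week exactly one label:
#' `nonwear` for minutes with `wear == FALSE`; otherwise `sedentary`
#' (value < `lpa_lower`), `lpa` (`lpa_lower` <= value < `mvpa_lower`) or
#' `mvpa` (value >= `mvpa_lower`).
#'
#' @param week an `activity_week` data.frame (columns `timestamp`, `value`,
#'   `wear`) as produced by [generate_activity_week()] or
#'   [read_activity_csv()].
#' @param cutpoints a [pa_cutpoints()] object.
#' @return factor of length `nrow(week)` with levels
#'   `sedentary, lpa, mvpa, nonwear`.
#' @export
classify_minutes <- function(week, cutpoints) {
  stopifnot(inherits(cutpoints, "pa_cutpoints"))
  if (any(week$value < 0, na.rm = TRUE)) stop("negative activity values")
  lab <- ifelse(!week$wear, "nonwear",
         ifelse(week$value >= cutpoints$mvpa_lower, "mvpa",
         ifelse(week$value >= cutpoints$lpa_lower, "lpa", "sedentary")))
  factor(lab, levels = c("sedentary", "lpa", "mvpa", "nonwear"))
}

# NHANES calibration rule: any run of > 60 consecutive worn zero-count
# minutes is reclassified as nonwear before wear-time evaluation
apply_nhanes_zero_runs <- function(week, max_zero_run = 60L) {
  zero_worn <- week$wear & week$value == 0
  r <- rle(zero_worn)
  flip <- r$values & r$lengths > max_zero_run
  if (any(flip)) {
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (j in which(flip)) week$wear[idx_start[j]:idx_end[j]] <- FALSE
  }
  week
}

#' Evaluate wear-time validity of an activity week
#'
#' UKB protocol: valid iff total worn time is at least 72 hours AND every
#' one of the 24 clock hours contains at least one worn minute (pooled over
#' days). NHANES protocol: runs of more than 60 consecutive worn zero-count
#' minutes are first marked nonwear (poor-calibration rule); valid iff at
#' least one calendar day has 600 or more worn minutes.
#'
#' @param week an `activity_week` data.frame.
#' @param protocol `"ukb"` or `"nhanes"`.
#' @return logical scalar, with attribute `worn_minutes`.
#' @export
wear_valid <- function(week, protocol = c("ukb", "nhanes")) {
  protocol <- match.arg(protocol)
  if (nrow(week) == 0L) stop("empty activity week")
  if (protocol == "nhanes") week <- apply_nhanes_zero_runs(week)
  worn <- sum(week$wear)
  secs <- as.numeric(week$timestamp)
  ok <- if (protocol == "ukb") {
    hours <- (secs[week$wear] %/% 3600) %% 24
    worn >= 72L * 60L && length(unique(hours)) == 24L
  } else {
    day <- secs %/% 86400
    any(tapply(week$wear, day, sum) >= 600L)
  }
  structure(ok, worn_minutes = worn)
}

#' Summarize an activity week into pattern-classification inputs
#'
#' Computes weekly MVPA and light-PA minutes over worn minutes, the share of
#' weekly MVPA accumulated in the two calendar days with the most MVPA
#' (`top2_share`, defined as 0 when there is no MVPA), and mean daily
#' sedentary minutes over days with at least 600 worn minutes (all observed
#' days if none qualify). Days are calendar days in device-local time.
#'
#' @inheritParams classify_minutes
#' @param protocol wear protocol passed to [wear_valid()].
#' @return list of class `weekly_summary`: `mvpa_min_week`, `lpa_min_week`,
#'   `sedentary_min_day`, `top2_share`, `wear_valid`, `days_observed`.
#' @export
summarize_week <- function(week, cutpoints, protocol = c("ukb", "nhanes")) {
  protocol <- match.arg(protocol)
  lab <- classify_minutes(week, cutpoints)
  day <- as.numeric(week$timestamp) %/% 86400  # calendar day, device-local
  mvpa_by_day <- tapply(lab == "mvpa", day, sum)
  mvpa <- sum(mvpa_by_day)
  top2 <- if (mvpa > 0) sum(sort(mvpa_by_day, decreasing = TRUE)[1:2], na.rm = TRUE) / mvpa else 0
  worn_by_day <- tapply(week$wear, day, sum)
  sed_by_day <- tapply(lab == "sedentary", day, sum)
  valid_days <- worn_by_day >= 600
  if (!any(valid_days)) valid_days <- worn_by_day > 0
  structure(list(
    mvpa_min_week = as.numeric(mvpa),
    lpa_min_week = as.numeric(sum(lab == "lpa")),
    sedentary_min_day = mean(sed_by_day[valid_days]),
    top2_share = as.numeric(top2),
    wear_valid = as.logical(wear_valid(week, protocol)),
    days_observed = length(unique(day))
  ), class = "weekly_summary")
}

#' Classify the weekly physical-activity pattern
#'
#' Applies the four mutually exclusive, exhaustive pattern rules:
#' `active_ww` (weekend warrior) iff MVPA >= 150 min/wk and at least 50% of
#' it falls in the two highest-MVPA days; `active_regular` iff MVPA >= 150
#' with less than 50% in the top two days; `active_lpa` iff MVPA < 150 and
#' light PA >= 1900 min/wk; `baseline` iff MVPA < 150 and light PA < 1900.
#' All thresholds are inclusive on the printed ">=" side.
#'
#' @param summary a `weekly_summary` (or any list with `mvpa_min_week`,
#'   `lpa_min_week`, `top2_share`, and optionally `wear_valid`).
#' @param mvpa_threshold,lpa_threshold,ww_share weekly thresholds
#'   (minutes, minutes, proportion).
#' @return length-1 factor with levels `pa_patterns()`.
#' @export
classify_pattern <- function(summary, mvpa_threshold = 150,
                             lpa_threshold = 1900, ww_share = 0.5) {
  if (!is.null(summary$wear_valid) && !isTRUE(as.logical(summary$wear_valid))) {
    stop("invalid wear time: week is excluded, not classifiable")
  }
  m <- summary$mvpa_min_week
  l <- summary$lpa_min_week
  s <- summary$top2_share
  lab <- if (m >= mvpa_threshold) {
    if (s >= ww_share) "active_ww" else "active_regular"
  } else if (l >= lpa_threshold) "active_lpa" else "baseline"
  pa_pattern_factor(lab)
}
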
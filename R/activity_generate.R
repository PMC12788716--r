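#' Generate a synthetic per-minute activity week hitting exact weekly targets
#'
#' Constructs a 7 x 1440 minute record whose classification under the given
#' dialect cut-points reproduces the requested weekly MVPA and light-PA
#' minutes exactly, with the requested fraction of MVPA minutes placed on
#' the two highest-MVPA calendar days (the "weekend": the last two days of
#' the week). `round(top2_share * mvpa_min)` MVPA minutes go to the weekend
#' days and the remainder is spread evenly over the other five days, so the
#' realized top-two share is `round(top2_share * mvpa_min) / mvpa_min`; pass
#' a share of the form k/mvpa_min for an exact round trip. Worn minutes not
#' assigned to MVPA or light PA carry a small nonzero sedentary value (so the
#' NHANES zero-run calibration rule is not tripped by construction).
#'
#' With `wear_valid_target = FALSE` the week is degraded to fail the stated
#' protocol: under `"ukb"`, total wear is cut below 72 h; under `"nhanes"`,
#' no day reaches 600 worn minutes.
#'
#' @param mvpa_min,lpa_min target weekly MVPA / light-PA minutes (>= 0).
#' @param top2_share requested fraction of MVPA on the two highest days, in
#'   \[0, 1\]. Low values may be infeasible (the top two of seven days always
#'   hold at least their even share); an error is raised if the placement
#'   cannot make the weekend the two highest-MVPA days.
#' @param cutpoints a [pa_cutpoints()]; determines the dialect and the
#'   values emitted for each intensity class.
#' @param wear_valid_target should the emitted week satisfy the wear rules?
#' @param protocol wear protocol the validity target refers to.
#' @param participant_id id stamped on the records.
#' @param start first timestamp (device-local, treated as UTC); defaults to
#'   a Monday 00:00.
#' @param seed integer seed (controls within-class value jitter only).
#' @return data.frame of class `activity_week` with columns
#'   `participant_id`, `timestamp`, `value`, `wear` (10,080 rows), and
#'   attribute `dialect`.
#' @export
generate_activity_week <- function(mvpa_min = 0, lpa_min = 0,
                                   top2_share = 0.5,
                                   cutpoints = pa_cutpoints("nhanes"),
                                   wear_valid_target = TRUE,
                                   protocol = c("ukb", "nhanes"),
                                   participant_id = 1L,
                                   start = as.POSIXct("2024-01-01 00:00:00",
                                                      tz = "UTC"),
                                   seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(mvpa_min >= 0, lpa_min >= 0, top2_share >= 0, top2_share <= 1)
  mvpa_min <- as.integer(round(mvpa_min))
  lpa_min <- as.integer(round(lpa_min))
  set.seed(as.integer(seed))

  n_day <- 1440L
  wear <- matrix(TRUE, nrow = n_day, ncol = 7L)
  if (!wear_valid_target) {
    if (protocol == "ukb") {
      # 60 h of wear over full days 1-2.5: every clock hour covered but < 72 h
      wear[] <- FALSE
      wear[, 1:2] <- TRUE
      wear[seq_len(720L), 3L] <- TRUE
    } else {
      # nhanes: no day reaches 600 worn minutes
      wear[] <- FALSE
      wear[seq_len(500L), ] <- TRUE
    }
  }

  worn_per_day <- colSums(wear)
  # MVPA placement: weekend (days 6-7) holds round(share * M)
  k2 <- as.integer(round(top2_share * mvpa_min))
  if (k2 > mvpa_min) k2 <- mvpa_min
  mvpa_day <- integer(7L)
  mvpa_day[6L] <- ceiling(k2 / 2)
  mvpa_day[7L] <- k2 - mvpa_day[6L]
  rest <- mvpa_min - k2
  base <- rest %/% 5L
  extra <- rest %% 5L
  mvpa_day[1:5] <- base + c(rep(1L, extra), rep(0L, 5L - extra))
  if (mvpa_min > 0 && max(mvpa_day[1:5]) > min(mvpa_day[6:7]) && k2 > 0) {
    stop("infeasible weekend concentration: a weekday would exceed a weekend day")
  }
  if (mvpa_min > 0 && k2 == 0 && top2_share > 0) {
    stop("top2_share rounds to zero weekend minutes; use share = k/mvpa_min")
  }
  lpa_day <- integer(7L)
  lpa_day[] <- lpa_min %/% 7L
  lpa_day[seq_len(lpa_min %% 7L)] <- lpa_day[seq_len(lpa_min %% 7L)] + 1L
  if (any(mvpa_day + lpa_day > worn_per_day)) {
    stop("target minutes exceed available wear minutes on at least one day")
  }

  cp <- cutpoints
  sed_hi <- cp$lpa_lower
  value <- matrix(0, nrow = n_day, ncol = 7L)
  for (d in 1:7) {
    worn_idx <- which(wear[, d])
    nm <- mvpa_day[d]; nl <- lpa_day[d]
    ns <- length(worn_idx) - nm - nl
    # daytime-first ordering: MVPA, then LPA, then sedentary fill
    vals <- c(
      runif(nm, cp$mvpa_lower, cp$mvpa_lower * 1.5),
      runif(nl, cp$lpa_lower, cp$lpa_lower + 0.9 * (cp$mvpa_lower - cp$lpa_lower)),
      runif(ns, sed_hi * 0.05, sed_hi * 0.5)
    )
    value[worn_idx, d] <- vals
  }
  out <- data.frame(
    participant_id = participant_id,
    timestamp = start + 60 * (seq_len(7L * n_day) - 1L),
    value = as.vector(value),
    wear = as.vector(wear)
  )
  structure(out, class = c("activity_week", "data.frame"),
            dialect = cp$dialect)
}
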
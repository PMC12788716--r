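# Kaplan-Meier estimate of the censoring survival G(t) = P(C > t),
# evaluated right-continuously, or as the left limit G(t-) with left = TRUE.
censoring_km <- function(time, event) {
  survival::survfit(survival::Surv(time, 1 - event) ~ 1)
}

km_eval <- function(fit, t, left = FALSE) {
  tt <- fit$time
  ss <- fit$surv
  f <- stats::stepfun(tt, c(1, ss), right = FALSE)
  if (left) {
    # left-continuous evaluation: value just before t
    vapply(t, function(ti) {
      below <- tt < ti
      if (!any(below)) 1 else ss[max(which(below))]
    }, numeric(1))
  } else {
    f(t)
  }
}

# IPCW weights at horizon t: events by t weighted by 1/G(T-), subjects still
# at risk past t by 1/G(t), censored-before-t subjects weight 0
ipcw_weights <- function(time, event, t, Gfit = censoring_km(time, event)) {
  w <- numeric(length(time))
  is_case <- time <= t & event == 1
  is_ctrl <- time > t
  Gt <- km_eval(Gfit, t)
  Gti <- km_eval(Gfit, time, left = TRUE)
  if (any(is_case & Gti <= 0) || (any(is_ctrl) && Gt <= 0)) {
    stop("censoring survival reaches 0 before the horizon; IPCW undefined")
  }
  w[is_case] <- 1 / Gti[is_case]
  w[is_ctrl] <- 1 / Gt
  list(w = w, case = is_case, control = is_ctrl)
}

#' IPCW Brier score at a horizon
#'
#' Censoring-adjusted (inverse probability of censoring weighted) Brier
#' score of predicted survival probabilities at horizon `t`:
#' \deqn{BS(t) = \frac{1}{n}\sum_i \frac{\hat S_i(t)^2 \, 1\{T_i \le t, \delta_i = 1\}}{\hat G(T_i^-)}
#'   + \frac{(1 - \hat S_i(t))^2 \, 1\{T_i > t\}}{\hat G(t)}}
#' with \eqn{\hat G} the Kaplan-Meier censoring survival. Subjects censored
#' before `t` contribute weight 0. Optional bootstrap percentile CI.
#'
#' @param pred_surv predicted survival probabilities at `t` (one per row).
#' @param time,event observed follow-up and event indicator.
#' @param t horizon.
#' @param n_boot bootstrap replicates for the CI (0 = no CI).
#' @param conf CI level.
#' @param seed seed for the bootstrap.
#' @return list of class `eval_metric`: `metric = "brier"`, `t`, `estimate`,
#'   `ci` (or `NULL`), `n`.
#' @export
brier_score <- function(pred_surv, time, event, t, n_boot = 0L,
                        conf = 0.95, seed = 1L) {
  stopifnot(length(pred_surv) == length(time))
  one <- function(pred_surv, time, event) {
    wt <- ipcw_weights(time, event, t)
    if (!any(wt$case | wt$control)) stop("no observable status at horizon t")
    err <- numeric(length(time))
    err[wt$case] <- pred_surv[wt$case]^2
    err[wt$control] <- (1 - pred_surv[wt$control])^2
    mean(err * wt$w)
  }
  est <- one(pred_surv, time, event)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    bs <- replicate(n_boot, {
      i <- sample.int(length(time), replace = TRUE)
      one(pred_surv[i], time[i], event[i])
    })
    ci <- unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(metric = "brier", t = t, estimate = est, ci = ci,
                 n = length(time)), class = "eval_metric")
}

#' IPCW cumulative/dynamic AUC at a horizon
#'
#' Time-dependent AUC with cumulative cases (events by `t`) and dynamic
#' controls (subjects beyond `t`), inverse-probability-of-censoring
#' weighted (Uno-type): the weighted probability that a case's risk score
#' exceeds a control's, ties counting one half.
#'
#' @param risk risk scores (higher = higher predicted risk; e.g.
#'   `1 - pred_surv`).
#' @inheritParams brier_score
#' @return list of class `eval_metric`: `metric = "auc"`, `t`, `estimate`,
#'   `ci` (or `NULL`), `n`, plus `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(risk, time, event, t, n_boot = 0L,
                               conf = 0.95, seed = 1L) {
  stopifnot(length(risk) == length(time))
  one <- function(risk, time, event) {
    wt <- ipcw_weights(time, event, t)
    if (!any(wt$case)) stop("no cases at horizon t")
    if (!any(wt$control)) stop("no controls at horizon t")
    rc <- risk[wt$case]; wc <- wt$w[wt$case]
    rk <- risk[wt$control]; wk <- wt$w[wt$control]
    # rank-based weighted concordance: for each case, total control weight
    # with lower risk (+ half of equal-risk weight)
    ord <- order(rk)
    rk <- rk[ord]; wk <- wk[ord]
    cumw <- cumsum(wk)
    upto <- findInterval(rc, rk)                    # controls with risk <= case
    below <- findInterval(rc, rk, left.open = TRUE) # controls with risk <  case
    w_below <- ifelse(below > 0, cumw[pmax(below, 1L)], 0)
    w_upto <- ifelse(upto > 0, cumw[pmax(upto, 1L)], 0)
    w_tie <- w_upto - w_below
    sum(wc * (w_below + 0.5 * w_tie)) / (sum(wc) * sum(wk))
  }
  est <- one(risk, time, event)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    bs <- replicate(n_boot, {
      i <- sample.int(length(time), replace = TRUE)
      one(risk[i], time[i], event[i])
    })
    ci <- unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  wt <- ipcw_weights(time, event, t)
  structure(list(metric = "auc", t = t, estimate = est, ci = ci,
                 n = length(time), n_cases = sum(wt$case),
                 n_controls = sum(wt$control)), class = "eval_metric")
}

#' @export
print.eval_metric <- function(x, ...) {
  cat(sprintf("%s(t = %g) = %.4f", toupper(x$metric), x$t, x$estimate))
  if (!is.null(x$ci)) cat(sprintf("  [%.4f, %.4f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Calibration curve at a horizon
#'
#' Bins subjects by deciles of predicted risk at `t` and contrasts mean
#' predicted risk with the Kaplan-Meier observed risk in each bin.
#'
#' @inheritParams brier_score
#' @param bins number of predicted-risk bins.
#' @return data.frame: `bin`, `n`, `predicted`, `observed`.
#' @export
calibration_curve <- function(pred_surv, time, event, t, bins = 10L) {
  risk <- 1 - pred_surv
  qs <- unique(stats::quantile(risk, seq(0, 1, length.out = bins + 1)))
  grp <- cut(risk, qs, include.lowest = TRUE)
  out <- lapply(levels(grp), function(g) {
    i <- which(grp == g)
    km <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    obs <- 1 - km_eval(km, t)
    data.frame(bin = g, n = length(i), predicted = mean(risk[i]),
               observed = obs)
  })
  do.call(rbind, out)
}
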
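# direct-sum IPCW oracles, written as plain per-subject loops over the
# Kaplan-Meier censoring survival (independent of the package's vectorized
# implementations)
oracle_G <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  list(at = function(t) {
    if (!any(fit$time <= t)) return(1)
    fit$surv[max(which(fit$time <= t))]
  }, before = function(t) {
    if (!any(fit$time < t)) return(1)
    fit$surv[max(which(fit$time < t))]
  })
}

oracle_brier <- function(pred_surv, time, event, t) {
  G <- oracle_G(time, event)
  total <- 0
  for (i in seq_along(time)) {
    if (time[i] <= t && event[i] == 1) {
      total <- total + pred_surv[i]^2 / G$before(time[i])
    } else if (time[i] > t) {
      total <- total + (1 - pred_surv[i])^2 / G$at(t)
    }
  }
  total / length(time)
}

oracle_auc <- function(risk, time, event, t) {
  G <- oracle_G(time, event)
  num <- 0; den <- 0
  for (i in seq_along(time)) {
    if (!(time[i] <= t && event[i] == 1)) next
    wi <- 1 / G$before(time[i])
    for (j in seq_along(time)) {
      if (time[j] <= t) next
      wj <- 1 / G$at(t)
      conc <- if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
      num <- num + wi * wj * conc
      den <- den + wi * wj
    }
  }
  num / den
}

censored_fixture <- function(n = 50, seed = 123) {
  set.seed(seed)
  lp <- rnorm(n, sd = 0.8)
  t_ev <- rweibull_ph(runif(n), 1.2, 12, lp)
  cens <- pmin(runif(n, 1, 25), 15)
  data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
             pred = exp(-(8 / 12)^1.2 * exp(lp)))
}

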
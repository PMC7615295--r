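# Non-parametric estimators: Kaplan-Meier curves with the Greenwood
# variance, KM-based restricted mean survival time, and the difference in
# survival proportions at a fixed time with a Wald interval.

#' Kaplan-Meier curve with Greenwood variance for one arm
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct observed event times, with the Greenwood variance
#' `Var(S(t)) = S(t)^2 sum_{t_i <= t} d_i / (n_i (n_i - d_i))`. Ties
#' between events and censorings at the same time are resolved
#' events-first (the censored subjects remain in the risk set). The
#' product-limit machinery is delegated to [survival::survfit()].
#'
#' @param ds A [survival_data] object restricted to a single arm.
#' @return An object of class `"km_curve"` with `event_times`, `survival`,
#'   `greenwood_var`, `n_at_risk`, `n_events`, plus `n` (arm size) and
#'   `t_max` (largest observed time, any status).
#' @export
kaplan_meier <- function(ds) {
  if (nrow(ds) < 1) stop_input("empty input")
  if (length(unique(ds$arm)) > 1)
    stop_input("kaplan_meier expects data from a single arm")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ds))
  keep <- fit$n.event > 0
  tt <- fit$time[keep]
  d <- fit$n.event[keep]
  n <- fit$n.risk[keep]
  surv <- cumprod(1 - d / n)
  inc <- d / (n * (n - d))
  inc[d == n] <- 0  # S has reached 0; Greenwood increment undefined, var 0
  gw <- surv^2 * cumsum(inc)
  structure(list(event_times = tt, survival = surv, greenwood_var = gw,
                 n_at_risk = n, n_events = d,
                 n = nrow(ds), t_max = max(ds$time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d distinct event times\n",
              x$n, length(x$event_times)))
  invisible(x)
}

# Internal: area under the KM step function from each event time to tau,
# plus the total area on [0, tau].
km_step_areas <- function(curve, tau) {
  tt <- curve$event_times
  ss <- curve$survival
  in_win <- tt <= tau
  tw <- tt[in_win]
  sw <- ss[in_win]
  # step function: S = 1 on [0, t_1), = sw[i] on [t_i, t_{i+1})
  grid <- c(0, tw, tau)
  vals <- c(1, sw)
  widths <- diff(grid)
  total <- sum(vals * widths)
  # forward areas A(t_i) = integral from t_i to tau of S
  A <- rev(cumsum(rev(vals[-1] * widths[-1])))
  list(total = total, forward = A, event_times = tw)
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' The point estimate is the area under the KM step function on
#' `[0, tau]`. The variance is the standard product-limit RMST variance
#' `sum_{t_i <= tau} A(t_i)^2 d_i / (n_i (n_i - d_i))` where
#' `A(t_i)` is the area under the curve from `t_i` to `tau`.
#'
#' RMST to `tau` is identifiable only if follow-up in the arm reaches
#' `tau` or the curve hits zero before `tau`.
#'
#' @param curve A `"km_curve"`.
#' @param tau Horizon in years.
#' @param alpha One-sided level used for the two-sided `1 - 2*alpha`
#'   confidence interval (default 0.025, i.e. a 95% interval).
#' @return A `"surv_estimate"` (see [new_estimate()]) with measure
#'   `"RMST"`.
#' @export
km_rmst <- function(curve, tau, alpha = 0.025) {
  if (tau <= 0) stop_input("tau must be positive")
  hits_zero <- length(curve$survival) > 0 &&
    min(curve$survival) <= 0 && min(curve$event_times[curve$survival <= 0]) <= tau
  if (curve$t_max < tau && !hits_zero)
    stop_numeric(sprintf(
      "RMST to tau = %g not identifiable: follow-up ends at %g", tau,
      curve$t_max))
  ar <- km_step_areas(curve, tau)
  in_win <- curve$event_times <= tau
  d <- curve$n_events[in_win]
  n <- curve$n_at_risk[in_win]
  inc <- d / (n * (n - d))
  inc[d == n] <- 0
  v <- sum(ar$forward^2 * inc)
  new_estimate(measure = "RMST", value = ar$total, se = sqrt(v),
               scale = "identity", alpha = alpha, tau = tau,
               method = "nonparametric")
}

#' Non-parametric difference in restricted mean survival time
#'
#' Research-arm RMST minus control-arm RMST on `[0, tau]`, each from the
#' arm's Kaplan-Meier curve; the arms are independent so the variance is
#' the sum of the two RMST variances, with a plain Wald interval.
#'
#' @param ds A two-arm [survival_data] object.
#' @param tau Horizon in years.
#' @param alpha One-sided level (default 0.025).
#' @return A `"surv_estimate"` with measure `"DRMST"`.
#' @export
nonpar_drmst <- function(ds, tau, alpha = 0.025) {
  check_two_arms(ds)
  rc <- km_rmst(kaplan_meier(ds[ds$arm == 0, ]), tau, alpha)
  ra <- km_rmst(kaplan_meier(ds[ds$arm == 1, ]), tau, alpha)
  new_estimate(measure = "DRMST", value = ra$value - rc$value,
               se = sqrt(ra$se^2 + rc$se^2), scale = "identity",
               alpha = alpha, tau = tau, method = "nonparametric")
}

#' Non-parametric difference in survival at a fixed time
#'
#' When every subject's status at `tau` is known (no censoring strictly
#' before `tau`), this is the simple difference in proportions surviving
#' beyond `tau` with the binomial Wald standard error
#' `sqrt(p_A (1 - p_A) / n_A + p_C (1 - p_C) / n_C)`. A subject with an
#' event at exactly `tau` counts as a non-survivor; one censored at
#' exactly `tau` counts as a survivor. If some subjects are censored
#' before `tau`, the difference falls back to the Kaplan-Meier estimates
#' of `S(tau)` with Greenwood variances (a message notes this).
#'
#' @param ds A two-arm [survival_data] object.
#' @param tau Horizon in years.
#' @param alpha One-sided level (default 0.025).
#' @return A `"surv_estimate"` with measure `"DS"`.
#' @export
nonpar_ds <- function(ds, tau, alpha = 0.025) {
  check_two_arms(ds)
  if (any(ds$time < tau & ds$event == 0)) {
    message("censoring before tau: falling back to Kaplan-Meier DS")
    stat <- function(arm) {
      cv <- kaplan_meier(ds[ds$arm == arm, ])
      in_win <- cv$event_times <= tau
      if (!any(in_win)) return(c(1, 0))
      i <- max(which(in_win))
      c(cv$survival[i], cv$greenwood_var[i])
    }
    sc <- stat(0); sa <- stat(1)
    val <- sa[1] - sc[1]
    se <- sqrt(sa[2] + sc[2])
  } else {
    surv <- !(ds$time <= tau & ds$event == 1)
    pc <- mean(surv[ds$arm == 0])
    pa <- mean(surv[ds$arm == 1])
    nc <- sum(ds$arm == 0)
    na <- sum(ds$arm == 1)
    val <- pa - pc
    se <- sqrt(pa * (1 - pa) / na + pc * (1 - pc) / nc)
  }
  new_estimate(measure = "DS", value = val, se = se, scale = "identity",
               alpha = alpha, tau = tau, method = "nonparametric")
}
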
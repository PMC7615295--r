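one_arm <- function(time, event) {
  survival_data(time = time, event = event, arm = rep(0, length(time)))
}

test_that("KM equals the empirical survival function without censoring", {
  cv <- kaplan_meier(one_arm(1:4, rep(1, 4)))
  expect_equal(cv$event_times, 1:4)
  expect_equal(cv$survival, c(3, 2, 1, 0) / 4)
  # Greenwood equals the binomial variance S(1-S)/n at each event time
  expect_equal(cv$greenwood_var[1:3],
               cv$survival[1:3] * (1 - cv$survival[1:3]) / 4)
  set.seed(5)
  tt <- rexp(40)
  cv2 <- kaplan_meier(one_arm(tt, rep(1, 40)))
  emp <- sapply(cv2$event_times, function(s) mean(tt > s))
  expect_equal(cv2$survival, emp)
  expect_equal(cv2$greenwood_var, emp * (1 - emp) / 40)
})

test_that("product-limit handles censoring as in the hand computation", {
  # times 1+ (censored), 2, 3: S(2) = 1 * (1 - 1/2) = 1/2, S(3) = 0
  cv <- kaplan_meier(one_arm(c(1, 2, 3), c(0, 1, 1)))
  expect_equal(cv$event_times, c(2, 3))
  expect_equal(cv$survival, c(0.5, 0))
  all_cens <- kaplan_meier(one_arm(c(1, 2), c(0, 0)))
  expect_length(all_cens$event_times, 0)
  expect_error(kaplan_meier(one_arm(numeric(0), numeric(0))),
               class = "nisurv_input_error")
})

test_that("KM matches survfit on a censored sample", {
  set.seed(8)
  ds <- one_arm(rexp(100, 0.4), rbinom(100, 1, 0.6))
  cv <- kaplan_meier(ds)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ds))
  keep <- fit$n.event > 0
  expect_equal(cv$survival, fit$surv[keep], tolerance = 1e-12)
  pos <- cv$survival > 0  # survfit's SE is undefined once S hits zero
  expect_equal(sqrt(cv$greenwood_var)[pos],
               (fit$surv * fit$std.err)[keep][pos], tolerance = 1e-10)
})

test_that("RMST reduces to tau or to the truncated sample mean without censoring", {
  # no events before tau: S = 1 on [0, tau]
  cv <- kaplan_meier(one_arm(c(5, 6, 7), c(0, 1, 1)))
  est <- km_rmst(cv, 3)
  expect_equal(est$value, 3)
  expect_equal(est$se, 0)
  set.seed(13)
  tt <- rexp(60, 0.5)
  est2 <- km_rmst(kaplan_meier(one_arm(tt, rep(1, 60))), 2)
  expect_equal(est2$value, mean(pmin(tt, 2)), tolerance = 1e-12)
})

test_that("RMST area and variance match a hand step-integration", {
  # times 1 (event), 2 (censored), 3 (event); tau = 3
  cv <- kaplan_meier(one_arm(c(1, 2, 3), c(1, 0, 1)))
  # S = 1 on [0,1), 2/3 on [1,3), 0 at 3
  expect_equal(km_rmst(cv, 3)$value, 1 + (2 / 3) * 2)
  # variance: A(1) = 4/3, A(3) = 0;
  # increments d/(n(n-d)): 1/(3*2) at t=1; at t=3, d=n (S hits 0) -> 0
  expect_equal(km_rmst(cv, 3)$se^2, (4 / 3)^2 / 6)
  # tau beyond follow-up is not identifiable unless S has hit zero
  cv2 <- kaplan_meier(one_arm(c(1, 2, 3), c(1, 0, 0)))
  expect_error(km_rmst(cv2, 5), class = "nisurv_numeric_error")
  expect_equal(km_rmst(cv, 5)$value, km_rmst(cv, 3)$value + 0)
})

test_that("RMST agrees with the survival package's restricted mean", {
  set.seed(21)
  ds <- one_arm(rexp(150, 0.4), rbinom(150, 1, 0.7))
  ds <- censor_at(ds, 4)
  cv <- kaplan_meier(ds)
  est <- km_rmst(cv, 2.5)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ds))
  tab <- summary(fit, rmean = 2.5)$table
  expect_equal(est$value, unname(tab["rmean"]), tolerance = 1e-10)
  expect_equal(est$se, unname(tab["se(rmean)"]), tolerance = 1e-10)
})

test_that("RMST is monotone in tau and bounded by tau", {
  set.seed(34)
  cv <- kaplan_meier(one_arm(rexp(80, 0.6), rbinom(80, 1, 0.8)))
  taus <- seq(0.2, 1.4, by = 0.2)
  vals <- sapply(taus, function(tau) km_rmst(cv, tau)$value)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= taus))
})

test_that("DRMST is zero for identical arms and antisymmetric under arm swap", {
  set.seed(55)
  tt <- rexp(60, 0.5)
  ev <- rbinom(60, 1, 0.8)
  same <- survival_data(c(tt, tt), c(ev, ev), rep(0:1, each = 60))
  same <- censor_at(same, 3)
  expect_equal(nonpar_drmst(same, 2)$value, 0)
  ds <- censor_at(make_exp_data(80, 0.5, hr = 1.6, seed = 56), 3)
  swapped <- survival_data(ds$time, ds$event, 1 - ds$arm)
  a <- nonpar_drmst(ds, 2)
  b <- nonpar_drmst(swapped, 2)
  expect_equal(b$value, -a$value)
  expect_equal(b$se, a$se)
})

test_that("non-parametric results ignore follow-up beyond tau", {
  d <- trial_design(s3_control = 0.6, n_per_arm = 150, true_hr = 1.3)
  ds_all <- simulate_trial(d, seed = 71)
  ds3 <- censor_at(ds_all, 3)
  for (f in list(nonpar_drmst, nonpar_ds)) {
    a <- f(ds_all, 3)
    b <- f(ds3, 3)
    expect_equal(a$value, b$value, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
  }
})

test_that("DS difference in proportions matches the binomial hand computation", {
  # arm A: 8/10 survive past 3; arm C: 9/10
  ds <- survival_data(time = rep(c(4, 1), c(17, 3)),
                      event = rep(c(0, 1), c(17, 3)),
                      arm = c(rep(1, 8), rep(0, 9), 1, 1, 0))
  est <- nonpar_ds(ds, 3)
  expect_equal(est$value, -0.1)
  expect_equal(est$se, sqrt(0.8 * 0.2 / 10 + 0.9 * 0.1 / 10))
  expect_equal(est$se, 0.1581, tolerance = 1e-4)
})

test_that("DS boundary conventions: events at tau lost, censored at tau survive", {
  ds <- survival_data(time = c(3, 3, 4, 4), event = c(1, 0, 0, 0),
                      arm = c(0, 0, 1, 1))
  est <- nonpar_ds(ds, 3)
  # control: event at exactly 3 counts as non-survivor -> p_C = 1/2
  expect_equal(est$value, 1 - 0.5)
  # all survive in both arms: degenerate 0 with collapsed interval
  all_surv <- survival_data(time = rep(4, 8), event = rep(0, 8),
                            arm = rep(0:1, 4))
  est2 <- nonpar_ds(all_surv, 3)
  expect_equal(est2$value, 0)
  expect_equal(est2$se, 0)
})

test_that("DS falls back to KM when status at tau is unknown for some subjects", {
  set.seed(91)
  tt <- rexp(200, 0.5)
  ev <- rbinom(200, 1, 0.7)
  ds <- survival_data(tt, ev, rep(0:1, 100))
  expect_message(est <- nonpar_ds(ds, 1.5), "falling back")
  s_km <- function(arm) {
    cv <- kaplan_meier(ds[ds$arm == arm, ])
    i <- max(which(cv$event_times <= 1.5))
    cv$survival[i]
  }
  expect_equal(est$value, s_km(1) - s_km(0), tolerance = 1e-12)
})
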
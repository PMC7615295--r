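test_that("knots sit at boundaries and equal-probability quantiles of log event times", {
  ds <- survival_data(time = exp(0:3), event = rep(1, 4), arm = c(0, 0, 1, 1))
  ks <- place_knots(ds, n_internal = 2)
  expect_equal(ks$boundary, c(0, 3))
  expect_equal(ks$internal,
               unname(quantile(0:3, c(1 / 3, 2 / 3), type = 7)))
  ks0 <- place_knots(ds, n_internal = 0)
  expect_length(ks0$internal, 0)
})

test_that("censored times are excluded and degenerate knot sets refused", {
  ds <- survival_data(time = c(exp(0:3), 100), event = c(rep(1, 4), 0),
                      arm = c(0, 0, 1, 1, 0))
  ks <- place_knots(ds, 2)
  expect_equal(ks$boundary, c(0, 3))  # the censored 100 plays no role
  dup <- survival_data(time = c(1, 1, 1, 5), event = rep(1, 4),
                       arm = c(0, 0, 1, 1))
  expect_error(place_knots(dup, 2), class = "nisurv_input_error")
})

test_that("restricted cubic basis vanishes below and is linear above the boundaries", {
  ks <- structure(list(boundary = c(0, 3), internal = c(1, 2)),
                  class = "knot_set")
  below <- rcs_basis(c(-2, -0.5), ks)
  expect_equal(below$basis[, 3:4], matrix(0, 2, 2))
  expect_equal(below$basis[, 1:2], cbind(1, c(-2, -0.5)))
  # beyond the upper boundary the spline is linear: second differences of
  # any gamma combination vanish
  gamma <- c(0.3, -1.2, 0.7, 2.1)
  x <- seq(3.5, 6, length.out = 30)
  s <- drop(rcs_basis(x, ks)$basis %*% gamma)
  expect_equal(diff(diff(s)), rep(0, 28), tolerance = 1e-10)
})

test_that("basis derivative matches centred finite differences", {
  ks <- structure(list(boundary = c(-0.5, 2.5), internal = c(0.4, 1.3)),
                  class = "knot_set")
  x <- seq(-1, 3, by = 0.11)
  h <- 1e-6
  num <- (rcs_basis(x + h, ks)$basis - rcs_basis(x - h, ks)$basis) / (2 * h)
  expect_equal(rcs_basis(x, ks)$deriv, num, tolerance = 1e-6)
})

test_that("with no internal knots the likelihood reduces to the exponential form", {
  ds <- toy_data()
  ks <- place_knots(ds, 0)
  for (lam in c(0.2, 0.5, 1.3)) {
    # H(t) = lambda t: gamma = (log lambda, 1), beta = 0
    expected <- sum(ds$event * log(lam)) - lam * sum(ds$time)
    expect_equal(log_likelihood(c(log(lam), 1), 0, ds, ks), expected,
                 tolerance = 1e-12)
  }
})

test_that("likelihood contributions match hand evaluation", {
  ks <- structure(list(boundary = c(log(0.01), log(10)),
                       internal = numeric(0)), class = "knot_set")
  one <- survival_data(time = 1, event = 1, arm = 0)
  # eta = 0, s' = 1: log(1) - log(1) + 0 - exp(0) = -1
  expect_equal(log_likelihood(c(0, 1), 0, one, ks), -1)
  # three subjects, gamma = (log 0.5, 1), beta = log 2:
  # H(t|z) = 0.5 t 2^z; events add log(0.5 * 2^z) per unit hazard
  trio <- survival_data(time = c(1, 2, 0.5), event = c(1, 0, 1),
                        arm = c(0, 1, 1))
  g <- c(log(0.5), 1); b <- log(2)
  expected <- (log(0.5) - 0.5) +            # event, t=1, arm 0
    (-0.5 * 2 * 2) +                        # censored, t=2, arm 1
    (log(1) - 0.5 * 0.5 * 2)                # event, t=0.5, arm 1: h = 1
  expect_equal(log_likelihood(g, b, trio, ks), expected, tolerance = 1e-12)
})

test_that("a negative fitted hazard at an event time hits the soft barrier", {
  ds <- toy_data()
  ks <- place_knots(ds, 0)
  expect_lt(log_likelihood(c(0, -1), 0, ds, ks), -1e9)
})

test_that("the fit recovers exponential truth and beats its starting value", {
  ds <- make_exp_data(500, rate_from_survival(0.6, 3), hr = 1, seed = 101)
  fit <- fit_flexpar(ds)
  expect_true(fit$converged)
  k <- length(fit$gamma)
  se_beta <- sqrt(fit$vcov[k + 1, k + 1])
  expect_lt(abs(fit$beta), 3 * se_beta)
  expect_equal(predict_survival(fit, 3, arm = 0), 0.6, tolerance = 0.05)
  # optimisation dominance over the exponential starting model
  lam0 <- sum(ds$event) / sum(ds$time)
  start_ll <- log_likelihood(c(log(lam0), 1, 0, 0), 0, ds, fit$knots)
  expect_gte(fit$loglik, start_ll - 1e-6)
})

test_that("log HR and its SE agree with a Cox partial-likelihood fit", {
  set.seed(77)
  d <- trial_design(s3_control = 0.6, n_per_arm = 400, true_hr = 1.4)
  ds <- simulate_trial(d, seed = 909)
  fit <- fit_flexpar(ds)
  cox <- survival::coxph(survival::Surv(time, event) ~ arm,
                         data = as.data.frame(ds))
  se_cox <- sqrt(vcov(cox)[1, 1])
  k <- length(fit$gamma)
  expect_lt(abs(fit$beta - coef(cox)[[1]]), 0.1 * se_cox)
  expect_equal(sqrt(fit$vcov[k + 1, k + 1]), se_cox, tolerance = 0.02)
})

test_that("fit agrees with an independent spline survival implementation", {
  skip_if_not_installed("flexsurv")
  d <- trial_design(s3_control = 0.6, n_per_arm = 300, true_hr = 1.3)
  ds <- simulate_trial(d, seed = 515)
  fit <- fit_flexpar(ds)
  ref <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ arm,
                                  data = as.data.frame(ds), k = 2,
                                  scale = "hazard")
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
  expect_equal(fit$beta, unname(coef(ref)["arm"]), tolerance = 1e-3)
  k <- length(fit$gamma)
  expect_equal(sqrt(fit$vcov[k + 1, k + 1]),
               sqrt(ref$cov["arm", "arm"]), tolerance = 0.01)
})

test_that("predicted survival is a proper, ordered survival function", {
  d <- trial_design(s3_control = 0.6, n_per_arm = 200, true_hr = 1.5)
  ds <- simulate_trial(d, seed = 33)
  fit <- fit_flexpar(ds)
  tt <- seq(0.05, 6, by = 0.05)
  s0 <- predict_survival(fit, tt, arm = 0)
  s1 <- predict_survival(fit, tt, arm = 1)
  expect_true(all(s0 > 0 & s0 < 1))
  expect_true(all(diff(s0) <= 0))
  expect_true(all(diff(s1) <= 0))
  if (fit$beta > 0) expect_true(all(s1 < s0)) else expect_true(all(s1 > s0))
  expect_error(predict_survival(fit, -1, 0), class = "nisurv_input_error")
})

test_that("exponential-reduction predictions have the closed form", {
  m <- manual_exp_model(lambda = 0.25, beta = 0)
  tt <- c(0.3, 1, 2, 5)
  expect_equal(predict_survival(m, tt, 0), exp(-0.25 * tt),
               tolerance = 1e-12)
  m2 <- manual_exp_model(lambda = 0.25, beta = log(2))
  expect_equal(predict_survival(m2, tt, 1), exp(-0.5 * tt),
               tolerance = 1e-12)
})
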
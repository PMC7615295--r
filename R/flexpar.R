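# Flexible parametric proportional-hazards survival model: a restricted
# cubic spline s(x; gamma) in x = log(t) models the log cumulative baseline
# hazard, and a single binary covariate (arm) acts proportionally:
#
#   log H(t | arm) = s(log t; gamma) + beta * arm
#
# so that S(t | arm) = exp(-exp(...)) and exp(beta) is the hazard ratio.

#' Place spline knots from uncensored survival times
#'
#' Boundary knots sit at the minimum and maximum of the log uncensored
#' times; internal knots at equally spaced probability quantiles of the
#' log uncensored times (for the default of two internal knots, the 33%
#' and 67% quantiles). Quantiles use linear interpolation of order
#' statistics ([stats::quantile()] type 7).
#'
#' @param ds A [survival_data] object.
#' @param n_internal Number of internal knots (default 2; 0 reduces the
#'   model family to Weibull).
#' @return An object of class `"knot_set"` with elements `boundary`
#'   (length 2) and `internal`, all on the log-time scale.
#' @export
place_knots <- function(ds, n_internal = 2) {
  tt <- ds$time[ds$event == 1]
  if (length(unique(tt)) < n_internal + 2)
    stop_input(sprintf(
      "only %d distinct uncensored times; need at least %d (try fewer knots)",
      length(unique(tt)), n_internal + 2))
  x <- log(tt)
  boundary <- range(x)
  internal <- numeric(0)
  if (n_internal > 0) {
    probs <- seq_len(n_internal) / (n_internal + 1)
    internal <- unname(stats::quantile(x, probs, type = 7))
  }
  all_knots <- c(boundary[1], internal, boundary[2])
  if (any(diff(all_knots) <= 0))
    stop_input(paste("knots are not strictly increasing (duplicate event",
                     "times collapse a quantile onto a boundary);",
                     "try fewer internal knots"))
  structure(list(boundary = boundary, internal = internal),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat("Spline knots (log-time scale)\n")
  cat("  boundary:", format(x$boundary, digits = 4), "\n")
  if (length(x$internal))
    cat("  internal:", format(x$internal, digits = 4), "\n")
  invisible(x)
}

#' Restricted cubic spline basis on log time
#'
#' Evaluates the natural (restricted) cubic spline basis and its first
#' derivative at `x`. The basis is `(1, x, v_1(x), ..., v_m(x))` with
#' `v_j(x) = (x - k_j)_+^3 - lambda_j (x - k_min)_+^3 -
#' (1 - lambda_j)(x - k_max)_+^3` and
#' `lambda_j = (k_max - k_j) / (k_max - k_min)`, which is linear beyond
#' the boundary knots.
#'
#' @param x Numeric vector of evaluation points (log-time scale).
#' @param knots A `"knot_set"` from [place_knots()].
#' @return A list with matrices `basis` and `deriv`, each
#'   `length(x)` by `2 + m` where `m` is the number of internal knots.
#' @export
rcs_basis <- function(x, knots) {
  kmin <- knots$boundary[1]
  kmax <- knots$boundary[2]
  ki <- knots$internal
  m <- length(ki)
  n <- length(x)
  B <- matrix(0, n, 2 + m)
  D <- matrix(0, n, 2 + m)
  B[, 1] <- 1
  B[, 2] <- x
  D[, 2] <- 1
  if (m > 0) {
    cube <- function(u) pmax(u, 0)^3
    dcube <- function(u) 3 * pmax(u, 0)^2
    c_min <- cube(x - kmin); d_min <- dcube(x - kmin)
    c_max <- cube(x - kmax); d_max <- dcube(x - kmax)
    for (j in seq_len(m)) {
      lam <- (kmax - ki[j]) / (kmax - kmin)
      B[, 2 + j] <- cube(x - ki[j]) - lam * c_min - (1 - lam) * c_max
      D[, 2 + j] <- dcube(x - ki[j]) - lam * d_min - (1 - lam) * d_max
    }
  }
  list(basis = B, deriv = D)
}

#' Log-likelihood of the spline-on-log-cumulative-hazard model
#'
#' For subject i with follow-up time `t_i`, event indicator `d_i` and arm
#' `z_i`, write `eta_i = s(log t_i; gamma) + beta z_i` and
#' `H_i = exp(eta_i)`. The contribution is
#' `d_i * (log s'(log t_i; gamma) - log t_i + eta_i) - H_i`,
#' where `s'` is the derivative of the spline with respect to log time.
#' A non-positive `s'` at an event time means a negative fitted hazard;
#' the likelihood then returns a large negative penalty (soft barrier)
#' rather than an error, which keeps quasi-Newton optimisation in smooth
#' territory.
#'
#' @param gamma Spline coefficients, length `2 + n_internal`.
#' @param beta Log hazard ratio (research vs control).
#' @param ds A [survival_data] object.
#' @param knots A `"knot_set"`.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(gamma, beta, ds, knots) {
  parts <- flexpar_parts(ds, knots)
  if (length(gamma) != ncol(parts$B))
    stop_input(sprintf("gamma must have length %d for these knots",
                       ncol(parts$B)))
  -flexpar_negll(c(gamma, beta), parts)
}

# Internal: precompute the design pieces once per dataset.
flexpar_parts <- function(ds, knots) {
  x <- log(ds$time)
  bd <- rcs_basis(x, knots)
  ev <- ds$event == 1
  list(B = bd$basis, D = bd$deriv, z = ds$arm, ev = ev, logt = x,
       Bev = bd$basis[ev, , drop = FALSE],
       Dev = bd$deriv[ev, , drop = FALSE],
       logt_ev = x[ev], z_ev = ds$arm[ev])
}

# Negative log-likelihood with soft barrier for non-monotone splines.
flexpar_negll <- function(par, parts) {
  k <- ncol(parts$B)
  g <- par[seq_len(k)]
  b <- par[k + 1]
  sp_ev <- drop(parts$Dev %*% g)
  if (any(sp_ev <= 0))
    return(1e10 * (1 + sum(pmax(0, -sp_ev))))
  eta <- drop(parts$B %*% g) + b * parts$z
  H <- exp(eta)
  if (any(!is.finite(H))) return(1e10)
  eta_ev <- drop(parts$Bev %*% g) + b * parts$z_ev
  -(sum(log(sp_ev) - parts$logt_ev + eta_ev) - sum(H))
}

# Analytic gradient of the negative log-likelihood.
flexpar_negll_grad <- function(par, parts) {
  k <- ncol(parts$B)
  g <- par[seq_len(k)]
  b <- par[k + 1]
  sp_ev <- drop(parts$Dev %*% g)
  if (any(sp_ev <= 0)) {
    # gradient of the barrier term
    bar <- as.numeric(sp_ev <= 0)
    gg <- -1e10 * colSums(parts$Dev * bar)
    return(c(gg, 0))
  }
  eta <- drop(parts$B %*% g) + b * parts$z
  H <- exp(eta)
  gg <- colSums(parts$Dev / sp_ev) + colSums(parts$Bev) -
    drop(crossprod(parts$B, H))
  gb <- sum(parts$z_ev) - sum(H * parts$z)
  -c(gg, gb)
}

# Observed information at the optimum by central differences of the
# analytic gradient; step scaled to parameter magnitude.
flexpar_hessian <- function(par, parts) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- 1e-5 * max(1, abs(par[j]))
    up <- dn <- par
    up[j] <- par[j] + h
    dn[j] <- par[j] - h
    H[, j] <- (flexpar_negll_grad(up, parts) -
                 flexpar_negll_grad(dn, parts)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit the flexible parametric proportional-hazards model
#'
#' Maximum-likelihood fit by BFGS with the analytic gradient. Starting
#' values come from an exponential fit (`gamma = (log(events / total
#' follow-up), 1, 0, ...)`, `beta = 0`), under which the spline reduces to
#' a constant-hazard model; up to `max_restarts` jittered restarts are
#' attempted before a convergence error is raised. The joint covariance of
#' `(gamma, beta)` is the inverse observed information, with the
#' information matrix obtained by central differences of the analytic
#' gradient at the optimum.
#'
#' @param ds A [survival_data] object containing both arms.
#' @param n_internal Number of internal spline knots (default 2).
#' @param max_restarts Number of jittered restarts after a failed
#'   optimisation (default 3).
#' @return An object of class `"flexpar"` with elements `knots`, `gamma`,
#'   `beta`, `vcov` (joint, gamma first), `loglik`, `converged`,
#'   `n_events`, `n`.
#' @examples
#' ds <- simulate_trial(trial_design(s3_control = 0.6, n_per_arm = 200),
#'                      seed = 1)
#' fit <- fit_flexpar(ds)
#' summary(fit)
#' @export
fit_flexpar <- function(ds, n_internal = 2, max_restarts = 3) {
  check_two_arms(ds, require_event = TRUE)
  for (a in 0:1)
    if (sum(ds$event[ds$arm == a]) < 1)
      warning(sprintf("arm %d has no events; estimates may be unstable", a))
  knots <- place_knots(ds, n_internal)
  parts <- flexpar_parts(ds, knots)
  k <- ncol(parts$B)
  lambda0 <- max(sum(ds$event), 0.5) / sum(ds$time)
  start <- c(log(lambda0), 1, rep(0, k - 2), 0)
  fit <- NULL
  for (attempt in 0:max_restarts) {
    par0 <- if (attempt == 0) start else
      start + c(stats::rnorm(k, 0, 0.1), stats::rnorm(1, 0, 0.05))
    opt <- tryCatch(
      stats::optim(par0, flexpar_negll, flexpar_negll_grad, parts = parts,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt) || opt$value >= 1e9) next
    gr <- flexpar_negll_grad(opt$par, parts)
    if (max(abs(gr)) > 1e-3 * (1 + abs(opt$value))) next
    info <- flexpar_hessian(opt$par, parts)
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) <= 0)) next
    fit <- list(opt = opt, vcov = (vc + t(vc)) / 2)
    break
  }
  if (is.null(fit))
    stop_convergence(
      "flexible parametric model failed to converge after all restarts")
  par <- fit$opt$par
  structure(list(knots = knots,
                 gamma = par[seq_len(k)],
                 beta = par[k + 1],
                 vcov = fit$vcov,
                 loglik = -fit$opt$value,
                 converged = TRUE,
                 n_internal = n_internal,
                 n_events = sum(ds$event),
                 n = nrow(ds)),
            class = "flexpar")
}

#' @export
print.flexpar <- function(x, ...) {
  cat("Flexible parametric PH survival model\n")
  cat(sprintf("  %d subjects, %d events, %d internal knots, logLik %.3f\n",
              x$n, x$n_events, x$n_internal, x$loglik))
  se_beta <- sqrt(x$vcov[length(x$gamma) + 1, length(x$gamma) + 1])
  cat(sprintf("  HR = %.4f (log HR %.4f, SE %.4f)\n",
              exp(x$beta), x$beta, se_beta))
  invisible(x)
}

#' @export
summary.flexpar <- function(object, alpha = 0.025, ...) {
  k <- length(object$gamma)
  est <- c(object$gamma, object$beta)
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - alpha)
  tab <- data.frame(estimate = est, se = se,
                    ci_low = est - z * se, ci_high = est + z * se,
                    row.names = c(paste0("gamma", seq_len(k) - 1), "beta"))
  structure(list(table = tab, model = object, alpha = alpha),
            class = "summary.flexpar")
}

#' @export
print.summary.flexpar <- function(x, ...) {
  print(x$model)
  print(round(x$table, 4))
  invisible(x)
}

#' Predicted survival from a fitted flexible parametric model
#'
#' `S(t | arm) = exp(-exp(s(log t; gamma) + beta * arm))`; beyond the
#' boundary knots the spline continues linearly in log time.
#'
#' @param model A fitted `"flexpar"` object.
#' @param t Vector of strictly positive times (years).
#' @param arm 0 (control) or 1 (research).
#' @return Vector of survival probabilities.
#' @export
predict_survival <- function(model, t, arm) {
  if (any(t <= 0)) stop_input("t must be strictly positive")
  if (!all(arm %in% c(0, 1))) stop_input("arm must be 0 or 1")
  surv_from_par(c(model$gamma, model$beta), model$knots, t, arm)
}

# Internal: survival as a function of a free parameter vector, used both
# for prediction and for delta-method differentiation.
surv_from_par <- function(par, knots, t, arm) {
  k <- length(par) - 1
  B <- rcs_basis(log(t), knots)$basis
  eta <- drop(B %*% par[seq_len(k)]) + par[k + 1] * arm
  exp(-exp(eta))
}
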
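# Shared fixtures, all built in code.

# Two-arm exponential dataset with no censoring.
make_exp_data <- function(n_per_arm, lambda_c, hr = 1, seed = 1) {
  set.seed(seed)
  survival_data(
    time = c(rexp(n_per_arm, lambda_c), rexp(n_per_arm, hr * lambda_c)),
    event = rep(1, 2 * n_per_arm),
    arm = rep(c(0, 1), each = n_per_arm))
}

# A hand-sized dataset used across modules.
toy_data <- function() {
  survival_data(time = c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5),
                event = c(1, 1, 0, 1, 1, 0, 1, 1),
                arm = c(0, 0, 0, 0, 1, 1, 1, 1))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Flexpar object with a hand-set exponential-reduction parameterisation
# (no internal knots, gamma = (log lambda, 1)): H(t) = lambda t exp(beta z).
manual_exp_model <- function(lambda, beta, vcov = diag(1e-4, 3)) {
  structure(list(
    knots = structure(list(boundary = c(log(0.01), log(10)),
                           internal = numeric(0)), class = "knot_set"),
    gamma = c(log(lambda), 1), beta = beta, vcov = vcov,
    loglik = NA_real_, converged = TRUE, n_internal = 0,
    n_events = NA_integer_, n = NA_integer_), class = "flexpar")
}
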
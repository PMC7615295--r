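# Trial simulator: uniform accrual over `accrual_years`, exponential
# event times in each arm, administrative censoring at the analysis date
# `total_years` after the start of recruitment.

#' Exponential rate from a survival probability
#'
#' The constant hazard `lambda = -log(s) / t` under which survival at
#' time `t` equals `s`.
#'
#' @param s Survival probability in (0, 1).
#' @param t Time in years (> 0).
#' @return The hazard rate (per year).
#' @export
rate_from_survival <- function(s, t) {
  if (any(s <= 0 | s >= 1)) stop_input("s must lie strictly between 0 and 1")
  if (any(t <= 0)) stop_input("t must be positive")
  -log(s) / t
}

# Internal: arm sizes under the design's allocation ratio.
arm_sizes <- function(design) {
  n_c <- design$n_per_arm
  n_a <- as.integer(round(design$n_per_arm * design$allocation_ratio))
  c(control = n_c, research = n_a)
}

# Internal: split a total sample size by an allocation ratio r
# (research : control): research = round(n_total * r / (1 + r)),
# remainder to control.
split_total <- function(n_total, ratio) {
  n_a <- as.integer(round(n_total * ratio / (1 + ratio)))
  c(control = as.integer(n_total) - n_a, research = n_a)
}

#' Simulate one trial dataset
#'
#' Per subject: entry time `E ~ Uniform(0, accrual_years)`, event time
#' `T ~ Exponential(lambda_arm)` with
#' `lambda_C = -log(s3_control) / tau` and
#' `lambda_A = true_hr * lambda_C`, administrative censoring time
#' `C = total_years - E`. The record is `(min(T, C), 1{T <= C}, arm)`.
#' With `tau <= total_years - accrual_years`, no subject is censored
#' before `tau`. The `censor_at_tau` variant additionally applies
#' [censor_at()] at `tau` (analysis ignoring follow-up beyond the
#' horizon).
#'
#' @param design A [trial_design()].
#' @param seed Optional integer seed; when `NULL` the current RNG state
#'   is used (the study harness seeds each repetition itself).
#' @param variant `"all_data"` (default) or `"censor_at_tau"`.
#' @param n_arms Optional named integer vector `c(control =, research =)`
#'   overriding the design's arm sizes (used for designs specified by
#'   total sample size).
#' @return A [survival_data] object.
#' @export
simulate_trial <- function(design, seed = NULL,
                           variant = c("all_data", "censor_at_tau"),
                           n_arms = NULL) {
  variant <- match.arg(variant)
  if (!inherits(design, "trial_design"))
    stop_input("design must be a trial_design object")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_arms)) n_arms <- arm_sizes(design)
  lam_c <- rate_from_survival(design$s3_control, design$tau)
  lam_a <- design$true_hr * lam_c
  n <- sum(n_arms)
  arm <- rep(c(0, 1), times = n_arms[c("control", "research")])
  entry <- stats::runif(n, 0, design$accrual_years)
  tev <- stats::rexp(n, rate = ifelse(arm == 1, lam_a, lam_c))
  cens <- design$total_years - entry
  ds <- survival_data(time = pmin(tev, cens),
                      event = as.numeric(tev <= cens),
                      arm = arm)
  if (variant == "censor_at_tau") ds <- censor_at(ds, design$tau)
  ds
}

#' Designs of the two PATCH prostate-cancer cohorts
#'
#' PATCH compares transdermal oestradiol patches with standard
#' luteinising hormone-releasing hormone analogue injections for
#' androgen suppression in prostate cancer, and was split into two
#' non-inferiority trials: a non-metastatic cohort (primary outcome
#' metastasis-free survival, control 3-year survival 83%, 1345 patients,
#' HR margin 1.27) and a metastatic cohort (overall survival, control
#' 3-year survival 66%, 1500 patients, HR margin 1.19). Both use a
#' 1.08:1 research:control allocation and a one-sided 5% level. Arm
#' sizes split the total as `round(n_total * 1.08 / 2.08)` research,
#' remainder control.
#'
#' @param which `"non_metastatic"` or `"metastatic"`.
#' @return A list with elements `design` (a [trial_design()]), `n_arms`
#'   (named sizes), `hr_margin` and `alpha`.
#' @export
patch_design <- function(which = c("non_metastatic", "metastatic")) {
  which <- match.arg(which)
  p <- switch(which,
              non_metastatic = list(s3 = 0.83, n_total = 1345, hr = 1.27),
              metastatic = list(s3 = 0.66, n_total = 1500, hr = 1.19))
  n_arms <- split_total(p$n_total, 1.08)
  design <- trial_design(s3_control = p$s3, n_per_arm = n_arms[["control"]],
                         accrual_years = 3, total_years = 6, tau = 3,
                         true_hr = 1, allocation_ratio = 1.08)
  list(design = design, n_arms = n_arms, hr_margin = p$hr, alpha = 0.05)
}

#' Simulate one dataset from a PATCH cohort design
#'
#' Equal-arms (true HR 1) data under the cohort's design; see
#' [patch_design()].
#'
#' @param which `"non_metastatic"` or `"metastatic"`.
#' @param seed Integer seed (required for reproducibility).
#' @return A [survival_data] object.
#' @export
simulate_patch_cohort <- function(which = c("non_metastatic", "metastatic"),
                                  seed) {
  pd <- patch_design(which)
  simulate_trial(pd$design, seed = seed, n_arms = pd$n_arms)
}

#' Expected event probability per subject under the simulator
#'
#' For a subject with hazard `lambda`, uniform entry over
#' `[0, accrual]` and administrative censoring at `total`:
#' `P(event) = 1 - (exp(-lambda (total - accrual)) - exp(-lambda total))
#' / (lambda * accrual)`. If `horizon` is given (analysis censored at the
#' horizon, which every subject reaches), this is simply
#' `1 - exp(-lambda * horizon)`.
#'
#' @param lambda Hazard rate (per year).
#' @param accrual,total Accrual duration and analysis time, years.
#' @param horizon Optional censoring horizon applied at analysis.
#' @return Event probability.
#' @export
event_probability <- function(lambda, accrual = 3, total = 6,
                              horizon = NULL) {
  if (lambda <= 0) stop_input("lambda must be positive")
  if (!is.null(horizon)) return(1 - exp(-lambda * horizon))
  if (accrual <= 0) return(1 - exp(-lambda * total))
  1 - (exp(-lambda * (total - accrual)) - exp(-lambda * total)) /
    (lambda * accrual)
}
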
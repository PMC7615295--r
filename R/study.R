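# Monte-Carlo study harness: rejection rates (type-I error under the
# margin null, power under equal arms) for each summary measure and
# analysis method, with Monte-Carlo standard errors and
# discard-and-replace handling of convergence failures.

#' Define a non-inferiority simulation scenario
#'
#' A scenario couples a trial design with an HR margin (matched onto the
#' DRMST and DS scales via [match_margins()]) and a hypothesis: under
#' `"null"` the research-arm hazard sits at the margin
#' (`true_hr = hr_margin`, so rejection is a type-I error), under
#' `"alternative"` the arms are equal (`true_hr = 1`, rejection is
#' power).
#'
#' @param id Scenario label.
#' @param s3_control Control survival at `tau`.
#' @param n_per_arm Per-arm sample size (1:1 allocation), or `NULL` when
#'   `n_total` is given.
#' @param hr_margin Non-inferiority margin on the HR scale.
#' @param hypothesis `"null"` or `"alternative"`.
#' @param alpha One-sided level (default 0.025).
#' @param n_total Optional total sample size, split by
#'   `allocation_ratio`.
#' @param allocation_ratio Research : control ratio (default 1).
#' @param tau,accrual_years,total_years Design times in years.
#' @param true_hr Optional data-generating HR overriding the
#'   hypothesis-derived value (e.g. a superiority alternative with
#'   `hr_margin = 1` and `true_hr < 1`).
#' @return An object of class `"ni_scenario"`.
#' @export
ni_scenario <- function(id, s3_control, n_per_arm = NULL, hr_margin,
                        hypothesis = c("alternative", "null"),
                        alpha = 0.025, n_total = NULL,
                        allocation_ratio = 1, tau = 3, accrual_years = 3,
                        total_years = 6, true_hr = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(true_hr))
    true_hr <- if (hypothesis == "null") hr_margin else 1
  if (is.null(n_per_arm)) {
    if (is.null(n_total))
      stop_input("give either n_per_arm or n_total")
    n_arms <- split_total(n_total, allocation_ratio)
    n_per_arm <- n_arms[["control"]]
  } else {
    n_arms <- NULL
  }
  design <- trial_design(s3_control = s3_control, n_per_arm = n_per_arm,
                         accrual_years = accrual_years,
                         total_years = total_years, tau = tau,
                         true_hr = true_hr,
                         allocation_ratio = allocation_ratio)
  structure(list(id = id, design = design, hr_margin = hr_margin,
                 matched = match_margins(s3_control, hr_margin, tau),
                 hypothesis = hypothesis, alpha = alpha, n_arms = n_arms),
            class = "ni_scenario")
}

#' @export
print.ni_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario %s (%s): S(%g)=%g, n/control arm %d, HR margin %g, alpha %g\n",
    x$id, x$hypothesis, x$design$tau, x$design$s3_control,
    x$design$n_per_arm, x$hr_margin, x$alpha))
  invisible(x)
}

#' The twelve-scenario non-inferiority grid
#'
#' Exponential proportional-hazards designs with control 3-year survival
#' 90%, 60% or 20%, per-arm sample sizes 250/450/1000/3750,
#' 75/125/250/1000 and 50/75/150/450, and HR margins 2, 1.75, 1.5 and
#' 1.25 respectively, labelled 13 to 24; uniform accrual over 3 years,
#' analysis at 6 years, one-sided 2.5% tests.
#'
#' @param hypothesis `"alternative"` (power) or `"null"` (type-I error).
#' @return A list of [ni_scenario()] objects.
#' @export
ni_grid <- function(hypothesis = c("alternative", "null")) {
  hypothesis <- match.arg(hypothesis)
  s3 <- rep(c(0.9, 0.6, 0.2), each = 4)
  n <- c(250, 450, 1000, 3750, 75, 125, 250, 1000, 50, 75, 150, 450)
  hr <- rep(c(2, 1.75, 1.5, 1.25), times = 3)
  Map(function(id, s, nn, h)
    ni_scenario(id = id, s3_control = s, n_per_arm = nn, hr_margin = h,
                hypothesis = hypothesis),
    13:24, s3, n, hr)
}

#' The two PATCH cohort scenarios
#'
#' Power (equal-arms) scenarios for the two PATCH cohorts at their
#' design parameters and a one-sided 5% level; see [patch_design()].
#'
#' @return A list of [ni_scenario()] objects.
#' @export
patch_scenarios <- function() {
  lapply(c("non_metastatic", "metastatic"), function(w) {
    pd <- patch_design(w)
    ni_scenario(id = w, s3_control = pd$design$s3_control,
                hr_margin = pd$hr_margin, hypothesis = "alternative",
                alpha = pd$alpha,
                n_total = sum(pd$n_arms), allocation_ratio = 1.08)
  })
}

# Internal: deterministic per-repetition seed derived from the master
# seed, the scenario id and the repetition index, so repetitions are
# reproducible and individually replaceable. Kept within [1, 2^31 - 2]
# using multiplicative-congruential mixing (exact in doubles).
rep_seed <- function(master_seed, scenario_id, rep_index) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(scenario_id))) h <- (h * 31 + ch) %% m
  s <- abs(master_seed) %% m
  s <- (s * 48271) %% m
  s <- (s + h) %% m
  s <- (s * 48271) %% m
  s <- (s + rep_index) %% m
  s <- (s * 48271) %% m
  as.integer(s %% (m - 1) + 1)
}

# The eight result cells: measure x method (no non-parametric HR).
study_cells <- function(methods) {
  cells <- c(nonpar = list(c("drmst", "ds")),
             flex3 = list(c("hr", "drmst", "ds")),
             flexall = list(c("hr", "drmst", "ds")))[methods]
  unlist(lapply(names(cells), function(m) paste(m, cells[[m]], sep = "_")))
}

#' Run one simulation repetition of a scenario
#'
#' Simulates one trial (all data), then analyses it up to three ways:
#' non-parametric DRMST and DS on the data censored at `tau`
#' (`"nonpar"`; including later follow-up would not change these), and
#' the flexible parametric model fitted to the data censored at `tau`
#' (`"flex3"`) and to all data (`"flexall"`), each yielding HR, DRMST and
#' DS tests against the scenario's matched margins at the scenario's
#' one-sided level.
#'
#' A convergence failure in either flexible parametric fit raises a
#' condition of class `"nisurv_convergence_error"`, which
#' [run_scenario()] handles by discarding and replacing the repetition.
#'
#' @param scenario An [ni_scenario()].
#' @param rep_index Repetition index (determines the seed together with
#'   `master_seed` and the scenario id).
#' @param master_seed Integer master seed.
#' @param methods Subset of `c("nonpar", "flex3", "flexall")`.
#' @return Named logical vector of rejection indicators, one per
#'   measure-method cell.
#' @export
run_repetition <- function(scenario, rep_index, master_seed,
                           methods = c("nonpar", "flex3", "flexall")) {
  methods <- match.arg(methods, several.ok = TRUE)
  seed <- rep_seed(master_seed, scenario$id, rep_index)
  ds <- simulate_trial(scenario$design, seed = seed,
                       n_arms = scenario$n_arms)
  tau <- scenario$design$tau
  alpha <- scenario$alpha
  m <- scenario$matched
  ds3 <- censor_at(ds, tau)
  out <- c()
  analyse_flex <- function(data, prefix) {
    fit <- tryCatch(suppressWarnings(fit_flexpar(data)),
                    nisurv_input_error = function(e)
                      stop_convergence(conditionMessage(e)))
    res <- c(ni_test(hr_estimate(fit, alpha), m$hr, alpha)$reject,
             ni_test(flexpar_drmst(fit, tau, alpha), m$drmst, alpha)$reject,
             ni_test(flexpar_ds(fit, tau, alpha), m$ds, alpha)$reject)
    names(res) <- paste(prefix, c("hr", "drmst", "ds"), sep = "_")
    res
  }
  if ("nonpar" %in% methods) {
    out <- c(out,
             nonpar_drmst = ni_test(nonpar_drmst(ds3, tau, alpha), m$drmst,
                                    alpha)$reject,
             nonpar_ds = ni_test(nonpar_ds(ds3, tau, alpha), m$ds,
                                 alpha)$reject)
  }
  if ("flex3" %in% methods) out <- c(out, analyse_flex(ds3, "flex3"))
  if ("flexall" %in% methods) out <- c(out, analyse_flex(ds, "flexall"))
  out
}

#' Monte-Carlo rejection rates for one scenario
#'
#' Accumulates `n_reps` successful repetitions; repetitions in which a
#' flexible parametric fit fails to converge are discarded and replaced,
#' with replacement repetitions drawn from a reserved index stream
#' (indices above `n_reps`) so that the seeds of successful repetitions
#' do not depend on failures elsewhere. A replacement rate above 1%
#' triggers a warning.
#'
#' @inheritParams run_repetition
#' @param n_reps Number of successful repetitions required.
#' @return An object of class `"scenario_result"`: a data frame with one
#'   row per measure-method cell (`cell`, `rejections`, `n_reps`,
#'   `proportion`, `mcse`) carrying the scenario and the replacement
#'   count as attributes. `mcse = sqrt(p (1 - p) / n_reps)`.
#' @export
run_scenario <- function(scenario, n_reps, master_seed,
                         methods = c("nonpar", "flex3", "flexall")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_reps < 1) stop_input("n_reps must be at least 1")
  cells <- study_cells(methods)
  rejections <- stats::setNames(numeric(length(cells)), cells)
  replaced <- 0L
  next_replacement <- n_reps
  done <- 0L
  k <- 0L
  while (done < n_reps) {
    k <- k + 1L
    if (k <= n_reps) idx <- k
    else {
      next_replacement <- next_replacement + 1L
      idx <- next_replacement
    }
    if (replaced > 10 * n_reps)
      stop_convergence(sprintf(
        "scenario %s: more than %d replacements; scenario looks degenerate",
        scenario$id, 10 * n_reps))
    res <- tryCatch(
      run_repetition(scenario, idx, master_seed, methods),
      nisurv_convergence_error = function(e) NULL)
    if (is.null(res)) {
      replaced <- replaced + 1L
      next
    }
    rejections <- rejections + res[cells]
    done <- done + 1L
  }
  if (replaced > 0.01 * n_reps)
    warning(sprintf(
      "scenario %s: %d of %d repetitions replaced (> 1%%); check the design",
      scenario$id, replaced, n_reps))
  p <- rejections / n_reps
  out <- data.frame(cell = cells, rejections = unname(rejections),
                    n_reps = n_reps, proportion = unname(p),
                    mcse = unname(sqrt(p * (1 - p) / n_reps)))
  attr(out, "scenario") <- scenario
  attr(out, "replaced") <- replaced
  class(out) <- c("scenario_result", "data.frame")
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Scenario %s (%s), %d repetitions (%d replaced)\n",
              sc$id, sc$hypothesis, x$n_reps[1], attr(x, "replaced")))
  df <- as.data.frame(x)
  df$percent <- sprintf("%.2f%%", 100 * df$proportion)
  print(df[, c("cell", "percent", "mcse")], row.names = FALSE)
  invisible(x)
}

#' Run a list of scenarios and tabulate rejection rates
#'
#' One row per scenario in the layout of the replication tables: design
#' parameters, the three matched margins, then the rejection percentage
#' for each measure-method cell. Under the null hypothesis, cells with
#' type-I error above 3% are flagged in a `flagged` column.
#'
#' @param scenarios List of [ni_scenario()] objects.
#' @param n_reps Repetitions per scenario.
#' @param master_seed Integer master seed.
#' @param out Optional CSV path to write the table to.
#' @param methods Subset of `c("nonpar", "flex3", "flexall")`.
#' @return A data frame (invisibly written to `out` when given).
#' @export
run_table <- function(scenarios, n_reps, master_seed, out = NULL,
                      methods = c("nonpar", "flex3", "flexall")) {
  methods <- match.arg(methods, several.ok = TRUE)
  cells <- study_cells(methods)
  rows <- lapply(scenarios, function(sc) {
    res <- run_scenario(sc, n_reps, master_seed, methods)
    p <- stats::setNames(res$proportion, res$cell)
    row <- data.frame(scenario = sc$id,
                      s3_control = sc$design$s3_control,
                      n_per_arm = sc$design$n_per_arm,
                      hr_margin = sc$hr_margin,
                      drmst_margin = sc$matched$drmst,
                      ds_margin_pct = 100 * sc$matched$ds,
                      n_reps = n_reps,
                      replaced = attr(res, "replaced"))
    for (cl in cells) row[[paste0(cl, "_pct")]] <- 100 * p[[cl]]
    row$flagged <- if (sc$hypothesis == "null")
      paste(cells[p[cells] > 0.03], collapse = ";") else ""
    row
  })
  if (length(rows) == 0) {
    tab <- data.frame(scenario = character(0), s3_control = numeric(0),
                      n_per_arm = integer(0), hr_margin = numeric(0),
                      drmst_margin = numeric(0), ds_margin_pct = numeric(0),
                      n_reps = integer(0), replaced = integer(0))
    for (cl in cells) tab[[paste0(cl, "_pct")]] <- numeric(0)
    tab$flagged <- character(0)
  } else {
    tab <- do.call(rbind, rows)
  }
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

#' Analytic power approximation for the HR non-inferiority test
#'
#' Schoenfeld's events-based approximation under equal arms:
#' `power = pnorm(sqrt(E / 4) * |log(hr_margin)| - qnorm(1 - alpha))`
#' where `E = 2 * n_per_arm * event_prob_per_arm` is the expected total
#' number of events. Used as an independent cross-check of the
#' simulation harness.
#'
#' @param n_per_arm Per-arm sample size.
#' @param event_prob_per_arm Event probability per subject (see
#'   [event_probability()]).
#' @param hr_margin Margin on the HR scale.
#' @param alpha One-sided level (default 0.025).
#' @return Approximate power (probability).
#' @export
schoenfeld_power <- function(n_per_arm, event_prob_per_arm, hr_margin,
                             alpha = 0.025) {
  if (event_prob_per_arm <= 0 || event_prob_per_arm >= 1)
    stop_input("event_prob_per_arm must lie strictly between 0 and 1")
  e_total <- 2 * n_per_arm * event_prob_per_arm
  stats::pnorm(sqrt(e_total / 4) * abs(log(hr_margin)) -
                 stats::qnorm(1 - alpha))
}

#' Read a list of scenarios from a YAML file
#'
#' The file holds a `scenarios:` list whose entries carry the arguments
#' of [ni_scenario()].
#'
#' @param path Path to a YAML file.
#' @return A list of `ni_scenario` objects.
#' @export
read_scenarios_yaml <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios))
    stop_input(sprintf("no 'scenarios:' list in %s", path))
  lapply(cfg$scenarios, function(s) do.call(ni_scenario, s))
}
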
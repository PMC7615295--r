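# Error condition helpers: conditions carry classes so the CLI can map them
# to exit codes and the study harness can recognise convergence failures.

stop_input <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("nisurv_input_error", "nisurv_error"),
                      call = call))
}

stop_numeric <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("nisurv_numeric_error", "nisurv_error"),
                      call = call))
}

stop_convergence <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c("nisurv_convergence_error", "nisurv_error"),
                      call = call))
}

#' Per-subject survival data for a two-arm trial
#'
#' Construct and validate a set of per-subject follow-up records. Each
#' record is a follow-up time since randomisation (in years), an event
#' indicator (1 = event observed, 0 = censored) and an arm label
#' (0 = control, 1 = research). Contrasts computed elsewhere in the
#' package are always research minus control (differences) or research
#' over control (ratios).
#'
#' @param time Numeric vector of strictly positive, finite follow-up times
#'   in years.
#' @param event Integer/numeric vector of event indicators in \{0, 1\}.
#' @param arm Integer/numeric vector of arm labels in \{0, 1\}
#'   (0 = control, 1 = research).
#' @param label Optional free-text label carried along for printing.
#' @return A data frame of class `"survival_data"` with columns
#'   `time`, `event`, `arm`.
#' @examples
#' ds <- survival_data(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
#'                     arm = c(0, 0, 1, 1))
#' n_events(ds)
#' @export
survival_data <- function(time, event, arm, label = NULL) {
  n <- length(time)
  if (n == 0L) stop_input("survival data must contain at least one record")
  if (length(event) != n || length(arm) != n)
    stop_input("time, event and arm must have equal length")
  time <- as.numeric(time)
  event <- as.numeric(event)
  arm <- as.numeric(arm)
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    stop_input(sprintf(
      "time must be strictly positive and finite (first offending row: %d)",
      bad[1]))
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad))
    stop_input(sprintf("event must be 0 or 1 (first offending row: %d)",
                       bad[1]))
  bad <- which(!(arm %in% c(0, 1)))
  if (length(bad))
    stop_input(sprintf("arm must be 0 or 1 (first offending row: %d)",
                       bad[1]))
  out <- data.frame(time = time, event = event, arm = arm)
  class(out) <- c("survival_data", "data.frame")
  attr(out, "label") <- label
  out
}

#' @export
print.survival_data <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Survival dataset", if (!is.null(lab)) paste0("'", lab, "'") else "",
      "\n")
  cat(sprintf("  %d subjects (%d control, %d research), %d events\n",
              nrow(x), sum(x$arm == 0), sum(x$arm == 1), sum(x$event)))
  invisible(x)
}

#' @rdname survival_data
#' @param ds A `survival_data` object.
#' @export
n_events <- function(ds) sum(ds$event)

# Internal: checks needed before any two-arm estimation. Model fitting
# additionally refuses datasets without any event.
check_two_arms <- function(ds, require_event = FALSE) {
  if (!all(c(0, 1) %in% ds$arm))
    stop_input("both arms (0 = control, 1 = research) must be present")
  if (require_event && sum(ds$event) < 1)
    stop_input("at least one event is required for model fitting")
  invisible(ds)
}

#' Read per-subject survival records from a CSV file
#'
#' Reads a delimited text file with a header and returns a validated
#' [survival_data] object. Column names default to `time`, `event`, `arm`
#' and can be remapped; arm labels other than 0/1 (for example `"C"` and
#' `"A"`) can be recoded through `arm_map`.
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param columns Named character vector mapping the roles `time`, `event`
#'   and `arm` to column names in the file.
#' @param arm_map Optional named vector recoding arm labels to 0/1, e.g.
#'   `c(C = 0, A = 1)`.
#' @param label Label for the dataset; defaults to the file name.
#' @return A `survival_data` object; row order is preserved.
#' @export
read_survival_csv <- function(path,
                              columns = c(time = "time", event = "event",
                                          arm = "arm"),
                              arm_map = NULL,
                              label = basename(path)) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  defaults <- c(time = "time", event = "event", arm = "arm")
  defaults[names(columns)] <- columns
  columns <- defaults
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop_input(sprintf("missing column(s) in %s: %s", path,
                       paste(missing_cols, collapse = ", ")))
  arm <- raw[[columns[["arm"]]]]
  if (!is.null(arm_map)) {
    m <- match(as.character(arm), names(arm_map))
    if (anyNA(m))
      stop_input(sprintf(
        "arm value not covered by arm_map (first offending row: %d)",
        which(is.na(m))[1]))
    arm <- unname(arm_map[m])
  }
  survival_data(time = raw[[columns[["time"]]]],
                event = raw[[columns[["event"]]]],
                arm = arm, label = label)
}

#' Write survival records to CSV
#'
#' @param ds A `survival_data` object.
#' @param path Output file path.
#' @return `path`, invisibly. Times are written at full precision so that
#'   a read/write round trip preserves every record exactly.
#' @export
write_survival_csv <- function(ds, path) {
  df <- data.frame(time = format(ds$time, digits = 17, trim = TRUE),
                   event = ds$event, arm = ds$arm)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Administratively censor a dataset at a horizon
#'
#' Every record with follow-up beyond `horizon` becomes censored at the
#' horizon; records with `time <= horizon` are unchanged, so an event at
#' exactly the horizon still counts as an event (closed interval).
#' The operation is idempotent and composing two horizons is equivalent to
#' censoring at the smaller of the two.
#'
#' @param ds A `survival_data` object.
#' @param horizon Positive censoring horizon in years.
#' @return A `survival_data` object of the same size.
#' @export
censor_at <- function(ds, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1 || !is.finite(horizon) ||
      horizon <= 0)
    stop_input("horizon must be a single positive number")
  over <- ds$time > horizon
  ds$event[over] <- 0
  ds$time[over] <- horizon
  ds
}

#' Trial design parameters
#'
#' Describes a two-arm non-inferiority/superiority trial design with
#' uniform accrual, exponential event times and administrative censoring
#' at the analysis date: subjects enter uniformly over `accrual_years`
#' and the analysis happens `total_years` after the start of recruitment,
#' so potential follow-up is uniform on
#' `[total_years - accrual_years, total_years]`. The constraint
#' `tau <= total_years - accrual_years` guarantees every subject has at
#' least `tau` years of potential follow-up.
#'
#' @param s3_control Control-arm survival probability at `tau`, in (0, 1).
#' @param n_per_arm Control-arm sample size (research arm is
#'   `round(n_per_arm * allocation_ratio)`).
#' @param accrual_years Duration of uniform recruitment, years.
#' @param total_years Time from start of recruitment to analysis, years.
#' @param tau Horizon at which the summary measures are defined, years.
#' @param true_hr Data-generating hazard ratio, research : control.
#' @param allocation_ratio Research : control randomisation ratio.
#' @return An object of class `"trial_design"`.
#' @export
trial_design <- function(s3_control, n_per_arm, accrual_years = 3,
                         total_years = 6, tau = 3, true_hr = 1,
                         allocation_ratio = 1) {
  if (!is.numeric(s3_control) || s3_control <= 0 || s3_control >= 1)
    stop_input("s3_control must lie strictly between 0 and 1")
  n_per_arm <- as.integer(n_per_arm)
  if (is.na(n_per_arm) || n_per_arm < 2)
    stop_input("n_per_arm must be an integer >= 2")
  if (accrual_years < 0 || accrual_years >= total_years)
    stop_input("need 0 <= accrual_years < total_years")
  if (tau <= 0 || tau > total_years - accrual_years)
    stop_input("need 0 < tau <= total_years - accrual_years")
  if (true_hr <= 0) stop_input("true_hr must be positive")
  if (allocation_ratio <= 0) stop_input("allocation_ratio must be positive")
  structure(list(s3_control = s3_control, n_per_arm = n_per_arm,
                 accrual_years = accrual_years, total_years = total_years,
                 tau = tau, true_hr = true_hr,
                 allocation_ratio = allocation_ratio),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Trial design\n")
  cat(sprintf("  control S(%g) = %g, %d per control arm (allocation %g:1)\n",
              x$tau, x$s3_control, x$n_per_arm, x$allocation_ratio))
  cat(sprintf("  accrual %g y, analysis at %g y, true HR %g\n",
              x$accrual_years, x$total_years, x$true_hr))
  invisible(x)
}

#' Read a trial design from a YAML configuration file
#'
#' The file must contain a `design:` block whose keys are the arguments
#' of [trial_design()].
#'
#' @param path Path to a YAML file.
#' @return A `trial_design` object.
#' @export
read_design_yaml <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design))
    stop_input(sprintf("no 'design:' block in %s", path))
  do.call(trial_design, cfg$design)
}
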
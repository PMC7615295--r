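# Matching non-inferiority margins across the three summary-measure
# scales. Under an exponential control reference with rate
# lambda_C = -log(s) / tau and a boundary research arm with rate
# hr * lambda_C, the same boundary curve is described by an HR margin, a
# DRMST margin (restricted mean survival years lost) and a DS margin
# (survival probability lost at tau).

#' Match a non-inferiority margin across summary-measure scales
#'
#' Given the control-arm survival at the horizon and an HR margin, finds
#' the DRMST and DS margins that describe the same boundary survival
#' curve. By default both arms are exponential (the reference under which
#' the trial designs considered here were constructed); a user-supplied
#' control survival function generalises this, with the research boundary
#' curve `S_C(t)^hr` and the two restricted means evaluated numerically.
#'
#' Losses are reported positive for `hr_margin > 1`; for `hr_margin < 1`
#' they come out negative (a mirrored, advantageous boundary).
#'
#' @param s_tau_control Control survival probability at `tau`, in (0, 1).
#' @param hr_margin Hazard-ratio margin (> 0; > 1 for a genuine
#'   non-inferiority margin).
#' @param tau Horizon in years (default 3).
#' @param control_surv Optional vectorised control survival function
#'   `S_C(t)`; when supplied it overrides the exponential reference (and
#'   `s_tau_control` is taken from `control_surv(tau)`).
#' @return An object of class `"matched_margins"` with elements
#'   `s_tau_control`, `tau`, `hr`, `drmst` (years), `ds` (probability).
#' @examples
#' match_margins(s_tau_control = 0.9, hr_margin = 2, tau = 3)
#' @export
match_margins <- function(s_tau_control, hr_margin, tau = 3,
                          control_surv = NULL) {
  if (hr_margin <= 0) stop_input("hr_margin must be positive")
  if (tau <= 0) stop_input("tau must be positive")
  if (is.null(control_surv)) {
    if (s_tau_control <= 0 || s_tau_control >= 1)
      stop_input("s_tau_control must lie strictly between 0 and 1")
    s <- s_tau_control
    lam_c <- -log(s) / tau
    lam_a <- hr_margin * lam_c
    ds <- s - s^hr_margin
    drmst <- (1 - s) / lam_c - (1 - s^hr_margin) / lam_a
  } else {
    s <- control_surv(tau)
    gl <- gl_rule(tau, 64)
    sc <- control_surv(gl$x)
    sa <- sc^hr_margin
    ds <- s - s^hr_margin
    drmst <- sum(gl$w * (sc - sa))
  }
  structure(list(s_tau_control = s, tau = tau, hr = hr_margin,
                 drmst = drmst, ds = ds),
            class = "matched_margins")
}

#' @export
print.matched_margins <- function(x, ...) {
  cat(sprintf("Matched non-inferiority margins at tau = %g y (control S = %g)\n",
              x$tau, x$s_tau_control))
  cat(sprintf("  HR    : %.4g\n", x$hr))
  cat(sprintf("  DRMST : %.4g years\n", x$drmst))
  cat(sprintf("  DS    : %.4g percentage points\n", 100 * x$ds))
  invisible(x)
}

#' Back-calculate an HR margin from a DRMST or DS margin
#'
#' Finds, by monotone root-finding, the hazard-ratio margin whose matched
#' margins (under the exponential control reference) reproduce the given
#' loss on the target scale. Round-trips with [match_margins()] to 1e-10.
#'
#' @param s_tau_control Control survival probability at `tau`.
#' @param tau Horizon in years.
#' @param target `"drmst"` or `"ds"`.
#' @param margin_value Positive loss on the target scale (years for
#'   DRMST, probability for DS).
#' @return The HR margin (scalar).
#' @examples
#' invert_margin(0.83, 3, "ds", 0.04)  # about 1.27
#' @export
invert_margin <- function(s_tau_control, tau, target = c("drmst", "ds"),
                          margin_value) {
  target <- match.arg(target)
  if (s_tau_control <= 0 || s_tau_control >= 1)
    stop_input("s_tau_control must lie strictly between 0 and 1")
  if (margin_value <= 0) stop_input("margin_value must be positive")
  s <- s_tau_control
  lam_c <- -log(s) / tau
  sup <- if (target == "ds") s else (1 - s) / lam_c
  if (margin_value >= sup)
    stop_input(sprintf(
      "%s margin %g is unattainable (supremum %g as the HR margin grows)",
      target, margin_value, sup))
  f <- function(h) match_margins(s, h, tau)[[target]] - margin_value
  hi <- 2
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1, hi), tol = 1e-12)$root
}
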
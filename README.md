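# nisurv

Population-level summary measures for two-arm randomised trials with
time-to-event outcomes, with a focus on non-inferiority testing.

Clinical trials with survival endpoints are usually designed around the
hazard ratio (HR), but the difference in restricted mean survival time

    DRMST(τ) = ∫₀^τ S_A(t) dt − ∫₀^τ S_C(t) dt

and the difference in survival at a fixed time point

    DS(τ) = S_A(τ) − S_C(τ)

are increasingly attractive absolute alternatives (here `A` is the
research arm, `C` the control arm). For non-inferiority trials the
choice matters: each summary measure carries its own null hypothesis,
and a fair comparison requires both *matched margins* (margins on
different scales describing the same boundary survival curve) and a
*common estimation model*.

`nisurv` provides the pieces needed to make, and to study, that
comparison:

* **One model, three measures.** A flexible parametric
  proportional-hazards survival model — a restricted cubic spline
  `s(ln t; γ)` for the log cumulative baseline hazard, so that
  `log H(t | arm) = s(ln t; γ) + β·arm` — fitted by maximum likelihood
  (`fit_flexpar()`). The HR is `exp(β)`; `DRMST(τ)` and `DS(τ)` are
  post-processed from the fitted parameters with delta-method standard
  errors (`hr_estimate()`, `flexpar_drmst()`, `flexpar_ds()`).
* **Non-parametric reference estimators.** Kaplan–Meier curves with the
  Greenwood variance, the KM restricted mean with the standard
  product-limit RMST variance, and the simple difference in proportions
  with a binomial Wald interval (`kaplan_meier()`, `km_rmst()`,
  `nonpar_drmst()`, `nonpar_ds()`).
* **Margin matching.** Translation of a non-inferiority margin between
  the HR, DRMST and DS scales under an exponential control-arm
  reference, in both directions (`match_margins()`, `invert_margin()`).
* **One-sided tests.** Non-inferiority (or superiority) Wald tests on
  the appropriate scale for each measure (`ni_test()`).
* **A trial simulator and Monte-Carlo harness.** Uniform accrual,
  exponential event times, administrative censoring
  (`simulate_trial()`); rejection-rate estimation with Monte-Carlo
  standard errors and discard-and-replace convergence handling
  (`run_scenario()`, `run_table()`), plus the analytic Schoenfeld
  events-based power cross-check (`schoenfeld_power()`).

## Worked example

Simulate one non-inferiority trial (250 per arm, control 3-year
survival 90%, equal arms), censor the analysis at τ = 3 years, and test
each measure against margins matched to an HR margin of 2:

```r
library(nisurv)

design <- trial_design(s3_control = 0.9, n_per_arm = 250, true_hr = 1)
ds     <- simulate_trial(design, seed = 42)
ds3    <- censor_at(ds, 3)

margins <- match_margins(s_tau_control = 0.9, hr_margin = 2, tau = 3)
margins
#> Matched non-inferiority margins at tau = 3 y (control S = 0.9)
#>   HR    : 2
#>   DRMST : 0.1424 years
#>   DS    : 9 percentage points

fit <- fit_flexpar(ds3)          # spline PH model, 2 internal knots
fit
#> Flexible parametric PH survival model
#>   500 subjects, 62 events, 2 internal knots, logLik -252.173
#>   HR = 1.1398 (log HR 0.1309, SE 0.2545)

ni_test(flexpar_drmst(fit, tau = 3), margin = margins$drmst)
#> DRMST(3) [flexpar]: -0.0235 (SE 0.0457 on identity scale, 95% CI -0.1131 to 0.0661)
#>   non-inferiority margin 0.1424, one-sided alpha 0.025: z = 2.601 -> non-inferiority concluded

ni_test(nonpar_drmst(ds3, tau = 3), margin = margins$drmst)
#> DRMST(3) [nonparametric]: -0.0043 (SE 0.0507 on identity scale, 95% CI -0.1036 to 0.0950)
#>   non-inferiority margin 0.1424, one-sided alpha 0.025: z = 2.726 -> non-inferiority concluded
```

The DRMST estimate is the research-minus-control difference in mean
survival over the first 3 years (here −0.02 years, i.e. about a week in
favour of control, with non-inferiority comfortably concluded against a
margin of 0.14 years). Operating characteristics over repeated trials
come from the harness:

```r
sc  <- ni_scenario(13, s3_control = 0.9, n_per_arm = 250, hr_margin = 2,
                   hypothesis = "alternative")
res <- run_scenario(sc, n_reps = 2000, master_seed = 20230620)
res
#> Scenario 13 (alternative), 2000 repetitions (0 replaced)
#>           cell percent        mcse
#>   nonpar_drmst  84.55% 0.008081762
#>      nonpar_ds  92.80% 0.005779965
#>       flex3_hr  68.00% 0.010430724
#>    flex3_drmst  92.90% 0.005742778
#>       flex3_ds  92.55% 0.005871531
#>     flexall_hr  84.20% 0.008155857
#>  flexall_drmst  97.90% 0.003206166
#>     flexall_ds  97.65% 0.003387311
```

Each row is the power of one measure/method combination: `nonpar_*` are
the non-parametric tests, `flex3_*` the flexible parametric model on
data censored at 3 years, `flexall_*` the same model on all follow-up.
Estimating DRMST under proportional hazards (92.9%) is markedly more
powerful than estimating it non-parametrically (84.6%), and using all
the data adds more power again (97.9%).

A command-line wrapper covering fitting, margin matching, simulation
and study runs is installed at `inst/cli/nisurv`:

```sh
Rscript inst/cli/nisurv match-margins --s-control 0.9 --hr 2 --tau 3
Rscript inst/cli/nisurv simulate --s-control 0.9 --n-per-arm 250 \
    --hr 1 --seed 1 --out trial.csv
Rscript inst/cli/nisurv fit --data trial.csv --tau 3
```

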
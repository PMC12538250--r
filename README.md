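# hpburden

Quantifying what a reimbursement delay costs a diagnosed cohort, in lives
and in productivity.

When an authorised medicine waits for reimbursement, diagnosed patients
age without access to it.  Because mortality rises with age, the cohort
that finally gets (or never gets) the drug faces the death probabilities
of an older cohort.  `hpburden` implements a complete, testable pipeline
for that mechanism, aimed at health-policy analysts and pharmaco-economic
modellers:

1. **Mortality law.**  The eight-parameter Heligman–Pollard model

   $$q_x = A\,(x+B)^C + D\,e^{-E(\ln x - \ln F)^2} + \frac{G H^x}{1+G H^x}$$

   is fitted to an observed schedule of age-specific death probabilities
   by loss-function optimisation (`fit_hp()`, eight predefined losses),
   with a binomial deviance goodness-of-fit test (`deviance_gof()`) and
   parametric-bootstrap confidence intervals and p-values
   (`bootstrap_fit()`).
2. **Cohort propagation.**  The life-table recursion
   $d_x = l_x q_x$, $l_{x+1} = l_x - d_x$ propagates an initial cohort
   from the *delay-shifted* diagnosis age
   $x = \text{age of diagnosis} + \text{delay}$
   (`propagate_cohort()`, `policy_scenario()`), on annual or quarterly
   grids, with remaining life expectancy derived from the survivorship
   curve.
3. **Burden metrics.**  Deaths become years of life lost
   $\mathrm{YLL} = \sum_x d_x e_x$ (`compute_yll()`), years of potential
   productive life lost
   $\mathrm{YPPLL} = \sum_j d_j(\text{retirement age} - \text{mean age}_j)$
   over five-year bands (`compute_yppll()`), and the cost of productivity
   loss $\mathrm{CPL} = \mathrm{YPPLL} \times \text{GDP per capita}$
   (`compute_cpl()`), singly (`burden_report()`) or across a sweep of
   delays (`delay_sweep()`).

A synthetic-data generator (`simulate_schedule()`,
`simulate_trial_like()`) supplies binomially noisy mortality schedules
and stochastic cohorts around a known curve, so the entire pipeline is
testable without access to any proprietary cohort data.  A thin CLI over
the same functions lives in `inst/cli/hpburden.R`
(subcommands `run`, `fit`, `simulate`, `lifetable`, `burden`, `sweep`).

## Worked example

Simulate a daily-resolution schedule around the reference curve, retain
the four quarter points of each year, fit, and compute the burden of a
two-year delay for a cohort of 160,000 diagnosed at 45:

```r
library(hpburden)

sched     <- simulate_schedule(synthetic_config(grid = "daily",
                                                exposure_per_age = 1e4,
                                                seed = 42))
quarterly <- to_quarterly_grid(sched)     # 164 ages: 45, 45.25, ..., 85.75
fit       <- fit_hp(quarterly)
fit
#> Heligman-Pollard fit (loss 'relative_sse', 164 ages, converged)
#> ...
#> deviance GOF: 158.2911 on 156 df, p = 0.4338

report <- burden_report(fit$params, policy_scenario(45, delay = 2),
                        mode = "replication")
report
#> Burden report (replication mode, start age 47, delay 2 y):
#>   YLL   525791.175 person-years
#>   YPPLL 2592898.361 person-years
#>   CPL   44979007869.11 EUR
```

The deviance near its 156 degrees of freedom (p = 0.43) says the fitted
curve is statistically compatible with the simulated counts.  The report
reads: under the aggressive replication-mode propagation, the cohort
diagnosed at 45 but starting two years late loses about 526k person-years
of life; 2.59M productive person-years vanish before the retirement age
of 67, worth about €45.0bn at a GDP per capita of €17,347.

Sweeping the delay re-runs the whole propagation per value:

```r
delay_sweep(fit$params, policy_scenario(45), delays = c(0, 1, 2, 5),
            mode = "replication")
```

With longer delays the first year after diagnosis kills strictly more
patients (the curve is increasing in age), while total YLL falls because
the cohort's remaining horizon shrinks — which is why first-year deaths,
not the YLL total, is the sharp signal of delay damage.

See `vignettes/delayed-access-burden.Rmd` for the model assumptions,
propagation conventions, identifiability caveats and design choices.

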
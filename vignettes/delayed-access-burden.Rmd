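---
title: "Modelling the mortality and productivity burden of delayed access to medicines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the mortality and productivity burden of delayed access to medicines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpburden)
```

## The problem

When a medicine is authorised but not yet reimbursed, diagnosed patients
wait.  During that wait they age, and because mortality rises with age,
each year of delay exposes the cohort to higher death probabilities than
it would have faced with immediate access.  `hpburden` quantifies that
mechanism: it models age-specific mortality parametrically, propagates a
diagnosed cohort along the fitted curve starting at the *delay-shifted*
diagnosis age, and converts the resulting deaths into three standard
population-health quantities:

* **YLL** (years of life lost): each death weighted by the remaining life
  expectancy at the age of death;
* **YPPLL** (years of potential productive life lost): deaths grouped into
  five-year age bands, weighted by the productive years remaining before
  the retirement age;
* **CPL** (cost of productivity loss): YPPLL valued at GDP per capita
  under the human-capital approach.

The delay is a *policy variable*: when a health policy guarantees access
(`health_policy = 1`), the effective delay is zero; otherwise the cohort's
starting age is shifted by the delay, in years (day-denominated
administrative delays are converted at 365.25 days per year at the I/O
boundary).

## The mortality model

The Heligman--Pollard (HP) law expresses the probability $q_x$ that a
person of exact age $x$ dies before age $x+1$ as a sum of three
interpretable components,

$$
q_x = A\,(x+B)^C
    + D\,\exp\!\big\{-E\,(\ln x-\ln F)^2\big\}
    + \frac{G\,H^x}{1+G\,H^x},
$$

a childhood-decline term (level $A$, offset $B$ years, decline rate $C$),
a lognormal accident hump (severity $D$, concentration $E$, peak age $F$
years), and a logistic-bounded Gompertz senescent term (level $G$, rate
$H$).  All eight parameters are non-negative; $H>1$ whenever mortality
rises with age.  The raw sum can exceed one at extreme ages, so evaluated
probabilities are clamped at $1-10^{-12}$ with a warning; nothing in the
45--86 window used below comes near the clamp.  Ages are real-valued
everywhere -- the law is routinely evaluated on quarterly and daily grids.

On the cardiovascular study window of ages 45--86 the senescent term
dominates by roughly two orders of magnitude (a ratio of about 60 at age
45, growing with age).  This has a consequence that shapes much of the
package's design: **the childhood and hump parameters are not identified
by data on this window.**  The fitted *curve* is extremely well
determined, and so are $G$ and $H$, but $A$--$F$ can wander over orders
of magnitude between fits of essentially identical quality.  Reports and
tests therefore focus on predictive recovery and on the senescent
parameters.

## Fitting

`fit_hp()` estimates the eight parameters by minimising one of eight
predefined losses (`hp_loss_names()`), the default being the classic
relative squared error $\sum_x (1-\hat q_x/q_x)^2$.  The registry also
contains the absolute and log squared errors, a Pearson-type weighted
squared error, the binomial and Poisson deviances of observed against
expected deaths, and two absolute-error variants.  The set spans the loss
families found in standard mortality-law software; the deviances connect
the fit directly to the goodness-of-fit test below.

Numerically, optimisation runs on a working scale -- $\log$ of each
parameter, $\log(H-1)$ for $H$ -- so positivity and $H>1$ hold by
construction, inside box bounds of $[10^{-12},10^6]$ for each parameter
except $C \le 200$ and $H \le 2$.  The six residual-form losses use
Levenberg--Marquardt with an analytic Jacobian; the two absolute-error
losses use Nelder--Mead with an L-BFGS-B polish.  Convergence is declared
at a relative objective change of $10^{-10}$ (`control$ftol`).  Because
the weakly identified parameters form a long flat valley, the iteration
cap can be reached while the objective still creeps; the fitter then
warm-restarts the search (which resets the trust-region damping) up to
four times and accepts stagnation below $10^{-7}$ relative improvement as
convergence.  A start outside the box -- for instance a multiplicatively
perturbed $H$ dipping below 1 -- is projected onto it rather than
rejected.  A failed search never returns anything worse than its start.

The HP objectives are multimodal, so the default start matters: it is
`hp_params_reference()`, a fitted parameter set appropriate for at-risk
cardiovascular cohorts on 45--86, which doubles as the synthetic
generator's default truth.

### Goodness of fit

`deviance_gof()` compares observed to expected deaths with the binomial
deviance
$D = 2\sum_i\big[d_i\ln(d_i/\hat e_i)+(n_i-d_i)\ln\{(n_i-d_i)/(n_i-\hat e_i)\}\big]$,
$\hat e_i = n_i\hat q_i$, with $0\ln(0/\cdot)=0$, referred to
$\chi^2_{\,\#\text{ages}-8}$.  The test suite verifies its calibration by
simulation: under correctly specified binomial sampling at exposure
$10^4$ over 164 quarterly ages, with the model refitted by deviance
minimisation per replicate, the rejection rate at $\alpha=0.05$ sits near
the nominal level (the acceptance run uses 500 replicates).

### Bootstrap inference

`bootstrap_fit()` provides percentile confidence intervals by parametric
bootstrap: deaths are redrawn as $\text{Binomial}(n_i,\hat q_i)$ and the
model is refitted *from the same starting values as the point fit*.  This
choice is deliberate and matters.  Warm-starting replicate refits at the
point estimate looks cheaper but understates uncertainty badly on this
age window: the information matrix is numerically rank-deficient, and the
sampling variability of $\hat H$ flows largely through a trade-off with
the childhood term that warm-started refits never explore.  In pilot
measurements at exposure $10^6$ the full-model standard error of $\hat H$
is roughly $1.4\times10^{-4}$, against $2\times10^{-5}$ if $G,H$ alone
are considered free; warm-started bootstrap spreads matched the latter
and halved the coverage of nominal 95% intervals.  Cold-started refits
reproduce the Monte-Carlo sampling spread and restore nominal coverage.

Replicate fits that fail to converge are dropped and counted; more than
20% failures aborts.  Boundary replicate counts (0 or full exposure) are
nudged inward by half a count so observed probabilities stay in $(0,1)$;
at the exposures and probabilities of this problem the nudge is
essentially never triggered.  P-values test $H_0:\theta=0$ by inverting
the *basic* (reflected) bootstrap interval --
$p = \min\{1,\,2\,\overline{[\theta^\ast \ge 2\hat\theta]}\}$, floored at
$1/(B+1)$ -- because percentile intervals of positivity-constrained
parameters can never cross zero and so cannot be inverted for this test.
A nonparametric row-resampling scheme is available behind
`scheme = "nonparametric"`.

## From curve to cohort

`propagate_cohort()` runs the life-table recursion $d_x = l_x q_x$,
$l_{x+\mathrm{step}} = l_x - d_x$ from an initial cohort (default
160,000) along an age grid.  Two conventions are exposed for sub-annual
grids:

* **replication** applies the annual probability at every step
  unadjusted.  On a quarterly grid this charges each annual $q_x$ four
  times per year -- an aggressive spreadsheet-style reading of the
  recursion under which the reference cohort collapses to below
  $10^{-3}$ of its initial size by age 72;
* **actuarial** (the default for new analyses) converts per step,
  $q_{\text{step}} = 1-(1-q_x)^{\text{step}}$, the standard
  constant-hazard-within-year convention.

Both are first-class and every report names the mode used.  Ages are
interval left endpoints; intervals are half-open $[x, x+\text{step})$.
Replication mode always yields lower survivorship than actuarial mode on
sub-annual grids, and the recursion conserves the cohort exactly:
$l_0 = l_{\text{end}} + \sum d_x$.

Remaining life expectancy is model-derived from the propagated
survivorship as a curtate sum plus a half-interval credit,
$e_x = \text{step}\cdot\sum_{k>x} l_k/l_x + \text{step}/2$, with
$e = \text{step}/2$ at the final grid age and $e=0$ (flagged) where the
cohort is extinct.  The half-interval credit is a convention choice --
deaths within an interval are credited half the interval on average.  An
external life table can be substituted by building the trajectory from
its own $q_x$ via `cohort_from_qx()`.

Fine schedules are thinned before fitting by `to_quarterly_grid()`, which
retains the four quarter points of each whole year from a daily grid by
nearest-point selection -- the common retention step when an
annual-probability law is fitted to sub-annual measurements (a daily grid
over 45--86, about 15,000 points, reduces to $41\times4 = 164$).

## Burden metrics

`band_cohorts()` groups trajectory deaths into the eight five-year bands
45--49 through 80--84 (ages above 84 cannot form a complete band and are
excluded by default; partially covered bands are an error unless
explicitly allowed, as in delay sweeps where a shifted start empties the
early bands).  Each band's representative `mean_age` is, by default, the
death-weighted mean of the grid ages -- statistically faithful to where
the deaths actually sit -- with the band midpoint available as an
alternative convention.

`compute_yppll()` multiplies band deaths by
$(\text{retirement age}-\text{mean age})$, truncated at zero: bands whose
mean age is past retirement contribute nothing, because negative "lost
productive years" have no meaning under the human-capital approach.  The
untruncated literal arithmetic is available behind `truncate = FALSE` for
comparison.  `compute_cpl()` values the total at GDP per capita
(default 17,347 currency units per person-year), flat across ages and
undiscounted; the retirement age defaults to 67.  The identity
$\text{CPL}/\text{GDP per capita} = \text{YPPLL}$ is exact by
construction, and all three burden totals are exactly linear in the
initial cohort size.

`delay_sweep()` re-propagates the full cohort for each delay value rather
than re-indexing one trajectory, so remaining life expectancy stays
consistent with each shifted start age.  Delays whose shifted start falls
off the grid produce per-delay error entries without aborting the sweep.

## The synthetic generator

No patient-level cohort data are distributed with the package; the
generator supplies inputs with the statistical structure the analysis
assumes.  `simulate_schedule()` draws deaths per grid age as
$\text{Binomial}(n, q_{\text{true}})$ around a known HP curve --
binomial, not Poisson, matching the probability interpretation of $q_x$
-- and `simulate_trial_like()` is the stochastic twin of the
deterministic recursion, killing a binomial draw of the survivors at each
step so that expected step-deaths equal the deterministic $d_x$ exactly.
Defaults are the package's replication setting: reference parameters as
truth, ages 45--86, initial cohort 160,000, and a choice of daily
($1/365.25$), quarterly, or annual grids, with the daily-then-thin route
reproducing the retention step described above.  The per-age exposure
defaults to $10^4$, large enough that observed probabilities are
well-resolved at $q_x \approx 0.045$--0.36 yet far from noise-free.

What the generator does *not* emulate: treatment effects (the framework
models delay purely as an age shift), cause- or sex-specific structure,
heaping or misstatement of ages, and period-versus-cohort distinctions.
Passing tests therefore demonstrate that the pipeline is internally
correct and statistically calibrated under its own assumptions, not that
those assumptions hold for any particular real registry.

Reproducibility follows a single-seed rule: every stochastic operation
takes an explicit integer seed, and the pipeline derives stage sub-seeds
deterministically (the bootstrap stage uses `seed + 1`), so an entire run
is reproducible from one integer.

## Problem sizes used in the checks

The test-suite simulation studies use sizes chosen to make their
statistical targets sharp while keeping the suite practical to run: the
deviance-calibration study uses 500 replicates at exposure $10^4$ over
the 164 quarterly ages; the bootstrap-coverage study uses 200 Monte-Carlo
repetitions at exposure $10^6$ on the annual 45--86 grid with 100
bootstrap replicates each (the documented minimum for `bootstrap_fit()`);
curve-recovery checks use the noise-free quarterly schedule plus one
noisy schedule at exposure $10^6$.

## Known limitations

* Childhood and hump parameters are reported but not interpretable when
  fitted to older-age windows; use the fitted curve, $G$ and $H$.
* Remaining life expectancy is derived from the fitted model's own
  trajectory unless an external table is supplied; YLL totals are
  therefore internally consistent but not comparable to figures computed
  against national life tables.
* Replication-mode propagation intentionally reproduces a sub-annual
  reading of annual probabilities that accelerates cohort extinction;
  use actuarial mode for defensible new analyses.
* The costing is flat human-capital: no discounting, no age--earnings
  profile, no friction-cost alternative.
* The bootstrap p-value construction is one defensible reading for
  positivity-constrained parameters; other constructions exist and can
  give different values.
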
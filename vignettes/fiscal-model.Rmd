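---
title: "A lifetime fiscal projection model for recurrent acute hepatic porphyria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime fiscal projection model for recurrent acute hepatic porphyria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahpfisc)
```

## The model

`ahpfisc` takes the government's accounting perspective on one individual's
life course: every year it books the cash that flows *to* the state (direct
taxes through the tax wedge, VAT on consumed disposable income) and *from*
the state (disability benefits, the retirement pension, publicly financed
health costs), weights each year by the probability of being alive, discounts
it to the model start, and sums to lifetime totals. A clinical scenario—when
attacks start, how long they last, whether the patient ever works
again—changes only which streams are switched on at each age; the comparator
is the same machinery run with background (general-population) disability,
activity and health-cost schedules. This framework deliberately prices
states' cash flows, not welfare: quality of life, informal care and patient
out-of-pocket costs are out of scope.

The modelled individual enters the workforce at 18, is diagnosed at 30 (all
three patient scenarios), retires at 65 and is followed to 100. Attacks, when
active, occur 12 times per year and every attack is hospital-treated.

### Streams

For age $a$ with model start $b = 30$:

* **Earnings** $E(a) = w(a)\,\mathrm{act}(a)\,(1+g)^{\max(0,\,a-b)}$, where
  $w$ is the cross-sectional age–earnings profile, $\mathrm{act}$ the
  age-specific activity rate and $g$ the annual wage growth. Wage growth
  compounds over *model time*, i.e. the cross-sectional profile is assumed to
  drift upward as the cohort ages; transfer indexation uses its own,
  slower rate because the two are published as distinct quantities.
* **Direct tax** $\tau E(a)$ with tax wedge $\tau$; **indirect tax**
  $v\,(1-\tau)E(a)$ with VAT rate $v$, assuming full consumption of
  disposable income (no savings-rate data are modelled).
* **Disability** $f(a)\,D\,(1+i_t)^{a-b}$ for $b \le a < 65$, where $f$ is
  the disabled fraction of the year and $D$ the average annual benefit. The
  benefit ceases at retirement for everyone—published results show identical
  pension costs across scenarios, which is only consistent if disability does
  not continue past 65—and the pension $P\,(1+i_t)^{a-b}$ takes over for all.
* **Health**: patients incur, per active attack year, the attack rate times
  the micro-costed per-attack episode cost plus the recurrent-category annual
  management cost; after attacks stop they keep the symptomatic-category cost
  for life (chronic comorbidities persist; this is a modelling choice—the
  published analysis does not state the post-attack composition, but reports
  identical health costs whether or not the recovered patient works, which
  this choice reproduces structurally). The patient never adds the background
  general-population cost on top. The comparator carries the age-specific
  background expenditure, inflated at the healthcare rate.

### Work and disability patterns

All scenarios work from 18 to 29. The comparator works on to 64 under the
background activity profile. Patients with lifelong attacks or persistent
post-attack disability never work from onset; the return-to-work scenario
resumes the *full* background pattern (activity rate and background
disability prevalence) from the first year after the attack phase. During
work-disabled years the disabled fraction is 1 (recurrent-attack AHP is
treated as fully disabling); a 50% rate for symptomatic disease is carried as
a parameter for user-defined scenarios but unused by the built-in three.

### Aggregation conventions

* **Timing**: cashflows are booked at the start of each model year, so the
  discount factor at age $a$ is $(1+r)^{-(a-b)}$ and the first modelled year
  is undiscounted. The simplest annuity-due convention; nothing in the source
  material fixes the timing.
* **Pre-model window**: earnings and work years from ages 18–29 are included
  (published results show substantial pre-onset earnings in the
  never-working scenario, so this window must exist) with the discount factor
  clamped at 1 rather than compounded upward—pre-model earnings count at
  face value.
* **Survival**: conditioned on being alive at 30 for every scenario and the
  comparator (no excess AHP mortality is applied; the same life table serves
  all columns). Ages before 30 carry weight 1.
* **Money**: internal arithmetic is double precision; report cells are
  rounded half-up to whole euros (episode costing to cents) only at the
  output layer, so no report-layer arithmetic can drift.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| tax wedge | 0.527 | fraction | gross earnings → direct tax |
| VAT rate | 0.21 | fraction | disposable income → indirect tax |
| wage growth | 0.013 | /yr | compounds earnings over model time |
| transfer indexation | 0.0062 | /yr | compounds disability + pension |
| health inflation | 0.02 | /yr | compounds all health costs |
| discount rate | 0.03 | /yr | start-of-year discounting |
| disability benefit | 13,613 | EUR/yr | transfer while work-disabled |
| pension | 14,400 | EUR/yr | transfer from 65, all scenarios |
| attacks per year | 12 | /yr | active attack phase |
| per-attack cost | 6,180.83\* | EUR | micro-costed episode total |
| management costs | 6,192 / 20,930 / 34,252 / 34,252 | EUR/yr | asymptomatic / symptomatic / recurrent / severe |

\*The shipped episode table sums its canonical per-line totals to 6,180.84;
three published lines do not reproduce their own `pct × units × unit cost`
product exactly (rounded unit values), so the canonical totals take
precedence and the printed grand total is matched to within EUR 0.02. The
factors remain authoritative for user-defined lines. The severe category
duplicates the recurrent cost as published.

## The synthetic country and its calibration

No national micro-data ship with the package. `country_generator_params()`
defines a Belgian-like country in closed form: Gompertz–Makeham mortality
$q_x = \min(1, A + Bc^x)$ (defaults $A = 2\times10^{-4}$, $B = 10^{-5}$,
$c = 1.11$, giving plausible adult mortality and life expectancy around 80);
log-quadratic earnings peaking at EUR 55,000 at age 50; an activity rate
ramping to a 0.85 plateau by 24 and tapering to zero over ages 55–65;
disability prevalence $\min(0.6,\,0.02\,e^{0.05(a-18)})$; health expenditure
growing 2.5%/yr of age from EUR 600 at 18. These shapes and levels were
chosen once as field-plausible magnitudes for a western European country.
Everything is deterministic; the seed (default 20210804) is recorded for
provenance and identical parameters yield byte-identical fixture files.

`calibrate_fixture()` then matches the general-population column of the
published lifetime table by (1) solving a single multiplicative tilt on
$q_x$ so the lifetime pension cost—which depends only on survival and
constants—hits its target (bracketed root find, tolerance $10^{-10}$);
(2) solving the activity scale for the work-year target by root finding
(rates are clipped at 1, making the response nonlinear); and (3) applying
linear scale factors for earnings, disability and health targets, sweeping
up to five times. Residuals for all seven targets are stored on the fixture.

**A structural residual is reported honestly:** under this tax model,
lifetime gross tax is *identically* $0.62633 \times$ lifetime earnings
(both are the same survival-and-discount-weighted earnings sum times
constants). The published table's ratio differs by column (0.687 for the
comparator, 0.884 for the never-working scenario), so no input schedule can
match both the earnings and the gross-tax cells; the published analysis
evidently books additional revenue the stated tax method does not generate
(VAT levied on transfer-financed consumption closes part, not all, of the
gap and is not adopted). The calibration therefore fits earnings, work
years, pension, disability, health and the additive total within 2% and
reports the gross-tax residual (about −9%) in `fx$residuals`. Patient-column
outputs are emergent from the calibrated inputs and are property-checked
(orderings, invariances), not value-matched. The pre-onset earnings of the
never-working scenario are reported as a soft diagnostic
(`fx$diagnostics`): with a realistic early-career earnings ramp the
synthetic pre-onset window is smaller than the published one, which implies
the published profile carries near-peak earnings before age 30.

What the fixture does *not* emulate: cohort-vs-period life-table effects,
migration, sex stratification, part-time work, education-dependent earnings,
savings behaviour. Tests passing on the fixture demonstrate the engine's
accounting identities and monotonicities, not the accuracy of any national
statistic.

## Sensitivity analysis

`owsa()` re-runs the full projection with one parameter at a time at
$(1 \pm f)$ of base (default $f = 0.25$), on the ten-year-attacks,
no-return-to-work scenario, reporting the lifetime sum of government costs.
The five varied parameters map to: the attack rate; the attack-phase
duration (±25% of 10 years gives fractional 7.5/12.5 years, so the boundary
year is prorated between the active and post-attack cost mix—avoiding a
variation that would otherwise round away); the chronic management costs
(all four categories scaled jointly, since no single published field is
named); the per-attack episode cost; and the disability benefit. Rows are
ranked by descending output range with alphabetical tie-breaks—relevant in
practice because the attack-rate and per-attack-cost parameters enter the
output through the same product and have *identical* ranges, landing
adjacent in the tornado, while the disability benefit ranks last. On the
calibrated fixture the joint chronic-cost parameter has the widest bar: it
scales both the recurrent-phase and the lifelong symptomatic cost.

## Numerical and degenerate-input behaviour

* Life tables must be contiguous single-year-of-age and closed ($q_x = 1$ at
  the terminal age); violations name the offending row.
* An infinite attack duration is a first-class value (lifelong attacks);
  scaling it in the sensitivity analysis is a no-op with range 0.
* A return-to-work scenario with lifelong attacks is rejected at
  construction. The recovery age with a fractional duration is the ceiling
  of onset + duration (health costs are prorated within the boundary year;
  work resumes at the next whole age).
* All-zero activity yields zero work years rather than an error; an activity
  schedule that misses the whole work window errors.
* `run_all()` calibrates the synthetic country once, under the *reference*
  fiscal parameters: configured parameters (e.g. a different discount rate)
  are analysis choices and must not be silently absorbed by recalibration.

## Problem sizes

The model window spans 83 ages (18–100); a full four-scenario run with
calibration completes in well under a second, and the test suite—including
property sweeps over randomised life tables and repeated one-way sensitivity
analyses—runs in a few seconds. These sizes are the model's natural scale:
single-year-of-age projection for one individual.

## Limitations

The engine prices one individual (cohort $n = 1$), applies general-population
mortality to patients (no AHP excess mortality), excludes liver
transplantation, models neither progressive taxation nor household
composition, and treats the post-attack chronic cost as the symptomatic
category for life. The gross-tax structural residual above is the main known
divergence from the published table and is intrinsic to the stated tax
method, not a calibration failure.
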
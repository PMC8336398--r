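# ahpfisc

Lifetime fiscal (government-perspective) projection of acute hepatic
porphyria (AHP) with recurrent attacks, parameterised for Belgium.

## The problem

AHP is a group of ultra-rare metabolic diseases marked by episodic
neuro-visceral attacks that often require hospitalisation. Patients with
recurrent attacks (three or more per year) are frequently unable to work and
depend on disability support, so the cost of the disease to government
extends well beyond healthcare: taxes that are never collected, disability
benefits paid for decades, and heavy attack-related hospital spending.

`ahpfisc` implements a public-economic lifetime model for a single
individual diagnosed at age 30 and followed to age 100. For each clinical
scenario it projects annual streams of

- gross earnings `E(a) = w(a) · act(a) · (1 + g)^(a−30)` from the
  age–earnings profile `w(a)`, activity rate `act(a)` and wage growth `g`;
- direct taxes `T_d(a) = τ · E(a)` via the tax wedge `τ = 52.7%` and
  indirect taxes `T_i(a) = v · (E(a) − T_d(a))` via VAT `v = 21%` on fully
  consumed disposable income;
- disability transfers (EUR 13,613/yr, indexed at 0.62%/yr) during
  work-disabled years, replaced at 65 by the pension (EUR 14,400/yr);
- health costs: per active attack year,
  `12 attacks × EUR 6,180.83 per hospitalised attack` (micro-costed from
  resource lines) plus the recurrent-category management cost
  (EUR 34,252/yr), falling back to the symptomatic-category cost
  (EUR 20,930/yr) once attacks stop; the comparator carries the
  age-specific general-population (GP) expenditure instead.

Every stream is weighted by conditional survival from Belgian-style life
tables and discounted at 3%/yr (start-of-year convention), then summed into
lifetime totals. Scenario minus GP gives the fiscal deltas, and the net
fiscal impact is `Δ(government costs) − Δ(gross tax)`.

Built-in scenarios: `AL-W` (attacks for life, never works again), `A10-W`
(attacks stop after 10 years, still unable to work), `A10+W` (attacks stop
after 10 years, returns to work), plus the GP comparator.

Because the underlying national input data (age–earnings, activity,
disability prevalence, GP health expenditure, life tables) are not shipped,
the package includes a deterministic synthetic-country generator
(Gompertz–Makeham mortality, hump-shaped earnings, plateau-and-taper
activity) whose schedules are calibrated so the GP column reproduces the
published lifetime totals of the Belgian reference analysis.

## Worked example

```r
library(ahpfisc)

ref <- belgium_reference()          # published lifetime totals per scenario
d   <- fiscal_delta(ref$al_w, ref$gp)
glance(d)
#> # A tibble: 1 × 10
#>   scenario  disability_transfers pension_costs health_costs sum_government_costs
#> 1 AL-W - GP               247242             0      3030316              3277558
#>   lifetime_earnings gross_tax work_years societal_cost net_fiscal_impact
#> 1           -347802   -183187      -13.9        347802           3460745
```

A lifetime of recurrent attacks costs government EUR 3,277,558 in extra
outlays (EUR 3,030,316 of it healthcare, EUR 247,242 disability support) and
EUR 183,187 in foregone taxes — a net fiscal impact of EUR 3,460,745 per
person, with EUR 347,802 of lost earnings as the societal (human-capital)
cost.

Running the model end to end on the calibrated synthetic country:

```r
fx <- belgian_fixture()             # generate + calibrate the country inputs
gp <- fiscal_summary(project_scenario(scenario_gp(), fx$life_table,
                                      fx$profiles, fiscal_parameters()))
glance(gp)
#> # A tibble: 1 × 8
#>   scenario disability_transfers pension_costs health_costs sum_government_costs
#> 1 GP                      40277        83110.        70218              193605.
#>   lifetime_earnings gross_tax work_years
#> 1            632367   396070.       25.2
```

The calibrated GP column matches the published disability, pension, health,
total-cost, earnings and work-year values; gross tax is structurally tied to
earnings through the combined rate 0.527 + 0.21·(1 − 0.527) = 0.62633 and is
reported as computed (see the methods vignette). `run_all()` projects all
four scenarios and assembles the seven-row results table with change
columns; `owsa()` produces the ±25% one-way sensitivity tornado
(`autoplot()` draws it).

A thin command-line wrapper ships in `inst/cli/ahpfisc` with verbs
`project`, `owsa`, `synth` and `validate-config`.

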
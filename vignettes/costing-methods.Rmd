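---
title: "Methods: activity-based micro-costing of differentiated PrEP delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-based micro-costing of differentiated PrEP delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepcost)
```

## The costing problem

Oral HIV pre-exposure prophylaxis (PrEP) in most of sub-Saharan Africa is
dispensed at clinic visits: under the standard of care (SOC) clients attend
quarterly and receive three 30-pill bottles; under a differentiated model
they attend semi-annually, receive six bottles, and bridge the interval
with an HIV self-test (HIVST) at three months. The health system's question
is what each model costs **per client-month of PrEP dispensed** (one
30-pill bottle = one client-month), from the payer perspective — client
travel and waiting time are excluded.

`prepcost` implements activity-based (ingredients) micro-costing over a
one-year horizon:

$$
\text{unit cost} \;=\;
\frac{\sum_{c \in \text{categories}} C_c}{\text{PrEP client-months
dispensed in the year}}
$$

with ten cost categories partitioned into **variable** costs that scale
with service volume (clinical personnel, PrEP drugs, laboratory testing,
recurrent training, supplies) and **fixed** costs that do not (start-up
microplanning, supervision, capital, overhead, start-up training).

## From stopwatch to wage bill

Time-and-motion observations record start and end times of each visit
activity — counselling & HIV testing, clinical examination, laboratory
testing, PrEP dispensing — plus waiting, which carries no provider and is
never costed. Each activity maps to one cadre
(`activity_cadre_map()`), and the personnel cost of a visit is

$$
\sum_{a} \frac{\text{minutes}_a}{60} \cdot
\frac{\text{annual salary}_{\,\text{cadre}(a)}}{\text{annual work hours}} .
$$

Annual work hours default to 2,080 (a 40-hour week); the ledger also
carries the alternative 231-weekday denominator so either convention can
be stated explicitly. Annual projections multiply the per-visit mean by
the scheduled visit frequency (4 for SOC, 2 for the six-month model) —
applied to the all-visit-types mean even though one annual visit is an
enrollment, matching how the source study projected its figures.

Summary conventions, chosen where the study protocol is silent:

* quartiles by linear interpolation between order statistics (type-7, R's
  default) — published medians/IQRs are therefore *synthetic-recovery*
  targets, not exact assertions, since the raw logs are not public;
* SD is the sample standard deviation (n−1), undefined at n = 1;
* display rounding is half-up to whole minutes; unrounded values are kept
  internally;
* enrollment strata pool both arms (enrollment procedures are identical;
  the study observed only one SOC enrollment visit).

## The cost ledger and its calibration

Ledgers (YAML, schema in `inst/extdata/ledger-schema.json`) carry economic
parameters, cadre salary tables per scenario (research-site `trial` pay
vs public-sector `moh` pay), unit prices, and itemised entries with a cost
basis: `per_year`, `per_visit`, `per_client_month`, or `one_off` with a
useful life of 1–5 years. One-off outlays are annuitized at the discount
rate $r$ (default 3%):

$$
\text{annual cost} = \frac{\text{outlay}}{a(r, n)}, \qquad
a(r, n) = \frac{1 - (1+r)^{-n}}{r},
$$

computed in the numerically stable `-expm1(-n log1p(r))/r` form (the naive
expression loses six digits at $r = 10^{-12}$). Useful lives follow the
usual convention: 5 years for equipment and capital, 1 year for training
and microplanning. A straight-line alternative (`outlay / n`) is exposed
as an engine option. KES amounts are divided by the exchange rate
(105.50 KES/USD default; the alternative published figure 105.35 is
exported as `kes_per_usd_2019_alt` — the two circulate side by side and we
surface rather than hide the discrepancy). All aggregation is at full
double precision, with half-even rounding to cents only at category/report
boundaries; half-up rounding is used for whole-percent and whole-minute
display.

Variable categories accrue against the arm's annual volumes: personnel
per visit × visits; drugs per client-month × client-months; one rapid HIV
test per visit in both arms; and in the intervention arm two HIVST kits
per visit priced at the mean of the oral-fluid and blood-based kit prices
(the trial allocated the two kit types 1:1 — both the kit count and price
are engine options). Fixed items tagged with an arm enter that arm
directly; untagged fixed totals are allocated by each arm's share of total
clinic visits (304/644 vs 340/644 in the study's accruals), with
`allocate_fixed()` conserving each category total to the cent (residual
cent to the larger arm).

Three calibration choices deserve emphasis, because the published tables
cannot be reproduced from their own printed inputs alone:

1. **Untimed personnel time.** The published clinical-personnel totals
   imply about \$24.80 of personnel cost per SOC visit, while the timed
   activities priced at the published salaries yield about \$4.31. The
   remainder — preparation, documentation, and other provider time outside
   the stopwatch protocol — is carried in the fixtures as a calibrated
   per-visit `personnel_untimed` item per arm and scenario. The
   time-and-motion pathway stays live: changing salaries or observed
   durations changes the result.
2. **Delivered drug prices.** The ex-works bottle price is \$6.75, but the
   published drug rows imply procurement-inclusive per-client-month prices
   of 7.17116 (SOC) and 7.10456 (intervention). The fixtures carry these
   as per-arm `per_client_month` items; the \$6.75 price remains in
   `unit_prices` and is the fallback for ledgers with no drug item.
   (A single shared delivered price cannot reproduce both printed rows.)
3. **Laboratory consumables.** Beyond the rapid test and HIVST kits, a
   calibrated per-visit consumable residual per arm reproduces the printed
   laboratory totals.

Fixed rows are recorded as per-arm amounts exactly as published (with
one-off raw outlays back-computed so that annuitization is exercised),
because no single visit-share rule reproduces them: four of the five fixed
categories imply a SOC share of ≈0.4726 (≈304/644), but the supervision
rows imply ≈0.49–0.50 in both scenarios. The package treats the published
supervision rows as direct per-arm measurements; the visit-share
allocation rule is implemented and property-tested, and the corresponding
acceptance check documents the supervision discrepancy rather than
papering over it.

## Scenarios

A scenario is a declarative ledger edit: select another salary table,
override, remove or add items. `moh_scenario.yaml` projects delivery at
public Ministry of Health clinics (public-sector salaries; public-clinic
start-up, supervision, capital, overhead and supply levels);
`creatinine_addon.yaml` adds twice-yearly serum creatinine monitoring —
the test kits at \$2.51 × 2 per client-year (entered per client-month)
plus a per-client-month personnel & equipment support item per arm.
Application is idempotent (re-applying a scenario already recorded on the
ledger is a no-op) and edits touching disjoint ledger parts commute, so
the salary swap and the creatinine add-on can be applied in either order.

Only the *with-creatinine* public-clinic category breakdown is published;
the without-creatinine configuration is published as unit costs alone. The
packaged `moh_2019.yaml` breakdown is therefore a calibrated construction:
the with-creatinine table minus the kit costs and the support item, with
the support residual placed in clinical personnel (its dominant component
and the placement that keeps every fixture amount non-negative). Its
totals reproduce the published unit costs; its category-level split is a
modelling choice, flagged as such in the fixture header.

Arm comparisons report the SOC-minus-intervention difference to the cent
and the percent difference with the SOC unit cost as denominator, rounded
half-up to a whole percent.

## The synthetic generator

`generate_observation_log()` emulates the observation protocol: per-arm
visits whose four activity durations are drawn independently from a normal
distribution truncated at zero (rejection sampling) at the published
per-activity means and SDs — SOC 27/17/3/7 minutes (total 54), intervention
32/18/5/21 (total 76) — with sequential, non-overlapping timestamps and a
waiting gap before dispensing. Defaults match the study's effort: 9 SOC and
13 intervention visits, 6 of them enrollments. A moment-matched lognormal
is available for robustness checks, since only means and SDs are published
and the true skew is unknown. Zero SD reproduces the means exactly, which
is how the acceptance pipeline feeds the engine the measured means while
still exercising the log-summarisation path. Seeds are mandatory and the
global RNG state is restored after generation.

What the generator does **not** emulate: inter-observer variation,
within-visit activity correlation, client discontinuation and re-initiation
dynamics, and seasonal caseload variation. Passing tests therefore
demonstrate the arithmetic and its statistical recovery properties on data
shaped like the study's, not robustness to messier real-world logs.

`generate_accruals()` defaults to the study's accruals (304 visits/913
client-months vs 340/2,039; 2,952 months in all); custom visit counts
derive months as visits × bottles per visit. `generate_ledger()` loads a
packaged fixture, optionally with seeded multiplicative jitter for
property tests.

## Problem sizes and runtime

All headline quantities are desk-scale: ledgers of ~20 items, 644 visits,
2,952 client-months. The test suite uses synthetic logs of 22 visits for
protocol-shaped checks and 500 visits per arm for mean-recovery checks
(each published mean recovered within 3 standard errors); the whole suite
runs in well under a minute on one CPU.

## Known limitations

* The calibrated items (untimed personnel, consumable residuals, delivered
  drug margins, creatinine support) reproduce the published tables but are
  not independently observable; transferring the fixtures to another
  setting requires re-costing those inputs.
* The public-clinic scenario inherits the research site's observed
  activity durations; provider efficiency at public clinics may differ.
* Discontinuation dynamics and demand-side (client) costs are out of
  scope: the denominator is months dispensed, not months adhered.
* Supervision fixed costs cannot be reconciled with the visit-share
  allocation rule (see above); they are carried as measured per-arm
  values.
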
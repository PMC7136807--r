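---
title: "Planning and valuing community-oriented primary care: the copcplan model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and valuing community-oriented primary care: the copcplan model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copcplan)
```

## The problem

Rural districts in South Africa carry a heavy, income-graded burden of
maternal, child, HIV, TB, non-communicable and acute disease, and facility-based
primary care alone does not reach scattered households. In community-oriented
primary care (COPC), full-time community health workers (CHWs), organised in
facility-linked teams under team leaders and clinical supervision and supported
by mobile data capture (ICT), deliver care to households. Before committing to
such a service at district scale, a planner needs to know: how many CHWs,
teams and supervisors the population requires; what the service costs per
year; how many deaths and life-years it can avert; and whether the benefits
justify the cost.

`copcplan` implements that calculation as a deterministic pipeline:

1. **population** — a small-area layer (SAL-like): many areas of 20–500
   households with coordinates, age structure and household incomes
   (`generate_small_areas()`), or the packaged Waterberg reference scenario
   (`waterberg_fixture()`);
2. **catchment** — every area is linked to its nearest facility by
   great-circle distance and classed *proximal* (< 2 km), *distal* (> 2 km,
   > 200 persons/km²) or *remote* (> 2 km, < 200 persons/km²)
   (`assign_nearest_facility()`, `classify_density()`);
3. **demand** — catchment populations become annual condition-specific
   person contacts (CSPC), risk-adjusted by income quintile
   (`compute_demand()`);
4. **workforce** — contacts become CHW full-time equivalents, headcounts,
   home-based carers and teams (`size_workforce()`);
5. **costing** — an 18-line annual ledger in exact cent arithmetic
   (`build_ledger()`);
6. **impact** — lives and life-years saved with lower/expected/upper
   effectiveness bounds (`impact_bounds()`);
7. **economics** — cost per life-year saved, threshold effectiveness,
   benefit streams and the benefit-to-cost ratio (`economic_summary()`,
   `benefit_ledger()`).

`run_scenario()` chains all stages; all randomness lives in the population
generator, so everything downstream is a pure function of its inputs and a
seeded run is exactly reproducible.

## The model

### Demand

Each condition $c$ has a prevalence $\pi_c$ (per 1000 eligible people), a
best-practice contact intensity $k_c$ (contacts per affected person per
year), and a poorest:richest mortality ratio $R_c$. Mortality (and hence
need) follows an income gradient: quintile rates $r_q$ satisfy
$r_1/r_5 = R_c$ with the population-weighted mean fixed at the base rate.
The default gradient is linear in quintile rank (`geometric` gives constant
adjacent-quintile ratios); both are mean-preserving by construction, so risk
adjustment redistributes demand without changing the district death total.
The richest quintile (Q5) is assumed privately insured and excluded, so the
eligible (poorer) population carries an average risk multiplier above 1.

Annual workload per class is

$$\text{CSPC} = \underbrace{N_e \sum_c \frac{\pi_c}{1000}\, k_c\, m_c}_{\text{condition-specific}}
 + \underbrace{H_e}_{\text{annual household visits}}
 + \underbrace{1.19\, N_e}_{\text{comprehensive care}}$$

with $N_e$ eligible population, $H_e$ eligible households and $m_c$ the
quintile risk multiplier. The comprehensive-care term covers health
promotion, adherence, rehabilitation and palliative contacts outside the
condition profile; household visits are counted inside total consultations
but outside condition-specific consultations when cost is allocated.

### Workforce

A full-time CHW works 180 days × 7 h; a contact takes 28 minutes in proximal
and distal classes, 30 in remote, giving annual capacities of 2700 and 2520
contacts. Several condition-specific contacts are delivered within one
household visit (`cspc_per_visit`, default 1.1115), so FTE = class CSPC /
(capacity × `cspc_per_visit`). Proximal and distal headcounts are FTE rounded
up; in remote classes CHWs work part-time across scattered settlements, so
headcount is driven by a cap of 50 households per remote CHW. Teams (one
team leader each) are FTE / 6.7; home-based carers scale at 0.186 per CHW;
clinical supervisors, associates and family physicians scale linearly with
eligible population from district ratios (49 / 63 / 6 per 630 565 people).

### Impact

Per condition, expected lives saved = baseline deaths × effectiveness,
rounded half-up to whole lives at condition level (matching integer planning
tables); life-years saved = lives × (life expectancy 60 − mean affected
age), with no utility or disability adjustment. Totals at the lower and
upper effectiveness bounds bracket the expected value. A single calibrated
deflation (0.711%) converts unadjusted to cohort-adjusted life-years,
standing in for all-cause mortality among the saved cohort; only this
aggregate input/output pair is known, so no richer survival model is
attempted.

### Economics

Cost per life-year saved = ledger total / annual life-years saved, to the
rand. Threshold effectiveness solves, in closed form, for the uniform
effectiveness at which cost per life-year equals a benchmark (GDP per capita
R99 169, or the cohort's average household income R79 524). Benefits under
the human-capital approach are the discounted future earnings of lives saved
(end-of-year annuity at the net growth-minus-inflation rate 0.72%, with 3%
and 6% sensitivity), plus health-system utilisation savings, HIV/TB
treatment savings (2.2 × 20.3% × R88.3m = R39.4m) and the CHW household wage
injection. Two earnings perspectives are implemented: *poverty reduction*
deducts tax (18%) but not schooling costs or child grants (they flow to the
household); *GDP* keeps tax but deducts schooling and grants as costs to the
state. Both apply the employment adjustment (default 0.393, the district
labour absorption rate).

## The Waterberg reference scenario

`waterberg_fixture()` encodes, by direct assignment, the district scenario
the model was built around: 630 565 eligible people in 168 345 households
(net of Q5), split 364 919 / 200 887 / 64 759 across proximal / distal /
remote classes, 1 870 482 CSPC per year, the seven-condition consultation
and mortality profile, the 18-line unit-cost table summing to R96 399 102,
and reference impact totals (932 lives, 36 134 unadjusted life-years per
year, 35 877 adjusted).

```{r waterberg}
res <- run_scenario(scenario = "waterberg")
res$economics
```

Three aspects of the scenario deserve honesty about their provenance:

* **Reproducible rows.** HIV (506), TB (54) and NCD (220) lives saved follow
  exactly from baseline deaths × expected effectiveness. The maternal,
  infant, child and acute rows embed counting conventions not derivable from
  those inputs (e.g. stillbirths valued at age 0 inflate maternal
  life-years); they are carried as scenario constants and the packaged
  effectiveness model intentionally does not reproduce them.
* **Class workload.** The per-class visits-per-capita figures
  (2.96/2.98/2.95) differ by amounts not derivable from any stated per-class
  input, so the scenario carries class CSPC directly; the bottom-up demand
  engine reproduces the *district-level* workload through the calibrated
  contact profile and the 1.19 comprehensive-care rate.
* **Published counts that do not reconcile.** The scenario's own staffing
  rule yields 360/200/411 CHWs where the reference tables print 360/205/414
  (and 643 FTE, 103 vs 122 teams — the source figures are internally
  inconsistent); none of these is used by the package's headline outputs.
  Likewise the reference per-capita cost R170.37 is not reproducible
  (96 399 102 / 630 565 = R152.88, which is what the package reports).

## Calibrated parameters

Values the underlying planning sources state are used as-is (wages, working
time, contact minutes, class thresholds, effectiveness bounds, mortality
ratios, tax and discount rates, GDP and household income, the HIV/TB saving
formula and the 15% ICT saving). Where a required input is not stated, it
was chosen once, as follows, and is exposed in `copc_params()`:

| parameter | default | basis |
|---|---|---|
| prevalences $\pi_c$ (per 1000) | 24, 22, 55, 101.3, 12, 140, 180 | plausible district figures (HIV = 63 847 PLHIV / 630 565) |
| contacts $k_c$ (per year) | 10.5, 8.2, 3.3, 2.8, 20.3, 2.0, 0.5 | calibrated once so condition workload shares match the reference consultation shares |
| `cspc_per_visit` | 1.1115 | calibrated on the proximal class caseload (3001 CSPC/CHW) |
| `social_support_contacts_per_capita` | 1.19/yr | district workload minus condition and household-visit contacts |
| health-system unit costs | R467.61 / R962.17 / R9 621.65 | plausible 2019 values scaled once so the stated utilisation reductions value to R120m; not official tariffs |
| `cohort_deflation_rate` | 0.00711 | calibrated to the 36 134 → 35 877 adjustment |
| `hbc_per_chw`, `chws_per_team` | 0.186, 6.7 | reference staffing ratios |
| schooling cost, child grant, employment | R15 000, R5 100, 0.393 | 2019 public figures |

These calibrations are constants of the package, not refit at run time.

## The synthetic generator

`generate_small_areas()` emulates what the analysis assumes about a SAL
layer: 20–500 households per area; mean household size 3.2–4.0 (rural) or
2.6–2.9 (urban); lognormal incomes (sdlog 1) with the log-mean set so ~43%
(rural) or ~30% (urban) of households fall under a R30 000/year
extreme-poverty line, with remote areas drawn poorer; ~45% of areas within
2 km of their anchor facility and the remainder split across the
200 persons/km² density line; and a seven-band age structure allocated by
largest remainder so bands sum exactly to the area population. It does *not*
emulate road-network travel times, household micro-structure, spatial
autocorrelation of disease, or migration — so green tests on synthetic data
demonstrate the pipeline's arithmetic and invariants, not predictive
validity for any real district.

```{r synthetic}
res_s <- run_scenario(scenario = "synthetic", seed = 42,
                      n_areas = 150, n_facilities = 4)
res_s$workforce
```

## Numerical choices and edge cases

* Ledger arithmetic is exact in integer cents; rounding of presentation
  figures is half-away-from-zero (half-up), matching published planning
  tables, not banker's rounding.
* Quintile thresholds are type-7 quantiles at 20/40/60/80%; a household
  whose income equals a threshold falls in the lower quintile, so an
  all-equal income vector degenerates to everyone in Q1.
* Exactly 2 km is non-proximal and exactly 200 persons/km² is remote: the
  boundary goes to the class with the lower caseload per CHW, the
  conservative staffing choice. Nearest-facility ties break to the lowest
  facility id.
* Zero demand produces a plan of zeros (no error); zero life-years or zero
  cost denominators raise argument errors rather than returning infinities.
* Test and example problem sizes (≤ 200 areas, ≤ 10 000 households) keep a
  full suite run to seconds; the model is linear in areas and households, so
  national-scale layers pose no algorithmic obstacle.

## Limitations

The model is annual steady-state arithmetic: no dynamics of incidence,
health literacy or secondary averted infections; no utility/DALY weighting;
violence and injuries are out of scope; prevalences are district averages.
The benefit-to-cost ratio for a synthetic scenario uses the bottom-up
benefit ledger, whose earnings component depends on the chosen employment
adjustment and perspective; the Waterberg headline BCR instead uses the
scenario's stated benefit decomposition (R155m district savings + R175m
societal benefits), and the two compositions are deliberately reported side
by side rather than forced to agree.
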
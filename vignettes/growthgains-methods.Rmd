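---
title: "Projecting schooling and lifetime-earnings gains from improved linear growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting schooling and lifetime-earnings gains from improved linear growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthgains)
```

## The model

`growthgains` converts a projected reduction in child stunting into two
non-health outcomes, per country and per birth cohort: additional years of
schooling and the net present value (NPV) of additional lifetime earnings.
The chain has three links.

**1. Improved linear growth.** Stunting in 12--23-month-old children is
described by a four-category height-for-age z-score (HAZ) distribution with
cut points at $-1$, $-2$ and $-3$; stunting prevalence is the mass below
$-2$. A scenario compares a baseline distribution with a counterfactual in
which growth has improved (for the SDG 2.2 scenario, prevalence falls
linearly from its 2020 level to 60% of its 2012 level by 2025). The quantity
carried forward is $\Delta HAZ$, the mean HAZ gain *among children stunted
at baseline*, extracted by a rank-preserving match: children keep their rank
in the distribution across scenarios, each category is represented by a
single z-score, and the baseline-stunted lowest-$p$ mass of the
counterfactual distribution is averaged against the baseline stunted mean
(categories are split pro-rata when $p$ falls inside one).

**2. Education.** Schooling gains are linear in the growth improvement:
$s = 0.47 \,\Delta HAZ$ years of additional schooling per stunted child,
the pooled coefficient from five LMIC birth-cohort studies linking
early-childhood growth to attainment. The coefficient is a configuration
parameter (`schooling_coefficient`).

**3. Earnings.** The base-year wage per worker is

$$w_0 = \frac{\text{GNI pc} \times \text{labor share}}{\text{LFPR}_{15+} \times (1 - \text{pop share}_{0\text{--}14})},$$

GNI per capita in Atlas USD, a 50% labor share by default, and the published
15+ labor force participation rate re-based to the total population.
Wages grow at the country's projected annual per-capita income growth rate,
constant within each five-year projection period 2020--2084. A child born in
year $b$ earns the uplift once per working year, ages 16 through 59
(44 payments), so the per-child present value at discount rate $d$ is

$$PV(d) = \sum_{a=16}^{59} w(b+a)\; r\, s\; (1+d)^{-(b+a-T_0)},$$

with $r$ the Mincerian return per school year and $T_0$ the discounting
reference year. Cohort totals multiply the per-child value by the number of
baseline-stunted children (births $\times$ baseline prevalence).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `schooling_coefficient` | 0.47 | school years per HAZ unit | pooled LMIC cohort estimate |
| `labor_share` | 0.5 | fraction of national income | global assumption, per-country overridable |
| `discount_rates` | 0.03, 0.05, 0.10 | annual fraction | the three conventional health-economics rates |
| `discount_reference` | `birth_year` | -- | see *Design choices* |
| `entry_age`, `exit_age` | 16, 60 | years | 44 working years, ages 16..59 |
| `uplift_mode` | `linear` | -- | annual gain $w\,r\,s$; `compound` gives $w\,[(1+r)^s - 1]$ |
| `haz_representatives` | 0.0, $-1.5$, $-2.5$, $-3.5$ | z-scores | interval midpoints, conservative open tails |
| `cohort_lag` | 0 | years | cohort $b$ read at calendar year $b$ |

Discounting is very influential here because the stream starts 16 years
after the growth improvement: moving from 5% to 3% roughly doubles the
totals, and 10% cuts them by three quarters.

## Design choices

The projection sits downstream of a cohort model whose published outputs do
not pin down every convention, so several choices were genuinely open.

* **$\Delta HAZ$ extraction.** Category outputs do not identify a unique
  mean improvement. We use fixed representative z-scores per category with
  the rank-preserving lowest-mass match described above; the representatives
  are configurable, and `delta_haz_override` lets users supply per-cohort
  mean improvements directly when these are available from the upstream
  model. The extraction is translation-equivariant (shifting all
  representatives by a constant leaves $\Delta HAZ$ unchanged) and
  nonnegative whenever the counterfactual stochastically dominates the
  baseline.
* **Cohort indexing.** The cohort born in year $b$ is evaluated against the
  trajectory at calendar index $b$ (`cohort_lag = 0`), matching the
  one-to-one pairing of six cohorts with six trajectory years 2020--2025 in
  the published South Asia projections. A strict age-timing reading (the
  cohort is 12--23 months old in year $b+1$) is available as
  `cohort_lag = 1`.
* **Stunted-count denominator.** Counts use the *baseline* prevalence, so
  per-stunted-child values divide by the population whose growth improved --
  the population to which the 0.47 coefficient applies.
* **Discount reference.** Defaults to each cohort's own birth year. With a
  growing scenario effect this makes later cohorts' per-cohort PVs rise, the
  pattern visible in the published tables; a fixed reference
  (`"fixed:2020"`) is available since the convention is not otherwise
  identified.
* **Uplift linearization.** The default annual gain is $w \, r \, s$ --
  returns per school year applied proportionally -- with exact compounding
  as an option; for realistic $r\,s$ the two differ by well under a percent.
* **Growth beyond 2084.** The 2025 cohort works through 2084; any year past
  the final five-year period reuses the final period's rate.
* **Medians.** Even-sized donor sets take the midpoint of the two central
  values. Missing returns to schooling and growth rates are imputed with
  WHO-region medians; missing GNI per capita, LFPR and 0--14 population
  share with income-group medians (the population share is needed to form
  the effective LFPR, so it joins the income-group pool), with a global
  fallback when a pool has no donors. Imputation is idempotent, never
  overwrites data, and is fully audited.
* **Units.** Every percent-like CSV column must declare its units through a
  `_pct` / `_frac` column-name suffix; internally everything is a fraction.
  This removes the classic 2.44-vs-0.0244 ambiguity at the file boundary.
* **Scope.** High-income countries are rejected at read time: the model and
  its imputation donor pools are defined over LMICs. The 12--23-month age
  band is used throughout. Counterfactuals that worsen stunting are rejected
  rather than clamped.

## The synthetic generator

`generate_profiles()` and `generate_trajectories()` emulate the *shape* of
the real inputs so the whole pipeline is testable offline: GNI per capita
log-uniform on [500, 12 000] USD, 15+ LFPR uniform on [0.40, 0.85], 0--14
population share uniform on [0.20, 0.45], Mincerian returns uniform on
[0.01, 0.15], growth rates from a mean-reverting walk clamped to
[$-2$%, 8%], round-robin regions and income groups, and beta-distributed
baseline prevalences centred in the 0.20--0.45 range with an SDG-ramp
counterfactual. Category shares come from a discretized normal
(sd 1.1 z-scores) whose mean matches the prevalence.

What the generator does **not** emulate: correlation between income and
stunting across countries, within-country heterogeneity in who benefits
from improved growth, non-normal HAZ shapes, demographic feedback on cohort
sizes, and real input vintages. Passing tests on synthetic panels therefore
demonstrate the correctness of the accounting and the numerics, not the
realism of any particular country projection; country results are only as
good as the user-supplied inputs.

## Numerics and degenerate inputs

Category shares must sum to 1 within $10^{-9}$; trajectories must be
contiguous in years; a zero baseline prevalence is an error (there is no
stunted child to improve); a trajectory that does not cover a cohort's
working years is an error rather than an extrapolation. The PV sum is
evaluated directly (44 terms), and matches the geometric-series closed form
to a relative $10^{-10}$ for constant growth, including the $g = d$
removable singularity, which the closed form handles as $44\,x^{16}$ with
$x = 1$. Report-table margins are computed before any rounding; rendering
rounds to the published precision (one decimal below ten thousand school
years, whole millions, whole dollars). CSV round trips of report tables are
bit-exact (17 significant digits).

Verification problem sizes, chosen to make the checks sharp while keeping
the suite quick: the rank-simulation oracle for $\Delta HAZ$ uses $10^6$
pseudo-children on 50 random distribution pairs (agreement within
$10^{-3}$); imputation is checked against a sort-based median oracle on 100
randomized 156-country panels; the NPV closed form is checked on a
$5 \times 5$ $(g, d)$ grid.

## Limitations

Cohort-level improvement is distributed evenly over stunted children;
within-country heterogeneity is out of scope. Labor share, participation
and returns are held constant over each cohort's working life; there is no
unemployment, tax, or schooling-cost modelling, and no monetization of
averted mortality or morbidity. Earnings are in nominal Atlas USD under the
projected income growth path, with no separate inflation treatment. The
packaged South Asia tables are published *outputs*; the exact upstream
inputs that generated them (survey-based category distributions, income
levels and growth vintages) are not public, so they serve as aggregation
fixtures rather than end-to-end regression targets.
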
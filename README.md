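# growthgains

Nutrition interventions that reduce child stunting produce benefits beyond
survival: children who grow better in their first two years stay in school
longer and earn more over their working lives. `growthgains` projects those
two non-health benefits — **additional years of schooling** and the
**net present value (NPV) of additional lifetime earnings** — per country
and per annual birth cohort, for analysts doing benefit–cost analysis of
nutrition programming in low- and middle-income countries (LMICs).

## The model

For each country and birth cohort the package chains three steps:

1. **Growth.** Baseline and counterfactual height-for-age z-score (HAZ)
   distributions for 12–23-month-olds, in four categories
   (>−1, −1 to −2, −2 to −3, <−3; stunting = mass below −2), give the mean
   HAZ gain ΔHAZ among baseline-stunted children via a rank-preserving
   category match. The SDG 2.2 scenario builder ramps prevalence linearly
   from its 2020 level to 60% of its 2012 level by 2025.
2. **Schooling.** s = 0.47 × ΔHAZ additional school years per stunted
   child (pooled LMIC cohort-study coefficient).
3. **Earnings.** Base wage w₀ = GNI pc × labor share / effective LFPR
   (15+ participation re-based by the 0–14 population share; labor share
   0.5 by default); wages grow at projected five-yearly per-capita income
   growth rates; the per-child gain is

   PV(d) = Σₐ₌₁₆⁵⁹ w(b+a) · r · s · (1+d)^−(b+a−T₀)

   over 44 working years, with r the Mincerian return per school year and
   d ∈ {3%, 5%, 10%}. Cohort totals scale by births × baseline stunting
   prevalence.

Missing country indicators are imputed with WHO-region medians (returns,
growth rates) or income-group medians (GNI, participation, age structure),
with a global fallback and a full audit trail.

## Worked example

Everything below is synthetic (no downloads); the same functions accept
real CSV inputs via `read_country_table()`, `read_stunting_table()` and
`run_project()`.

```r
library(growthgains)

profiles <- impute_missing(
  generate_profiles(5, seed = 20220402, missing_fraction = 0.1))
trajectories <- generate_trajectories(profiles, seed = 20220403)
proj <- project_growth_benefits(profiles, trajectories)
proj
#> <growth_projection> 5 countries, cohorts 2020-2025
#>   stunted children (baseline): 12 056 169
#>   schooling gained: 1 149.1 thousand school years
#>   PV lifetime earnings at 3%: 16 286 USD millions
#>   PV lifetime earnings at 5%: 8 196 USD millions
#>   PV lifetime earnings at 10%: 1 922 USD millions
```

Across the six 2020–2025 birth cohorts of these five synthetic countries,
about 12.1 million children are stunted at baseline; reaching the SDG
stunting target would buy them ~1.15 million extra school years, worth
US$8.2 billion in present-value lifetime earnings at a 5% discount rate
(and roughly double that at 3%, a quarter at 10% — discounting dominates
because earnings start 16 years after the growth improvement).

```r
schooling_table(proj$impacts)
#> Additional years of schooling gained per birth cohort (thousand school years)
#>       2020 2021  2022  2023  2024  2025 Total
#> SAA      0  6.6  13.0  19.0  26.0  31.0    96
#> SAB      0  4.9   9.8  14.0  19.0  24.0    72
#> SAC      0  3.0   6.0   8.9  12.0  15.0    45
#> SAD      0 63.0 124.0 185.0 242.0 302.0   917
#> SAE      0  1.4   2.7   4.0   5.2   6.4    20
#> Total    0 79.0 156.0 232.0 304.0 378.0  1149

per_child_table(proj$impacts, rate = 0.05)
#> Present value of additional lifetime earnings per stunted child at 5% discount rate (USD)
#>     2020 2021 2022 2023 2024 2025 Average
#> SAA    0   40   82  126  173  221     107
#> SAB    0  209  436  683  950 1239     586
#> SAC    0  234  487  762 1059 1380     654
#> SAD    0  289  591  908 1240 1587     769
#> SAE    0   95  194  297  403  512     250
```

The 2020 column is zero because the counterfactual ramp starts at the 2020
baseline; later cohorts see progressively larger prevalence gaps, hence
larger ΔHAZ, schooling and earnings gains. Per-child values differ across
countries through wages, returns to schooling and growth paths only — they
are independent of cohort size.

A shell front end wraps the same pipeline
(`exec/growthgains <validate|project|demo|tables>`), and
`write_demo_bundle()` / `run_project()` round-trip complete CSV input
bundles deterministically.

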
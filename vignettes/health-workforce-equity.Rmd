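---
title: "Measuring equity of health workforce allocation with equipanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring equity of health workforce allocation with equipanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equipanel)
```

## The problem

Whether a region's health workforce is distributed *equitably* depends on
what you divide by. A province can hold staff in proportion to its resident
population while leaving mountainous prefectures underserved per square
kilometre, or match its GDP while lagging behind its population share.
`equipanel` implements the standard multi-indicator toolkit used in
Chinese regional health-resource studies — the grouped Gini coefficient,
the decomposable Theil index, and agglomeration degrees — against three
allocation bases (resident population, GDP, land area), together with
descriptive staffing indicators and a year-trend regression layer. All of
it operates on one canonical object: a long-format panel of headcounts by
year x region x personnel category, paired with a dimension table of the
three bases.

## Data model

A `panel()` couples `resources` (`year, province, city, category, count`)
with `dimensions` (`year, province, city, population, gdp, area_km2`).
Counts are stored in persons; yearbook tables printed in units of 10,000
persons ("wan") are converted on load (`load_panel(..., count_unit =
"wan")`). An empty `city` field marks a province-level record. Validation
is basis-aware: a panel with no GDP column still supports every
population-based analysis, and the descriptive layer (growth rates,
staffing-structure ratios) needs no dimension table at all — the shipped
`yrd_panel()` is exactly such a panel. Region identifiers are opaque
strings, trimmed but never normalised: there is no canonical prefecture
list, so the unit set is whatever the user supplies.

## The grouped Gini coefficient

Regions are ranked in **ascending order of resource density**
$d_i = c_i / b_i$ (staff per person, per hundred-million yuan, or per
km²), and the Lorenz polygon accumulates basis shares $X_i$ against
resource shares $Y_i$ from $(0,0)$ to $(1,1)$. The coefficient is the
trapezoid integral over all $n$ polygon segments,

$$G \;=\; 1 - \sum_{i=0}^{n-1} (X_{i+1}-X_i)(Y_i+Y_{i+1}),$$

which is zero exactly at perfect equality and bounded above by
$1 - \min_i X$-width for grouped data. Ties in density keep input order;
the value is unaffected because equal densities contribute identical
trapezoids. A second, independent route is provided by
`gini_pairwise()`, the weighted mean-absolute-difference form

$$G \;=\; \frac{\sum_i \sum_j p_i\, p_j\, |d_i - d_j|}{2 \bar d},
\qquad \bar d = \sum_i p_i d_i,$$

and the two routes agree to better than $10^{-12}$ on randomized grouped
inputs — this dual-route check is part of the test suite, not an internal
shortcut: the trapezoid path never calls the pairwise path.

Fairness bands follow the convention with 0.4 as the warning line, applied
half-open so classification is deterministic: $[0, 0.2)$ high fairness,
$[0.2, 0.3)$ comparative, $[0.3, 0.4)$ relative, $[0.4, 1]$ unfair. The
boundary 0.4 itself is "unfair" — it is the warning line, so a value
sitting on it should warn.

## The Theil index and its decomposition

With city resource shares $F_i$ and basis shares $P_i$ (each summing to
1),

$$T = \sum_i F_i \ln\!\frac{F_i}{P_i},$$

using the natural logarithm throughout and $0 \ln 0 := 0$ by continuity.
Grouping cities into provinces with totals $F_k, P_k$,

$$T = \underbrace{\sum_k F_k \ln\frac{F_k}{P_k}}_{T_\text{inter}}
    + \underbrace{\sum_k F_k\, T_k}_{T_\text{intra}},$$

where $T_k$ is the Theil index of the **group-renormalised** shares
$F_i/F_k$ vs $P_i/P_k$ — the only convention under which the identity is
exact, and the package tests it to $10^{-12}$ on randomized panels.
Contribution rates are $T_\text{inter}/T \times 100\%$ and
$T_\text{intra}/T \times 100\%$; they always sum to 100 when $T > 0$ and
are reported as `NA` when $T = 0$, where the split is undefined.

## Agglomeration degrees

The health resource agglomeration degree compares a region's staffing
density to a reference region's,

$$\mathrm{HRAD}_i = \frac{HR_i / A_i}{HR_n / A_n}, \qquad
  \mathrm{PAD}_i = \frac{P_i / A_i}{P_n / A_n},$$

and their ratio reduces algebraically to relative per-capita staffing,
$(HR_i/P_i)/(HR_n/P_n)$. Verdicts use 1 as the equity point with a
$10^{-9}$ equality tolerance (floating-point determinism): above 1
"better", below "worse". Two identities pin the implementation down:
area-weighted HRAD over any partition of the reference sums to exactly 1,
and the ratio matches the per-capita formulation to $10^{-12}$.

The reference region defaults to the **union of the regions in the
panel**, not to national totals: that keeps the computation closed over
the data actually supplied, and published agglomeration tables at
sub-national scale are generally consistent with a regional rather than a
national denominator. A larger reference (for instance national totals)
can be used by adding it as an explicit region and naming it in
`agglomeration_table(..., reference = )`.

## Descriptive indicators

Aggregate growth is the percentage change of summed headcounts between two
years over a region scope — invariant to the count unit. The
staffing-structure ("healthcare") ratio is rendered physicians : nurses as
`1:x` with `x = nurses / physicians`; the direction is fixed by how every
published cell reads (national planning targets call for 1:2). Printed
style values are rounded **half away from zero** at 2 decimals
(`round_half_up()`), since base R's round-half-to-even does not match how
yearbook tables are typeset; full precision is kept internally and
rounding is applied only at serialization in `run_analysis()`.

## Year-trend regression

Each fairness indicator is regressed on calendar year by ordinary least
squares, with a $t$-test on the slope ($df = n-2$) and a 95% confidence
interval. Year enters as a raw integer; an `origin` option re-centres it,
changing only the intercept — slope, standard error, $t$ and $p$ are
origin-invariant, which the tests assert. Synthetic series are often
exactly collinear, so the degenerate case is part of the contract rather
than an error: zero-residual fits report `se = 0`, a confidence interval
collapsed at the slope, and `p = 0` for a nonzero slope. A constant series
is also zero-residual but carries no trend, so it reports slope 0 with
`p = 1`. The collinearity threshold is relative
(RSS $\le 10^{-18} \sum y^2$), so it scales with the series.

## The synthetic panel generator

`generate_panel()` emulates the statistical structure of a
province-to-prefecture staffing panel so that every pipeline stage is
testable without yearbook data. City population and land area are
log-normal; GDP is population times a per-capita base with log-normal
noise; the per-10,000 staffing rate of province $k$, city $j$, year $t$
is

$$r_{kjt} = r_0 \exp\!\big(\eta_k + \varepsilon_j + \beta (t - t_0)\big),
\qquad \eta_k \sim N(0, \sigma_\text{inter}^2),\;
\varepsilon_j \sim N(0, \sigma_\text{intra}^2).$$

Defaults describe a Yangtze-River-Delta-like setting, chosen once as
plausible magnitudes for that region: 4 provinces x 10 prefecture cities
x 2014–2022; mean city population $4 \times 10^6$ (log-SD 0.5); mean area
9,000 km² (log-SD 0.5); GDP per capita 90,000 yuan with 0.2 log-SD noise
so GDP-basis indices vary distinctly from population; category base rates
(70, 28, 30, 3.5, 3.5 per 10,000 for technicians, physicians, nurses,
pharmacists, others) near the region's recent staffing levels; and
$\sigma_\text{inter} = 0.15 < \sigma_\text{intra} = 0.25$, so the
within-province component dominates the Theil decomposition, the
structure such regions actually show. Counts are real-valued by default —
integer rounding (available via `integer_counts`) would add noise that
obscures the $10^{-12}$ identity checks. One seed fixes the entire panel,
and the generator restores the caller's RNG state.

The generator deliberately does **not** emulate: spatial autocorrelation
between neighbouring cities, cross-city patient flows, year-to-year
population change, workforce attrition dynamics, or calibration to any
real province's magnitudes. Passing recovery tests therefore demonstrate
that the estimators measure what they claim under the assumed
log-normal/independent structure — not that real yearbook data satisfy
that structure.

### Trend injection

`inject_trend()` forces the overall Gini (on a chosen basis and category)
onto a linear path $g_t = g_0 + \beta(t - t_0)$ by tilting city densities
with a power transform: counts are reshaped as $c_i \propto b_i
d_i^\gamma$ with $\gamma$ solved per year by root-finding ($\gamma = 0$
gives perfect equality; the Gini is monotone in $\gamma$), preserving
each year's total headcount and every other category untouched. Targets
outside $[0, g(\gamma_{\max})]$ raise a feasibility error. The path is
matched to far better than the documented $10^{-6}$ per-year tolerance,
which has one statistical consequence: the injected series is essentially
collinear, so `fit_trend()` returns a (near-)degenerate confidence
interval at the estimated slope. Recovery experiments therefore judge
coverage with the documented injection tolerance ($10^{-6}$) as an
allowance around the interval — a decision made when the experiment was
designed, reflecting what "the true slope is recovered" can mean for an
exact path.

## Numerical choices, sizes, and limitations

* Identity checks (Gini dual-route, Theil additivity, HRAD partition) run
  on 1,000 randomized grouped inputs at $10^{-12}$; the worked
  decomposition examples are checked at their printed 7-decimal
  precision.
* The trend-recovery experiment uses 500 seeded replicates of the default
  4 x 10 x 9 panel with an injected decline of 0.01/yr from 0.30; the CI
  coverage experiment for noisy series uses 2,000 replicates at
  $\sigma = 0.02$. These sizes give stable Monte-Carlo estimates while
  keeping the default test run fast.
* Shares are validated to sum to 1 within $10^{-9}$; basis values must be
  strictly positive wherever an analysis uses them.
* The package computes inequality of *allocation*, not accessibility: no
  travel-time or gravity modelling stands behind HRAD, and the indicators
  say nothing about within-city distribution. Grouped Gini values depend
  on the unit list supplied; with few, large units the index is bounded
  well below 1.
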
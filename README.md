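# equipanel

Equity analysis of regional health-workforce allocation from long-format
staffing panels.

Health planners and health-services researchers routinely ask whether a
region's health human resources — technicians, physicians, nurses,
pharmacists — are distributed fairly across its sub-regions, and *fair
against what*: resident population, economic output, or land area.
`equipanel` implements the standard multi-indicator toolkit for that
question on a single canonical data object (a year × region × category
headcount panel plus a population/GDP/area dimension table):

- **Grouped Gini coefficient** from the Lorenz polygon over regions ranked
  by resource density, `G = 1 − Σ (X_{i+1} − X_i)(Y_i + Y_{i+1})`, with
  the conventional fairness bands (`[0, 0.2)` high, `[0.2, 0.3)`
  comparative, `[0.3, 0.4)` relative, `≥ 0.4` unfair) and an independent
  pairwise mean-absolute-difference oracle
  `G = Σᵢⱼ pᵢ pⱼ |dᵢ − dⱼ| / (2 d̄)`.
- **Theil index** `T = Σ Fᵢ ln(Fᵢ/Pᵢ)` with its exact decomposition
  `T = T_inter + T_intra` into between- and within-province components and
  contribution rates `T_·/T × 100%`.
- **Agglomeration degrees** `HRAD = (HRᵢ/Aᵢ)/(HRₙ/Aₙ)`,
  `PAD = (Pᵢ/Aᵢ)/(Pₙ/Aₙ)` and their ratio (relative per-capita staffing),
  with equity verdicts around 1.
- **Descriptive indicators**: aggregate growth rates, physician-to-nurse
  ratios (`1:x`), staffing per 10,000 population.
- **Year-trend regression** (OLS with slope t-test and 95% CI) over any of
  the above.
- A **seeded synthetic generator** of province→prefecture panels with
  controllable between/within-province dispersion, plus exact linear
  Gini-trend injection, so the whole pipeline is testable without
  yearbook data.

The package ships a province-level panel of the four Yangtze River Delta
provinces (2014–2022, five personnel categories) as a worked data set.

## Worked example

```r
library(equipanel)

p <- yrd_panel()                                # shipped 4-province panel
growth_rate(p, "registered_nurse", 2014, 2022)
#> [1] 75.33                                     # % growth of the 4-province total

subset(descriptive_table(p), province == "Shanghai" & year == 2022)$healthcare_ratio
#> [1] "1:1.24"                                   # nurses per physician

# synthetic prefecture-level panel: 4 provinces x 10 cities x 2014-2022
syn <- generate_panel(synthetic_config(seed = 2024))

head(gini_table(syn, bases = "population", categories = "registered_nurse"), 3)
#>   scope  year basis      category           gini classification
#> 1 P01    2014 population registered_nurse 0.0799 high
#> 2 P01    2015 population registered_nurse 0.0799 high
#> 3 P01    2016 population registered_nurse 0.0799 high

head(theil_table(syn, bases = "population", categories = "registered_nurse"), 1)
#>   year basis      category          total    inter  intra contrib_inter contrib_intra
#> 1 2014 population registered_nurse 0.0274  0.00233 0.0251          8.49          91.5

head(agglomeration_table(syn, categories = "registered_nurse"), 1)
#>   province year category          hrad  pad   ratio geo_verdict pop_verdict
#> 1 P01      2014 registered_nurse 0.911 0.989 0.922  worse       worse
```

The Gini of 0.08 says province P01 allocates nurses across its cities
almost in proportion to population (high-fairness band). The Theil
decomposition attributes ~92% of the panel-wide inequality to
within-province differences. P01's HRAD below 1 means it holds fewer
nurses per km² than the four-province aggregate, and the HRAD/PAD of 0.92
means its per-capita staffing also sits 8% below the aggregate.

`run_analysis(analysis_config(...))` executes all stages over a panel and
writes one CSV per table plus a JSON bundle and run log;
`inst/scripts/equipanel.R` wraps it for shell use (`run` and `synth`
subcommands).

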
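# sdohmarkers

County-level scoring and analysis of social-determinants-of-health (SDOH)
vulnerability markers and their alignment with primary care Health
Professional Shortage Areas (pcHPSAs).

## What it does

Health-workforce planners need to know not just *where* primary care
providers are scarce, but what else burdens the populations living there.
`sdohmarkers` implements a county-level ecological analysis for that
question:

1. **Marker scoring.** Every U.S. county (or county equivalent) is scored
   0/1 against fifteen binary markers of medical, economic, and geographic
   vulnerability. Twelve markers are national-quantile rules — a marker is
   set when the county measure *x* strictly exceeds the national 75th
   percentile (or, for median household income and population density, falls
   strictly below the 25th): `m = 1{x > Q_0.75(x_national)}`, with
   `Q` the linear-interpolation empirical quantile at position `1 + (n-1)q`.
   Three markers are pre-defined classifications: persistent poverty (an
   input flag), rurality (Rural-Urban Continuum Code 7–9 or Urban Influence
   Code 9–12), and pcHPSA-county status (whole/partial-county designation or
   at least one pcHPSA record active as of the 2017-07-01 snapshot).
2. **Burden summaries.** Per-county marker totals (0–15, missing scores
   count as zero), a data-driven high-burden cutoff (the smallest integer
   `t` such that "more than `t` markers" means exceeding the national 75th
   percentile of totals), regional summaries by HHS Region, marker
   frequency rankings among pcHPSA counties, and the full 15×15 conditional
   co-occurrence matrix `P(b = 1 | a = 1)`.
3. **Variability analysis.** A from-scratch Multiple Correspondence
   Analysis of the complete disjunctive coding of the markers (low birth
   weight excluded for missingness): eigenvalues `λ_k = σ_k²` from the SVD of
   the standardized correspondence residuals, total inertia `J/Q − 1`, and
   category contributions `ctr_jk = c_j g_jk² / λ_k`, which rank the
   markers driving cross-county variability in each HHS Region.
4. **Synthetic data.** Because the underlying AHRF/HRSA extracts are bulk
   downloads, a calibrated generator (`simulate_counties()`) emulates the
   3,142-county study design — Gaussian-copula-correlated measures,
   density-linked rurality codes, per-region pcHPSA rates — so the whole
   pipeline runs, and is tested, without any external data.

## Worked example

```r
library(sdohmarkers)

sim <- simulate_counties(sim_config(seed = 1))      # 3,142 counties
res <- run_pipeline(sim$counties, sim$hpsas)

res$overview
#> Counties: 3142
#>   no markers:           60 (1.9%)
#>   >= 10 markers:       240 (7.6%)
#>   at maximum (14):       2 (0.1%)
#>   >= 1 marker:        3082 (98%)

res$cutoff
#> [1] 6        # high burden = more than six markers

regional_summary(res$markers, sim$counties, res$cutoff, region = 4)
#> HHS Region 4: 736 counties, 681 pcHPSA (92.5%), 178 with > 6 markers (24.2%)
#> Top markers among pcHPSA counties:
#>   Poverty (37.9%)
#>   Education (34.5%)
#>   Low income (33.9%)

res$mca[["ALL"]]$sources
#> [1] "poverty"    "low_income"
```

Reading the output: 89% of the simulated counties are pcHPSA counties;
marker burden concentrates in HHS Regions 4 and 6; and the national MCA
identifies poverty and low income as the two markers contributing most to
cross-county variability among pcHPSA counties (the leading dimension
carries 30% of total inertia). `write_pipeline_outputs(res, "out/")` exports
the seven CSVs (per-county markers suitable for choropleth mapping,
regional summary, frequencies, co-occurrence, eigenvalues, contributions,
variability sources) plus a run log with every computed threshold.

To run from files instead, `read_county_table()` and `read_hpsa_file()`
ingest the documented CSV schemas (see `county_schema()`), with hard
validation errors for duplicate FIPS codes, unknown states, out-of-range
percentages, and unparseable dates.

## Vignette

`vignettes/sdoh-markers-methods.Rmd` documents the model and its
assumptions, every tunable parameter, the synthetic-data design and what it
does and does not emulate, and the numerical and design choices (quantile
estimator, strict inequalities, missing-data policy, MCA ranking rule).
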
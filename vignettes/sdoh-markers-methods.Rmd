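---
title: "Methods: county vulnerability markers, burden summaries, and MCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: county vulnerability markers, burden summaries, and MCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdohmarkers)
```

## The analysis

`sdohmarkers` implements a county-level ecological analysis of how primary
care Health Professional Shortage Area (pcHPSA) designations align with
other markers of medical, economic, and geographic vulnerability. The unit
of analysis is the U.S. county (or county equivalent, identified by a
5-digit FIPS code stored as a zero-padded string); the reference design
covers 3,142 counties across the ten HHS Regions, snapshotted at
2017-07-01.

Being ecological, the analysis describes *county populations*, not
individuals; a county with the poverty marker is a county in the national
top quartile of poverty rates, not a county where everyone is poor.

## The fifteen markers

Each county receives fifteen 0/1 scores (`score_markers()`). Twelve are
quantile rules against the *national* distribution of a continuous measure;
three are pre-defined classifications.

| # | Marker | Rule |
|---|--------|------|
| 1 | Older population | % aged 65+ > national Q75 |
| 2 | Low birth weight | LBW births per 1,000 > Q75 (may be missing) |
| 3 | Low income | median household income < Q25 |
| 4 | Unemployment | unemployment rate > Q75 |
| 5 | Poverty | % below 100% FPL > Q75 |
| 6 | Deep poverty, 65+ | % of adults 65+ in deep poverty > Q75 |
| 7 | Deep poverty, under 18 | % of children in deep poverty > Q75 |
| 8 | Persistent poverty | input flag (classification) |
| 9 | Education | % adults 25+ without HS diploma > Q75 |
| 10 | Race/ethnicity | % non-White or Hispanic origin > Q75 |
| 11 | Insurance | % uninsured ≤64 below 200% FPL > Q75 |
| 12 | Sparse population | persons per square mile < Q25 |
| 13 | Rurality | RUCC ∈ {7,8,9} or UIC ∈ {9..12} |
| 14 | pcHPSA county | AHRF whole/partial class, or ≥1 active pcHPSA record |
| 15 | pcHPSA count | county's pcHPSA count > Q75 of all counties' counts |

Numerical choices, fixed once and applied everywhere:

* **Quantile estimator.** Linear interpolation between order statistics at
  position $1 + (n-1)q$ (`stats::quantile`, type 7). The estimator choice
  only moves boundary ties; it is configurable through the rule set
  (`read_marker_rules()`) for sensitivity analyses.
* **Strict inequalities.** "Exceeds" means $>$, "is less than" means $<$.
  A county sitting exactly on a threshold scores 0.
* **Missing data.** Only the low birth weight rate may be missing (about a
  quarter of counties in the emulated data). Missing values are excluded
  from threshold computation, a missing measure yields a missing score, and
  missing scores count as **zero** toward the burden total — totals must be
  defined for every county despite LBW missingness — with a per-county
  `n_missing` carried for transparency. In frequency tables missing scores
  are excluded from the numerator only.
* **Marker 15's threshold** is computed over *all* counties' pcHPSA counts,
  zeros included. In designs where more than three quarters of counties
  have no designation the threshold is 0 and the marker reduces to "has at
  least one pcHPSA".
* **HPSA filtering.** A record counts only if its status is `designated`
  and its designation date is on or before the snapshot (default
  2017-07-01); `proposed_withdrawal` and `withdrawn` records and
  later designations are dropped. Status history is not reconstructed: the
  input file is treated as a snapshot.

## Burden and the high-burden cutoff

The burden total is the count of markers scored 1 (0–15).
`high_burden_cutoff()` returns the smallest integer $t$ such that
"more than $t$ markers" selects exactly the counties strictly above the
national 75th percentile of totals; under the reference design this yields
$t = 6$. Regional summaries report pcHPSA counties and high-burden pcHPSA
counties **as percentages of all counties in the region** (matching the
reference tables' denominators), rounded half-away-from-zero to one
decimal; exact whole hundreds print without decimals ("100"). Marker
frequency rankings among pcHPSA counties use the region's pcHPSA counties
as denominator, sort non-increasing, and break ties by marker id; the
pcHPSA-county marker itself (100% by construction) is omitted from the
top-3 display but retained in the full frequency export.

Conditional co-occurrence, `cooccurrence(a, b)`, is the percent of
in-scope counties with marker *a* that also carry marker *b* — asymmetric
by design, undefined (flagged, `NA`) when no county carries *a*.

## Multiple Correspondence Analysis

`run_mca()` is a from-scratch correspondence analysis of the complete
disjunctive coding: each of the $Q$ included markers contributes an
(absent, present) column pair, so every row of the $n \times 2Q$ indicator
matrix $Z$ sums to $Q$. With $P = Z / nQ$, row masses $r_i = 1/n$, and
column masses $c_j$, the standardized residuals
$s_{ij} = (p_{ij} - r_i c_j) / \sqrt{r_i c_j}$ are decomposed by SVD;
principal inertias are the squared singular values, total inertia is
$J'/Q' - 1$ (exactly 1 for all-binary codings), principal category
coordinates are $g_{jk} = v_{jk} \sigma_k / \sqrt{c_j}$, and the
contribution of category $j$ to dimension $k$ is
$c_j g_{jk}^2 / \lambda_k$; a variable's contribution sums its two
categories. The low birth weight marker is excluded by default (its
missingness would otherwise force county deletion); any other marker with
missing values is a hard error instructing exclusion rather than silent
dropping.

Degenerate inputs are handled explicitly: markers constant in scope are
removed with a message and $Q$ reduced (routine in regional runs — the
pcHPSA-county marker is constant among pcHPSA counties), an indicator with
no cross-row variation is an error, and regional fits require at least 15
in-scope counties. Tests compare coordinates up to per-dimension sign,
since singular vectors are sign-indeterminate. Benzécri-adjusted inertia
rates are available (`correction = "benzecri"`) but off by default.

### Ranking "variability sources"

`variability_sources()` maps the decomposition to a ranked marker list.
Two modes exist:

* **`dim1` (default):** rank by contribution to the first principal
  dimension — the single largest axis of cross-county association.
* **`weighted`:** sum eigenvalue-weighted contributions over the smallest
  leading dimension set reaching 50% of total inertia.

The weighted mode looks attractive but has a structural flaw for binary
SDOH data: a marker nearly independent of all others owns a dimension of
its own with inertia close to $1/Q$ and contribution close to 1, so its
weighted score ($\approx 1/Q$) beats members of the correlated deprivation
block that dimension 1 captures ($\approx$ their share of $\lambda_1$).
In planted-structure experiments the weighted rule recovered an isolated
high-count marker instead of the planted poverty/low-income pair in every
seed, while dimension-1 ranking recovered the pair in every seed. The
default is therefore `dim1`; the weighted mode remains available for
comparison.

## The synthetic generator

`simulate_counties()` emulates the study conditions so every stage is
testable without restricted downloads:

* **Design size.** 3,142 counties, allocated to the ten HHS Regions with
  the reference regional shares (largest-remainder apportionment), states
  drawn from each region's true composition, FIPS codes built from real
  state prefixes with sequential **odd** county codes (no collision with
  real counties, exercising zero-padding).
* **Continuous measures** via a Gaussian copula. The default correlation is
  a two-factor structure (a county deprivation factor plus an age/density
  factor) whose implied pairwise correlations are poverty–income $-0.88$,
  poverty–education $+0.64$, poverty–deep-poverty $+0.74$,
  poverty–unemployment and poverty–uninsured $+0.53$, income–density
  $+0.32$, and 65+–density $-0.30$; a factor construction is used because
  an arbitrary pairwise table need not be positive semi-definite. The
  poverty/income loadings are calibrated so the poverty → low-income
  conditional marker co-occurrence lands near the assumed 76% — pairwise
  latent correlation understates marker tail dependence once marginals and
  quartile thresholds are applied.
  Marginals are log-normal for income and density and beta-scaled for
  percent measures, with modest per-region latent shifts (higher poverty in
  Regions 4 and 6, lower density in 7, 8, and 10, older populations in 1
  and 3). Values are rounded to realistic precision (whole dollars, two
  decimals for percents), which also makes CSV round-trips exact.
* **Rurality codes** derive from a noisy copy of the density percentile
  (latent correlation 0.85, chosen from a closed-form bivariate-normal tail
  computation so that rural counties are sparse-population counties at
  roughly the reference conditional rate of ~58%), banded to approximate
  the national RUCC/UIC code distributions.
* **pcHPSA structure.** Per-region pcHPSA rates equal the reference
  regional percentages; counties with records draw 1 + negative-binomial
  extra designations with region-varying means; record-holding counties get
  AHRF class partial/whole/none with probabilities 0.7/0.1/0.2 (so both
  arms of the marker-14 OR rule are exercised), and zero-record counties
  can still be whole-county pcHPSAs where the regional rate requires it.
  The emitted designation file also contains withdrawn,
  proposed-for-withdrawal, and post-snapshot distractor records that the
  filter must remove.
* **Missingness.** LBW rates are masked missing completely at random at
  rate 0.25.
* **Determinism.** All randomness flows from the config seed; the same
  config yields byte-identical CSVs.

What the generator does **not** emulate: spatial autocorrelation between
neighboring counties, demographic micro-simulation, the exact marginal
distributions of the real AHRF measures (unpublished), or the real
geography of persistent poverty. Passing tests therefore demonstrate that
the pipeline's logic and numerics are correct under the assumed structure,
not that real-data tables would be reproduced digit-for-digit; real-data
marker frequency and variability tables are treated as qualitative
patterns (e.g., the national poverty/low-income variability pair, which
the calibrated default does recover).

`plant_structure()` supports recovery experiments: it inflates a region's
within-region spread on chosen measures by mapping the extreme half of the
region (by in-region rank) onto a national quantile band beyond the marker
threshold (q85–q98 high, q02–q15 low) and the rest onto a band around the
median, interpolated by an effect size in $[0,1]$. The mapping is
rank-preserving, so planted markers keep their copula correlations; effect
0 is the identity.

## Problem sizes and runtimes

The test suite simulates designs of 120–3,142 counties and cross-checks
the MCA against a brute-force residual-matrix decomposition on 100+ random
indicator matrices up to 30 rows × 10 categories; the planted-recovery
experiment uses 20 seeds of the full design with Region 6 (503 counties)
planted. The whole suite runs in well under a minute; the acceptance
script's full-design run takes a few seconds.

## Known limitations

* Boundary-tie behaviour at quantile thresholds depends on the estimator;
  the strict-inequality convention is fixed, but a different quantile
  definition could flip counties lying exactly on a threshold.
* The high-burden cutoff assumes integer totals; it is data-driven and so
  shifts with the burden distribution (use `burden_mode = "fixed:N"` to pin
  it).
* MCA variability rankings between strongly correlated markers (poverty
  and low income in particular) are close calls; single-marker rankings
  should be read jointly with the contribution table.
* The package consumes persistent-poverty status as an input flag; the
  underlying 10-20-30 rule over 1989/1999/2017 poverty estimates is out of
  scope.
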
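---
title: "Methods: constructing and comparing two area-level deprivation indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and comparing two area-level deprivation indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deprindex)
```

## The two indices

Area-level socioeconomic deprivation is usually measured with composite
indices built from census indicators. `deprindex` implements the two most
widely used U.S. designs and a pipeline for quantifying how far they agree.

**ADI (Area Deprivation Index).** A factor-based index of 17 block-group
indicators of income, education, employment and housing quality. Each
indicator is multiplied by its factor score coefficient and summed; seven
items whose larger values indicate affluence (median family income, white
collar occupation, high-school attainment, owner occupancy, median mortgage,
gross rent, home value) enter with negative coefficients. The weighted sums
are rescaled to mean 100 and standard deviation 20 and released as national
percentile ranks 0&ndash;100, higher meaning more deprived. Block groups with
fewer than 30 housing units, fewer than 100 people, more than one third of
the population in group quarters, or a census-acknowledged data error are
excluded (strict inequalities; the first violated rule in that order is the
recorded reason). For tract-level comparison the percentiles are aggregated
by population-weighted means and decile-ranked.

**SVI (Social Vulnerability Index).** A rank-based index of 15 tract
indicators in four themes (socioeconomic status; household composition and
disability; minority status and language; housing type and transportation).
Every item is percentile-ranked across tracts in [0, 1] after orienting it so
larger means more vulnerable (per capita income is the only reversed item);
item percentiles are summed within themes, theme sums are percentile-ranked,
and the overall score is the percentile rank of the total sum, again
decile-ranked for comparison.

## Agreement analysis

Tracts missing either index are dropped, and the paired scores feed:

* Spearman correlations of the continuous values and of the decile scores
  (Pearson correlation of average ranks; `spearman_rho()`).
* A 10&times;10 decile cross-tabulation (`decile_crosstab()`).
* Agreement classes: *good* for a 0&ndash;1 decile difference, *poor* for a
  difference of at least 6, *intermediate* otherwise
  (`classify_agreement()`). The cutoffs are configurable
  (`agreement_thresholds()`); `decile_margin_counts()` reproduces the
  marginal-count diagnostic that motivates the poor cutoff.
* Eight extreme-decile comparison groups (`build_comparisons()`): each of the
  four anchors (top/bottom decile of either index) split into its good and
  poor subgroups, with subgroup shares of the anchor count and mean scores on
  a common 0&ndash;100 scale. Reported gaps difference the two means after
  rounding each to one decimal, matching how such tables are printed;
  unrounded gaps are also emitted.
* Item drivers (`driver_analysis()`): per item, a two-sided Welch
  unequal-variance t-test between the poor and good subgroup and Cohen's
  *d* = (mean difference)/pooled SD, classified negligible/small/medium/large
  at 0.20/0.50/0.80. A *driver* is an item with p &lt; 0.05 and |d| &ge; 0.80;
  no multiplicity adjustment is applied by default (Benjamini&ndash;Hochberg
  available). Items bounded in [0, 1] are multiplied by 100 before
  comparison, and every item is also compared on a deprivation-oriented
  percentile-rank scale.
* Urban composition of each subgroup (`urban_fractions()`), with urbanicity
  taken from RUCA codes (1&ndash;3 urban by default).

## Conventions fixed by this package

Where the published descriptions of the two indices leave numerical freedom,
the package fixes one convention and exposes the alternative:

* **Percentile rank** is `(rank - 1) / (n - 1)` with average ranks for ties,
  so unique extremes map exactly to the endpoints. Tied extremes take their
  average rank.
* **Standardization SD** is the sample (n&minus;1) SD by default
  (`adi_config(sd_type = "population")` for the n convention).
* **Raw ADI scores** weight z-scored indicators: factor score coefficients
  presuppose standardized inputs, and dollar and proportion items are on
  incommensurable scales. `compute_raw_adi(..., standardize_items = FALSE)`
  gives the literal coefficient-times-value sum.
* **Aggregation quantity**: national percentiles are population-weighted to
  tracts (the released form of the ADI); standardized scores behind
  `adi_config(aggregate_on = "standardized")`.
* **Decile assignment** sorts by value with a stable tie-break on the unit
  identifier and slices rank *r* of *n* into decile `ceiling(10 r / n)`, so
  occupancies differ by at most one.
* **Overall SVI** ranks the sum of theme sums (equivalently of all 15 item
  percentiles); ranking the sum of theme percentile ranks is available via
  `svi_config(overall_from = "theme_percentiles")`.
* **Minority share** is stored directly as the vulnerable-direction item
  (1 &minus; non-Hispanic-White share), avoiding a reversed direction flag.
* **ADI factor coefficients** are config-supplied. When absent they are
  estimated from the input data by iterated principal-axis factoring of the
  correlation matrix of the 17 standardized items (squared multiple
  correlations as starting communalities; regression-method score
  coefficients `R^{-1} lambda`), sign-oriented so the poverty item is
  positive.

## The synthetic census generator

Real ADI/SVI releases derive from American Community Survey tables that this
package does not download; `generate_geography()` creates census-like inputs
with the statistical structure the agreement analysis assumes:

* Nested geography: states &rarr; tracts &rarr; 1&ndash;5 block groups, block
  group populations uniform on 600&ndash;3,000 (census block-group scale),
  with a geography table linking levels and a population-conservation
  invariant.
* A dominant latent deprivation factor *D* ~ N(0,1) per tract, loading on all
  27 unique items with signed loadings; poverty, income and education items
  carry the largest magnitudes.
* A latent urban housing-market factor
  *H* = `housing_urban_shift`&middot;urban +
  `housing_confound_strength`&middot;&epsilon;, &epsilon; ~ N(0,1), entering
  only the three housing-cost items (median home value, mortgage, gross rent)
  with sensitivities 0.30/0.27/0.24 in log-dollars. Urban flags are
  Bernoulli(`urban_probability`) and surfaced as RUCA codes (1&ndash;3 urban,
  4&ndash;10 rural).
* Proportion items are inverse-logit transforms and dollar items exponential
  transforms of `base + loading * D + gamma * H + noise`, giving
  range-correct rates and heavy-tailed housing costs. Item noise is drawn
  mostly at tract level (`noise_sd`, default 0.85 on the latent scale) with a
  half-scale block-group component; dollar items use 0.3&times; the scale,
  administrative medians being more stable than small-sample survey rates.
  These values put item&ndash;factor correlations near 0.5&ndash;0.8 and the
  decile-level correlation of the two finished indices near 0.8.
* A configurable fraction of block groups is forced to violate one ADI
  exclusion rule, covering the exclusion edge cases.

Tract items are population-weighted means of their block groups' values.
Given a seed the output is reproducible byte for byte, and the draw order
does not depend on parameter values, so runs differing only in
`housing_confound_strength` share every latent and noise draw.

### The housing-cost confound and the calibration era

The divergence mechanism under study is that a factor-weighted index with
fixed historical coefficients misreads expensive urban housing as affluence.
Two design decisions in this package encode that situation:

1. In the analysis-era data the housing-cost items load only weakly on
   deprivation (defaults &minus;0.15/&minus;0.12/&minus;0.12): urban market
   heterogeneity and gentrification largely decouple prices from
   neighborhood deprivation in today's cross-section.
2. `adi_reference_coefficients()` estimates the factor score coefficients on
   a matched reference run with the market factor switched off and the
   housing items loading strongly (&minus;0.65/&minus;0.60/&minus;0.55),
   emulating a calibration era in which housing cost was a valid deprivation
   signal. Mechanism studies construct the ADI with these fixed weights.

The second point matters because estimating coefficients on the confounded
data itself (the in-pipeline default when no coefficients are supplied) is
self-correcting: principal-axis factoring down-weights exactly the items the
market factor inflates, so the finished index barely reacts to the confound.
A deployed index does not enjoy that protection &mdash; its weights were fixed
long before the present housing market &mdash; and the reference-calibration
helper reproduces the deployed situation. Both routes are exported; studies
of the confound should use the reference coefficients.

Because dollar items are log-normal, the same idiosyncratic market draw
moves urban tracts (already shifted up by the urban premium, about twice
rural costs at the median) much further in raw dollars than rural ones.
High-deprivation urban tracts in the upper market tail are therefore the
tracts whose ADI collapses while their SVI stays high &mdash; the mismatch
group that drives poor agreement, and in synthetic runs with a strong
confound (strength 2) it is almost entirely urban and its item drivers are
the three housing-cost items.

### What the generator does not emulate

Single-factor deprivation plus one market factor cannot reproduce the full
multidimensionality of real indicator tables: the decile correlation between
the finished synthetic indices (~0.8) is well above the ~0.5 reported for
the real products, so synthetic mismatch groups are relatively smaller and
purer than real ones. There is no spatial autocorrelation, no person-level
population synthesis, and no emulation of specific ACS variable codes or
sampling error models. Passing tests on this generator validate the
pipeline's arithmetic and the direction of the confound mechanism, not the
empirical magnitudes of any real-data comparison.

## Problem sizes and numerical choices

Package tests exercise the pipeline end to end on geographies of 1,000
tracts (about 3,000 block groups), the scale at which decile occupancies,
mismatch groups and driver tests are all well populated while a full
five-replicate mechanism study runs in seconds. Standardization requires at
least two distinct retained scores (constant input is a degenerate-input
error); ranking requires two non-missing values and decile assignment ten.
Factoring iterates communalities to 1e-8 with a cap of 0.999 to keep the
reduced correlation matrix well behaved. Exclusion rules use strict
inequalities, so boundary units (exactly 30 housing units, 100 people, or a
group-quarters share of exactly one third) are retained.

## A worked run

```{r example, eval = FALSE}
params <- synthetic_params(housing_confound_strength = 2,
                           urban_probability = 0.3, seed = 1)
geo <- generate_geography(params)

coef <- adi_reference_coefficients(params)
adi <- compute_adi(geo$blockgroups, adi_config(coefficients = coef))
svi <- compute_svi(geo$tracts)

records <- classify_agreement(
  pair_indices(adi$tract_scores, svi$tract_scores, geo$tracts))
agreement_summary(records)

comparisons <- build_comparisons(records)
items <- tract_item_table(geo$blockgroups, geo$tracts)
drivers_II <- driver_analysis(records, items, "II")
urban_fractions(records)
```

`run_pipeline()` wires the same steps behind a single configuration and
writes every table, a GeoJSON export and a JSON manifest; a thin command-line
front end is installed under `inst/cli/deprindex.R`.
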
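---
title: "Curating historical genebank regeneration phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating historical genebank regeneration phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocurate)
```

## The data problem

Genebanks regenerate their seed stocks by growing accessions in field
campaigns, and they score a few traits every time -- typically days to
heading (HD), plant height (PH) and thousand kernel weight (TKW).  Because
an accession is only grown when its stock runs low, the accession-by-year
incidence matrix is extremely sparse and unbalanced: most accessions appear
in one or two campaigns, a handful in dozens.  The records accumulate over
decades, under changing staff and conventions, so they contain recording
errors, entire failed campaigns, and isolated aberrant values.  This package
turns such raw records into curated per-accession trait estimates with an
attached quality statement (an entry-mean heritability), using only the
structure the data themselves provide.

## The model

All curation is organized around the additive two-way linear mixed model

$$y_{ij} = \mu + g_i + a_j + e_{ij},$$

where $y_{ij}$ is the phenotype of accession $i$ in campaign year $j$,
$g_i$ the accession effect, $a_j$ the year effect, and
$e_{ij} \sim N(0, \sigma^2_{e,j})$ a residual with a **year-specific**
variance.  Heterogeneous residual variances matter here: campaigns differ in
scoring staff, weather and management, and a pooled residual variance would
let one noisy campaign contaminate the standardized residuals of every
other campaign.

The accession term is used in two roles:

* **random** ($g_i \sim N(0, \sigma^2_G)$) when the goal is variance
  components and heritability;
* **fixed** when the goal is outlier detection and per-accession BLUEs.

The year term is random except in the campaign-scoring stage, where the
roles are reversed (campaign fixed, accession random) so that each
campaign's mean and residual variance can be read off directly.

`fit_reml()` maximizes the restricted likelihood through the sparse
mixed-model equations (`Matrix` Cholesky with a cached symbolic analysis),
over log-parameterized variance components with a finite-difference
gradient and an `nlminb` + `L-BFGS-B` polish.  On balanced designs the
estimates agree with closed-form ANOVA estimators to better than $10^{-6}$
relative error, and on heterogeneous unbalanced data they agree with
`nlme::lme(weights = varIdent(...))` (both checked in the test suite; the
external packages serve only as cross-checks, never as the implementation).

Numerical choices worth knowing:

* observations are centred before fitting (exactly neutral for REML, but it
  removes a catastrophic-cancellation term from the objective);
* each variance has a floor of $10^{-8}\,\mathrm{var}(y)$; estimates ending
  on the floor are reported in `fit$boundary`, never silently clipped;
* years with fewer than 3 records share one pooled residual variance
  (reported in `fit$pooled_years`) -- two records barely identify a mean,
  let alone a variance;
* BLUEs use cell-means coding (accession indicators, no intercept), so the
  fixed-effect solutions are directly on the observation scale
  $\mu + g_i$.  This is algebraically equivalent to reference-level coding
  followed by recentring, and avoids the arbitrary choice of a reference
  accession.  Standard errors use the normal approximation, with no
  small-sample degrees-of-freedom correction.

## The curation sequence

`run_pipeline()` executes, per genebank collection, seasonal type and trait
(the caller slices; records of unclassified seasonal type form their own
group):

1. **Plausibility trimming** (`apply_range_filter()`): deliberately lax
   closed-interval screens against recording errors -- 5--250 cm for PH,
   50--250 days for HD, 5--100 g for TKW.
2. **Connectivity filtering** (`apply_connectivity_filter()`): accessions
   tested in a single year and campaigns holding a single record carry no
   information for a two-way model; both rules are iterated to a fixed
   point, because removing a sparse campaign can strand an accession in a
   single year and vice versa.  The fixed point is the only
   order-independent reading of the two rules (verified against a
   randomized repeat-until-stable oracle).  A `strict_plus_one` switch
   raises both thresholds by one for poorly connected collections; it is
   off by default and deliberately manual, since no automatic trigger for
   the stricter setting is defined.
3. **Campaign-level outliers** (`campaign_cv_scores()` +
   `drop_outlier_campaigns()`): fit with campaign fixed / accession random,
   compute per-campaign coefficients of variation
   $CV_j = \hat\sigma_{e,j} / |\hat m_j|$, standardize across campaigns,
   and drop campaigns with a z-score above 3.5.  The CV is taken of the
   *fitted* campaign dispersion and mean rather than of raw campaign
   values; this follows directly from extracting the heterogeneous error
   variances first, and the definition is isolated in one function so the
   raw-value alternative is a one-line change.  Removal is one-sided: low
   dispersion is not an error signal.  This stage runs once, not iterated.
   Note a structural fact about z-scores: with $m$ campaigns the largest
   attainable standardized CV is $(m-1)/\sqrt{m}$, so with fewer than about
   15 campaigns the 3.5 threshold can never fire -- the stage is only
   informative for collections with long campaign histories.
4. **Point-level outliers** (`flag_outlier_points()`): refit with accession
   fixed / campaign random, standardize residuals by their year's
   $\hat\sigma_{e,j}$, convert to two-sided normal p-values, Holm-adjust,
   and remove records with adjusted $p < 0.05$ (strict inequality).
5. **Variance components and heritability**: a final random-genotype fit on
   the curated records gives $\hat\sigma^2_G$ and
   $\hat\sigma^2_{e,j}$, and the entry-mean heritability
   $$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_e/\bar N_Y},$$
   with $\bar N_Y$ the mean number of test years per accession in the
   curated data.  The single $\sigma^2_e$ is the **unweighted mean** of the
   year-specific variances; the formula is written with one error variance
   and some collapse rule must be chosen, so the choice is exposed
   (`sigma2_e_summary`: mean, record-weighted mean, or median).
6. **BLUEs**: a fixed-genotype fit of the curated records (reused from
   step 4 when no points were removed).

After stages 3 and 4 the connectivity filter is re-applied: removing a
campaign or a record can strand accessions in a single year, and the later
fits require the connectivity guarantee.  These re-checks are logged as
separate stages so the retention percentages reconcile exactly:
`raw = kept + sum(all stage removals)`, an invariant the tests assert.

A collection can legitimately end empty (every accession tested once, say);
the report then carries the explicit `"no_data"` state rather than NAs of
unclear origin, and batch runs continue past it.  Non-convergence of a fit
is likewise a flagged report state, never a silent result.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of deposited regeneration data:
a right-skewed number of test years per accession (default profile 0.55 /
0.25 / 0.10 / 0.05 / 0.05 over 1--5 years, the shape of real incidence
histograms with the bulk at one or two campaigns), one record per accession
per campaign, additive accession and year effects, year-specific residual
noise, and trait-scale presets (HD: mean 150 d; PH: 100 cm; TKW: 40 g, with
variance defaults well inside the plausibility windows).
`inject_outliers()` adds the two contamination types the pipeline is built
to remove: points shifted by a multiple of the local residual SD with a
fair-coin sign, and campaigns whose residuals are redrawn with inflated
variance -- variance inflation, not a mean shift, because the campaign
detector targets dispersion.  Everything is labelled in a truth object, so
recovery is measurable.

What the generator does **not** emulate: within-year replicates, spatial
field trends, genotype-by-year interaction, drifting measurement
conventions, or non-normal error tails.  Passing recovery tests therefore
demonstrate that the estimators are correct under the stated model, not
that real genebank data satisfy that model.

## Validation experiments and problem sizes

Two packaged experiments (used by both the test suite and
`scripts/acceptance.R`) state the package's empirical claims:

* `heritability_recovery_experiment()`: 20 replicates of 2,000 accessions
  over 12 years with $\sigma^2_G = 4$ and per-year residual variances
  averaging 1.96, a setting whose true entry-mean heritability at the
  expected post-curation replication ($\bar N_Y \approx 2.78$) is 0.85.
  The claim is that the pipeline's mean reported $h^2$ is within 0.05 of
  the mean true value.
* `outlier_recovery_experiment()`: 20 replicates of roughly 10,000 records
  over 20 campaigns, contaminated with 1% point outliers at 8 local SDs and
  one campaign at 25-fold residual variance.  The campaign stage is
  expected to remove the inflated campaign essentially always, with false
  point flags at or below 1 per 1,000 clean records.

Smaller Monte-Carlo checks (null calibration of the campaign scores,
familywise error of the point stage) run at reduced replicate counts chosen
to keep the default test suite quick while leaving the Monte-Carlo noise
well below the margins being asserted.

## A known limitation of the point-outlier stage

The fixed-genotype residuals that drive step 4 carry the leverage of the
accession means.  For an accession tested in $k$ years, a single shifted
record retains only a fraction $(1 - 1/k)$ of its shift in its residual,
and for $k = 2$ the two residuals are *exactly* opposite
($r_1 = -r_2$): the procedure cannot tell which of the pair is the
aberrant one.  Under the default right-skewed replication profile, about
40% of post-filter records belong to two-year accessions, so the
achievable sensitivity of the point stage against 8-SD outliers is far
below 1 (about 0.3 in the packaged experiment) even though its
false-flag rate is excellent.  This is a property of the detector's design
-- Holm-tested standardized residuals from a fixed-genotype fit -- not of
the implementation: any re-scaling of the residuals trades the missed
two-year outliers against falsely flagging their siblings.  In practice the
stage is best understood as removing *gross* errors on accessions with
adequate replication, while the plausibility screen catches the rest.

## Worked example

```{r, eval = FALSE}
p <- simulation_params(500, 12, trait = "PH", point_outlier_rate = 0.01,
                       n_outlier_campaigns = 1, seed = 42)
sim <- simulate_dataset(p)
con <- inject_outliers(sim$dataset, sim$truth, p)

res <- run_pipeline(con$dataset, pipeline_config("PH", label = "demo"))
res$report
summarize_collections(list(res))
true_heritability(sim$truth, res$curated)
```

## Exchange format

`read_workbook()` / `write_curated()` move datasets through a MIAPPE-style
tabular layout: three logical sections (study metadata,
observation-variable definitions, long-format data) as `study.csv`,
`variables.csv`, `data.csv` in a directory, with `.xlsx` reading supported
when `readxl` is installed.  Column headers are mapped through a layout
object rather than hard-coded, values are written with 17 significant
digits so round-trips are bit-exact, empty cells and the literal token
`"NA"` mean "absent" while any other non-numeric token is an error-logged
skip, and accessions are identified throughout by the standard triplet of
FAO-WIEWS institute code, genus and accession number.  Heading-date values
are stored as plain numbers with the reference convention (days from
January 1 vs from sowing) carried in the trait's method note and never
converted, because the convention differs between genebanks and silent
conversion would manufacture comparability that the data do not have.
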
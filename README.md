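# phenocurate

Curation and quality validation of historical phenotype records from
genebank seed-regeneration campaigns.

## The problem

Genebanks score a few traits — days to heading (HD), plant height (PH),
thousand kernel weight (TKW) — every time an accession is grown out to
refresh its seed stock.  Decades of such records are a valuable phenotyping
resource, but a messy one: accessions are grown only when stocks run low,
so the accession × year incidence is extremely sparse and non-orthogonal
(most accessions appear in one or two campaigns), and the raw values carry
recording errors, failed campaigns and isolated aberrant points.
`phenocurate` is for data curators and quantitative geneticists who need to
turn such records into per-accession trait estimates with an attached
quality statement.

## The method

Everything is organized around the additive two-way mixed model

    y_ij = mu + g_i + a_j + e_ij,    e_ij ~ N(0, sigma^2_e,j)

with accession effects `g_i`, campaign-year effects `a_j`, and a
**year-specific** residual variance, fitted by REML on the sparse
mixed-model equations.  The curation sequence per collection × seasonal
type × trait:

1. plausibility trimming (lax closed intervals: 5–250 cm PH, 50–250 d HD,
   5–100 g TKW);
2. connectivity filtering to a fixed point (single-year accessions and
   single-point campaigns out);
3. campaign-level outlier removal: fit with campaign fixed, standardize the
   per-campaign coefficients of variation `sigma_e,j / |mean_j|`, drop
   campaigns with z > 3.5;
4. point-level outlier removal: fit with accession fixed, Holm-adjust
   two-sided normal p-values of the standardized residuals, drop records
   with adjusted p < 0.05;
5. final random-genotype fit, entry-mean heritability
   `h2 = sigma2_G / (sigma2_G + sigma2_e / Nbar_Y)`, and BLUEs of the
   accession means.

A synthetic-data generator with full ground truth (`simulate_dataset()`,
`inject_outliers()`) makes every stage testable, and a MIAPPE-style tabular
reader/writer (`read_workbook()`, `write_curated()`) moves data in and out.

## Worked example

```r
library(phenocurate)

p   <- simulation_params(500, 20, trait = "PH", point_outlier_rate = 0.01,
                         n_outlier_campaigns = 1, seed = 42)
sim <- simulate_dataset(p)
con <- inject_outliers(sim$dataset, sim$truth, p)

res <- run_pipeline(con$dataset, pipeline_config("PH", label = "demo"))
res$report
#> <curation_report demo: ok>
#>   raw: 901 points / 500 accessions
#>   kept: 573 points (63.6%) / 201 accessions (40.2%)
#>   heritability: 0.806  (N_bar_Y = 2.85)

true_heritability(sim$truth, res$curated)
#> [1] 0.8533262
```

Reading the report: 901 raw records shrink to 573 — the connectivity filter
removes the single-year accessions (the bulk of the reduction, as in real
regeneration data), the campaign stage has removed the variance-inflated
campaign (`res$report$logs$campaign_cv$years_removed` names it), and the
Holm stage a handful of shifted points.  The reported entry-mean
heritability 0.806 is a noisy but unbiased estimate of the ground-truth
value 0.853 computed from the generating parameters (at 500 accessions the
accession-variance estimate carries visible sampling noise; the packaged
20-seed experiment at 2,000 accessions recovers the true value to within
0.01 on average), and `res$blues` holds one
trait-scale BLUE (with standard error) per retained accession.
`summarize_collections()` turns a list of such reports into the standard
summary table (data points, accessions, % kept, heritability);
`plot_reports()` writes the diagnostic panels.

A thin CLI over the same functions is in
`inst/scripts/phenocurate.R` (`simulate`, `filter`, `outliers`, `fit`,
`run` subcommands).

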
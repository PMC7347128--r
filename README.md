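# blight311

Measure urban blight from municipal 311 service-request data.

Urban blight — litter, graffiti, vacant or abandoned property, sidewalks
in disrepair — is a neighborhood exposure with documented links to
violence, mental health, and chronic disease, yet it is usually measured
with expensive street audits or one-dimensional proxies such as vacancy
rates. 311 systems log millions of georeferenced complaints a year with
free-text descriptions. `blight311` turns those records into a
tract-level blight surface, for epidemiologists, urban planners, and
public-health analysts.

## The algorithm

Given a labelled training corpus (complaint types mapped to seven blight
domains or non-blight, with rater agreement quantified by Cohen's
kappa), the package:

1. cleans and tokenizes call descriptions (case folding, punctuation
   stripping, explicit misspelling map, stopword removal);
2. partitions the training vocabulary into blight-exclusive,
   non-blight-exclusive, and shared tokens, and scores every call by its
   count of **distinct** blight-lexicon tokens
   (`unique_token_count`);
3. fits logistic regressions of the blight label —

   ```
   model 1:  logit P(y=1) = β₀ + β₁·(unique token count)
   model 2:  … + borough          (5 levels, Bronx reference)
   model 3:  … + borough + agency (15 levels, "unassigned" reference)
   ```

4. validates on held-out labelled calls with full confusion-matrix
   metrics (sensitivity, specificity, accuracy, PPV, NPV); and
5. aggregates classified calls to census tracts (point-in-polygon on
   GeoJSON tract polygons) and correlates the per-tract percent of
   blight-classified calls against ACS and HUD/USPS vacancy measures
   (Pearson r with t-based p-values), the standard convergent-validity
   check.

A synthetic-data module generates 311-like corpora, toy tract grids, and
vacancy tables with known ground truth — through the same CSV/GeoJSON
dialects the readers parse — so the whole pipeline is testable offline.

## Worked example

```r
library(blight311)
library(dplyr)

dir <- file.path(tempdir(), "demo"); dir.create(dir)
sim <- simulate_calls(sim_config(n_records = 4000, n_tracts = 16,
                                 exclusivity = 0.7, seed = 7))
write_calls_csv(sim$calls, file.path(dir, "calls.csv"))
readr::write_csv(sim$mapping, file.path(dir, "mapping.csv"))
write_tracts_geojson(sim$tracts, file.path(dir, "tracts.geojson"))

res <- run_pipeline(pipeline_config(
  calls = file.path(dir, "calls.csv"),
  mapping = file.path(dir, "mapping.csv"),
  tracts = file.path(dir, "tracts.geojson"),
  out_dir = file.path(dir, "run"),
  model_id = 2, min_count = 50, shared_ratio = 2, seed = 7
))

res$lexicon
#> <blight_lexicon> 1113 tokens: 384 blight-exclusive (35%), 415
#> non-blight-exclusive (37%), 314 shared (28%); scoring vocabulary 524 tokens

tidy(res$model)
#> # A tibble: 6 × 5
#>   term                  estimate std.error statistic  p.value
#>   <chr>                    <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)             -5.08      0.480   -10.6   3.05e-26
#> 2 unique_token_count       2.48      0.178    14.0   2.17e-44
#> 3 borough:Brooklyn        -1.03      0.470    -2.20  2.78e- 2
#> 4 borough:Manhattan        0.137     0.469     0.292 7.70e- 1
#> 5 borough:Queens          -0.515     0.460    -1.12  2.63e- 1
#> 6 borough:Staten Island    0.526     0.637     0.825 4.09e- 1

res$evaluation$metrics |> select(ends_with("_pct")) |> round(1)
#> # A tibble: 1 × 6
#>   prevalence_pct sensitivity_pct specificity_pct accuracy_pct ppv_pct npv_pct
#> 1           63.6            96.4            95.1         95.9    97.1    93.8

head(res$summaries, 4)
#> # A tibble: 4 × 4
#>   tract_id    n_calls n_blight_predicted pct_blight
#> 1 36000000001     274                160       58.4
#> 2 36000000002     260                162       62.3
#> 3 36000000003     231                130       56.3
#> 4 36000000004     244                140       57.4
```

The lexicon line says 35% of the realized training vocabulary appeared
only in blight-labelled calls (the generator leaks a third of its blight
vocabulary into non-blight records, so those tokens surface as shared;
the skew-ratio rule admits them back into the 524-token scoring
vocabulary). The positive `unique_token_count` coefficient is the core
signal: each additional distinct lexicon token multiplies the odds a
call is blight-related by about e^2.5 in this synthetic regime. Holdout
sensitivity/specificity near 96/95 reflect a corpus whose vocabulary
separates classes far more cleanly than real city text does. The tract
table is the output a practitioner maps: percent of calls classified
blight-related, per tract.

Every artifact (lexicon CSV, model JSON, evaluation JSON, tract
summaries CSV/GeoJSON, correlation table, seed-stamped manifest) is also
written to `out_dir`. A thin command-line wrapper ships at
`inst/cli/blight311.R` (`simulate` and `run-all` subcommands over a YAML
config).

## Documentation

The methods vignette (`vignettes/blight-identification.Rmd`) documents
the model and its assumptions, the generator's design (including the
token-level exclusivity mechanism and the quasi-separation regime), all
tunable parameters with defaults and rationale, numerical choices, and
known limitations.
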
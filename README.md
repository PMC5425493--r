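# aquaros

Censored-data analysis of arsenic and uranium in unregulated drinking-water
sources.

## The problem

Rural populations without piped water haul it from unregulated wells,
springs and storage tanks. In former uranium-mining regions those sources
are sampled — when they are sampled at all — by different agencies whose
laboratories report anything below their own *reporting limit* only as
"not detected". The result is a multiply left-censored dataset: the same
analyte may be censored at 0.01 µg/L in one survey and at 10 µg/L in
another. Naive substitution (zero, the limit, half the limit) biases
every summary statistic. The questions that matter are nevertheless
simple: how often do arsenic and uranium exceed their drinking-water
Maximum Contaminant Levels (MCLs: 10 µg/L As, 30 µg/L U), how often do
they exceed them *together*, and are sources near abandoned uranium
mines worse than distant ones?

## What the package implements

* **Robust regression on order statistics (ROS)** for multiply
  left-censored data: the Hirsch–Stedinger exceedance-probability
  recursion over the distinct censoring limits, Weibull plotting
  positions, regression of log detects on normal scores, imputation of
  nondetects from the fitted line, and summary statistics on the
  combined set in original units — `ros_fit()`.
* **Harmonisation** of heterogeneous surveys: uranium activity → mass
  (0.67 pCi/µg), exclusion of undocumented results, maximum observation
  per source — `harmonize()`.
* **Exceedance screening**: MCL and half-MCL (co-)exceedance with
  indeterminate flags for nondetects whose limits exceed a threshold,
  Kendall tau-b correlation between the analytes — `co_exceedance()`,
  `kendall_tau()`.
* **Mine proximity**: haversine distance to the nearest mine, a strict
  6.4 km near/far partition, a Peto–Peto two-group test for censored
  concentrations, and a binned distance–concentration profile —
  `nearest_mine()`, `partition_summaries()`, `distance_profile()`.
* **A synthetic multi-survey generator** (`generate_survey()`,
  `multi_survey_preset()`) reproducing the statistical structure above —
  correlated lognormal analytes, survey-specific limits, clustered
  mines with an exponentially decaying enrichment — so the whole
  pipeline is testable without any external data.
* **A pipeline** (`run_pipeline()`) emitting regional summary tables,
  near/far tables with tests, profile CSVs, a GeoJSON point map and a
  run manifest. A thin CLI lives in `inst/cli/aquaros.R`.

## Worked example

```r
library(aquaros)

# a multiply censored stratum: nondetects at 1 and 2 ug/L
fit <- ros_fit(values   = c(1, 1.5, 2, 2.5, 5),
               censored = c(TRUE, FALSE, TRUE, FALSE, FALSE))
fit
#> Robust ROS fit: n = 5 (2 censored at 2 levels)
#>   log-scale intercept 0.4682, slope 0.9493
#>   mean 2.11  median 1.5  sd 1.77  IQR 0.971-2.5 ug/L
fit$imputed_values
#> [1] 0.5970990 0.9708388
```

The two nondetects (`<1`, `<2`) are imputed at 0.60 and 0.97 µg/L from
the log-scale regression line, and the reported mean (2.11 µg/L) is the
plain average of `{0.60, 1.5, 0.97, 2.5, 5}` — no substitution constant
ever enters.

End to end on a synthetic campaign:

```r
sim <- simulate_to_dir(multi_survey_preset(seed = 11), "demo")
res <- run_pipeline(sim["sources"], sim["mines"], analysis_config(), "demo/report")
subset(res$summary, stratum == "overall",
       c(analyte, n, detection_frequency_pct, ros_median, frac_exceed_mcl_pct))
#>   analyte   n detection_frequency_pct ros_median frac_exceed_mcl_pct
#> 1 arsenic 464                    37.5   1.555739                21.8
#> 7 uranium 464                    78.4   4.496458                16.8
res$proximity_tests
#>   analyte statistic      p_value n_far n_near
#> 1 arsenic  51.75426 6.290023e-13   378     86
#> 2 uranium  46.40670 9.608640e-12   378     86
```

464 of the 468 generated sources survive the documentation rules; 37 %
have detectable arsenic, a fifth exceed the arsenic MCL, and sources
within 6.4 km of a mine have significantly higher concentrations of both
analytes (Peto–Peto χ² with 1 df). `demo/report/` then contains the
summary CSVs, `distance_profile.csv` (per-bin ROS medians declining to
the overall median by ~25–30 km), `sources.geojson` and
`manifest.json`.

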
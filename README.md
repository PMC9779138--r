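# aqgapfill

Sub-range neural regression for filling gaps in hourly air-monitoring records.

## The problem

Automatic air-monitoring stations record 1-hour averages of pollutant
concentrations (O3, NO, NO2, SO2, CO, PM10) and meteorology (wind speed WS,
temperature T, solar radiation I, relative humidity RH). Air-quality assessment
requires nearly complete hourly series, but real records miss 4–20% of hours
per variable. When the target pollutant's true value is absent while
co-measured variables are present, a regression model trained on the station's
own history can approximate it.

A single model over the whole concentration range is least accurate exactly
where it matters — at high concentrations. This package implements **segmented
modeling**: sort the complete cases by a key value, cut them into k
equal-count sub-ranges (k ∈ {1, 2, 4, 8}), and train an independent
multilayer perceptron per sub-range:

* **RVS** (Real Values Sorting) sorts by the *true* target concentration — an
  oracle that quantifies the potential gain of segmentation (it cannot route
  unseen cases).
* **PVS** (Predicted Values Sorting) trains a preliminary full-range model,
  sorts by its *predictions*, and stores the cut points so unseen cases are
  routable: stage-1 prediction → boundary comparison → dedicated sub-model.

Each (sub-)model is a fixed architecture — inputs → 10 logistic hidden units →
1 logistic output — trained by full-batch BFGS on the sum-of-squares loss

    SOS = Σᵢ (ŷᵢ − yᵢ)²,

capped at 300 iterations, from Gaussian random starts, best of 5 restarts by
validation SOS, on a seeded 70/15/15 train/validation/test split. Accuracy is
reported per sub-range and overall as

    MAE = (1/n) Σ|xᵢ − yᵢ|,   RMSE = √(Σ(xᵢ − yᵢ)²/n),

where the **overall** MAE/RMSE is the arithmetic mean of the per-sub-range
values, and segmented models are compared with the full-range model via
100·(sub − full)/full percentage changes.

Because the station data behind the reference design are not public, the
package ships a synthetic generator of monitoring-like hourly series (seasonal
and diurnal cycles, AR(1) persistence, structurally positive right-skewed
concentrations, O3–NO anticorrelation, PM10–SO2 winter coupling, realistic
missingness), so the whole pipeline is testable end to end.

## Worked example

```r
library(aqgapfill)

# six synthetic years at the urban-background profile
series <- generate_series(default_station_config("zabrze", seed = 1))
series
#> <monitoring_series> station: synthetic-zabrze | hours: 52608
#>  span: 2011-01-01 00:00 .. 2016-12-31 23:00
#>  completeness: O3 93.3%, NO 86.8%, NO2 94.0%, SO2 94.3%, CO 94.3%, PM10 86.9%, ...

# complete cases for an ozone model (predictors: H, D, other pollutants, WS, T, I)
cases <- build_case_table(series, default_variable_spec("O3", "zabrze"))
nrow(cases)   # 25246 of 52608 hours survive complete-case filtering

# subsample for speed, then fit full-range, RVS and PVS models
cfg <- train_config(seed = 42, restarts = 2, max_epochs = 120)
set.seed(42)
cases5k <- case_table_subset(cases, sort(sample.int(nrow(cases), 5000)))
full <- fit_rvs(cases5k, 1, cfg)
rvs4 <- fit_rvs(cases5k, 4, cfg)

evaluate(rvs4, cases5k)
#> <error_report> RVS k = 4, target O3
#>  subrange   label   low   high    n    mae   rmse
#>         1 RVS-1/4  5.10  23.00 1250  2.352  2.946
#>         2 RVS-2/4 23.00  34.77 1250  2.399  2.956
#>         3 RVS-3/4 34.77  52.66 1250  3.896  4.747
#>         4 RVS-4/4 52.68 465.10 1250 12.194 17.671
#>  overall MAE 5.21 | overall RMSE 7.08

comparison_table(list(evaluate(full, cases5k), evaluate(rvs4, cases5k)))
#>   mode k overall_mae overall_rmse dmae_pct drmse_pct
#> 1  RVS 1    9.041819    13.004592      0.0       0.0
#> 2  RVS 4    5.210364     7.079985    -42.4     -45.6
```

Reading the output: each sub-range row shows its concentration bounds, case
count and errors — the error grows toward the top sub-range, which absorbs the
heavy right tail. Four oracle sub-models cut the overall MAE by 42.4% relative
to the single full-range model (dmae_pct), reproducing the qualitative finding
that segmentation pays, most of all for RVS.

A practical (PVS) model routes unseen cases itself:

```r
pvs4 <- fit_pvs(cases5k, 4, cfg)
route_case(pvs4, cases5k[1:3, ])   # stage-1 routing: sub-range per case
predict(pvs4, cases5k[1:3, ])      # routed sub-model predictions
```

The full experiment grid (modes × k, reports, comparison table, manifest) is
one call — or one shell command via the CLI:

```r
run_experiment(experiment_config(target = "PM10", preset = "zabrze",
                                 modes = c("rvs", "pvs"), k_values = c(1, 2, 4, 8),
                                 seed = 7, out_dir = "out"))
```

```sh
Rscript inst/cli/aqgapfill simulate --preset zabrze --years 2011-2016 --seed 1 --out sim.csv
Rscript inst/cli/aqgapfill run --target PM10 --input sim.csv --mode rvs,pvs --k 1,2,4,8 --seed 7 --out out/
```

## Package layout

* `R/monitoring-series.R`, `R/time-encode.R`, `R/case-table.R` — ingestion,
  validation, time encoding, complete-case tables, seeded splits
* `R/mlp.R` — the perceptron: scaling, BFGS training, restarts, prediction,
  JSON serialization
* `R/segmentation.R` — equal-count partitioning, RVS/PVS fitting, routing
* `R/evaluation.R` — MAE/RMSE, overall aggregation, percentage changes,
  report writers
* `R/synthetic.R` — the monitoring-like series generator
* `R/experiment.R`, `R/cli.R` — experiment orchestration, manifest, CLI
* `vignettes/subrange-modeling.Rmd` — the methods vignette (model,
  conventions, generator scope, numerical choices, limitations)
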
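# imvLAI

Interpretable deep-learning regression of leaf area index (LAI) on soil
moisture and air temperature, for land-surface and vegetation ecologists
who want not only per-grid LAI predictions but a per-sample estimate of
*which* driver the prediction relied on.

## What it does

The package implements a complete, tested pipeline:

1. **Simulate** gridded 8-day series of soil moisture (kg/m²), temperature
   (°C) and LAI (m²/m²) with realistic seasonal cycles, persistent
   anomalies, per-class phenology (including bimodal double-season crops)
   and a known ground-truth dominance parameter λ ∈ [0, 1] that splits
   LAI's dependence between soil-moisture and temperature history.
2. **Preprocess**: fixed-range min–max normalization (SM 0–1000 kg/m²,
   T −50–50 °C, LAI 0–10 m²/m²), validity filtering (whole-series mean
   LAI < 0.1 excluded), sliding 7-composite windows (56 days) targeting
   the final step's LAI, chronological 70/10/20 splits.
3. **Train** one of three model families with Adam (lr 0.001, batch 256,
   300 epochs at full scale), keeping the parameters at the minimum
   validation loss; optionally pretrain on pooled grids and fine-tune per
   grid:
   - `ann` — feed-forward tanh network on the flattened window,
   - `lstm` — single-layer LSTM, last hidden state to an affine head,
   - `imv` — IMV-LSTM: per-variable hidden blocks (tensorized cell) with
     temporal attention per variable and a variable-attention mixture
     `ŷ = Σ_n Pr(z = n) · μ_n`.
4. **Evaluate** R² = 1 − SS_res/SS_tot, RMSE and MAE on the denormalized
   test split, per grid and summarized by vegetation class.
5. **Interpret**: `Pr(z = soil moisture)` is the soil-moisture importance
   of a sample (temperature importance is its complement); grids with mean
   importance > 0.5 are moisture-dominant; aggregations by season,
   LAI phase and driver value reproduce the analysis products.

Core classes are Bioconductor-style S4: `LaiGrids` (extends
`SummarizedExperiment`; grids × composites with three assays),
`LaiSamples`, `LaiModel`, `LaiFit`. All model forward passes, backprop and
the Adam optimizer are implemented in the package and verified in the test
suite against scalar-loop oracles and numerical gradients.

## Worked example

```r
library(imvLAI)

res <- runLaiPipeline(
  spec    = gridSpec(4, 4),
  years   = 6,
  params  = couplingParams(dominance_lambda = 0.9),  # moisture-driven truth
  family  = "imv",
  profile = laiProfile("test"),   # hidden 16, 100 epochs: minutes on 1 CPU
  finetune = FALSE,
  seed    = 1
)

median(res$metrics$r2, na.rm = TRUE)
#> [1] 0.2439372
mean(res$importance$sm_importance)
#> [1] 0.5670953
res$dominance$fractions
#>    moisture temperature 
#>  0.92307692  0.07692308
```

λ = 0.9 is the hardest condition for prediction — LAI follows persistent
soil-moisture *anomalies* rather than the smooth seasonal cycle — hence
the modest test R²; what matters for interpretation is that the extracted
mean soil-moisture importance lands above 0.5 and 12 of the 13 vegetated
grids are labelled moisture-dominant, matching the generating dominance.
With `dominance_lambda = 0.1` the same call yields mean importance ≈ 0.29
and every grid temperature-dominant. `importanceVsLai(res$importance)` and
`importanceVsDriver(res$importance, "temperature")` produce the binned
phase/driver curves, including the temperature value at which the two
importances cross.

See `vignettes/hydrothermal-lai-modelling.Rmd` for the model equations,
generator assumptions, and design decisions, and
`inst/scripts/lai_pipeline.R` for a shell entry point
(`simulate` / `preprocess` / `train` / `interpret` subcommands).

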
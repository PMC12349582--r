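Package: imvLAI
Title: Interpretable Deep Learning of Leaf Area Index from Soil Moisture
    and Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates gridded 8-day soil moisture, air temperature and
    leaf area index (LAI) series with a known ground-truth driver
    dominance; preprocesses them into sliding-window samples with fixed
    physical-range min-max normalization and chronological splits; trains
    feed-forward, LSTM and interpretable multi-variable LSTM (IMV-LSTM)
    regressors with Adam and minimum-validation-loss model selection,
    optionally pretraining on pooled grids before per-grid fine-tuning;
    evaluates R2, RMSE and MAE per grid and vegetation class; and
    extracts attention-based soil-moisture versus temperature importance
    with dominance maps, seasonal aggregates, LAI-phase curves and
    driver-binned curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
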
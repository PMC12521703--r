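Package: retentime
Title: Generative Retentive Transformer Pre-Training for Healthcare Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoder-only generative pre-training for healthcare time series,
    built on multi-head Retention with an extrapolatable rotary-plus-decay
    (xPos) position embedding. Supports continuously monitored multivariate
    biosignals (via a convolution-subsampling tokenizer and temporal
    convolution blocks) and irregularly-sampled clinical event sequences (via
    a continuous-time decay extension that conditions the recurrent state on
    real time gaps). Provides parallel, recurrent and chunk-wise retention
    forms, next-token pre-training and fine-tuning loops, trajectory-based and
    time-specific forecasting, evaluation metrics (MAE, top-K recall, AUPRC),
    and synthetic-data generators for trend-plus-periodic signals and
    timestamped code sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
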
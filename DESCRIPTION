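Package: esnccm
Title: Lagged Causal Discovery for Daily Time-Series Panels with Echo
    State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects directed causal relationships between pairs of daily
    time series (for example lexicon sentiment scores and social-media
    activity counts) by integrating convergent cross mapping with leaky
    echo state networks. A fixed random reservoir is driven by one series
    and a ridge-regression readout is trained to predict the other series
    at a range of leads and lags; the lag at which the cross-map skill
    (Pearson correlation between predictions and observations) peaks
    discriminates causal direction and coupling delay. Includes
    leave-one-unit-out cross-validated grid search of the reservoir
    hyperparameters, tweet-panel preparation (text cleaning, bag-of-words
    sentiment and emotion scoring, daily aggregation, period-stratified
    descriptives), and synthetic generators (coupled chaotic logistic maps
    and a five-feature tweet-activity panel) with known causal ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
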
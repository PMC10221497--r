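Package: eventpulse
Title: Event-Interrupted Engagement, Sentiment, and Trust-Connotation Analysis of Social-Media Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure how an abrupt public event changed engagement,
    sentiment, and expressed trust in a stream of short social-media posts.
    Provides a seeded synthetic tweet-corpus generator with planted ground
    truth; ingestion, deduplication, tokenization and period labeling; topic
    filtering by latent Dirichlet allocation fit with collapsed Gibbs
    sampling; pluggable per-post sentiment classification with ordinal
    encoding and daily aggregation; a Bayesian local-level structural
    time-series counterfactual with pointwise, cumulative, and relative
    effects and a posterior tail-area probability; skip-gram negative-sampling
    word embeddings with antonym-pair semantic-axis (trust dimension)
    projection; sentiment-stratified TF-IDF term volumes with exemplar-post
    selection; and an end-to-end seeded pipeline with a consolidated report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
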
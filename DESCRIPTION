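Package: narratopics
Title: Topic-Model Comparison for Two-Class Clinical Narrative Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two topic-modeling tracks for characterizing labeled
    narrative-medicine corpora (e.g. Long COVID patient testimonies versus
    writings by healthcare professionals): collapsed-Gibbs latent Dirichlet
    allocation with coherence/perplexity model selection, and an
    embedding/reduction/density-clustering pipeline with class-based TF-IDF
    topic keywords (including a full HDBSCAN implementation with a noise
    topic). Provides CSV corpus I/O, Italian-oriented text preprocessing
    with pluggable lemmatization, a generative two-class synthetic corpus
    simulator with full ground truth for parameter-recovery experiments,
    and a semi-supervised topic-to-class evaluation (majority mapping,
    accuracy, grouped fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
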
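Package: dtflex
Title: Embedding-Based Flexibility Scoring for Verbal Divergent-Thinking Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated scoring of verbal divergent-thinking (DT) tasks from
    word embeddings. Flexibility is measured as the semantic distance
    (1 - cosine similarity) between consecutive responses to the same prompt,
    originality as the distance between the prompt and each response, and
    fluency as the response count; each score is aggregated per item as sum,
    mean (divided by fluency to correct the fluency confound), and maximum.
    Free-text responses are tokenized, stoplisted, and represented as
    weighted averages of their word vectors in a GloVe-format embedding
    space. A psychometric toolkit supports validation: Spearman and Pearson
    correlations with Fisher r-to-z confidence intervals, comparison of two
    correlations via Fisher's z, Cronbach's alpha, McDonald's omega,
    coefficient H, and maximum-likelihood confirmatory factor analysis with
    RMSEA, CFI, TLI, and SRMR fit indices. Seeded generators provide
    planted-cluster embedding spaces, simulated response sequences with a
    known category-switching probability, and factor-model indicator data,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
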
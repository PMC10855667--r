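Package: embedhdp
Title: Topic-Model Based Evaluation of Sentence Suggestions in Care Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the informational similarity between a generated sentence
    suggestion and its ground-truth care-record sentence. Token embeddings are
    quantized into pseudo-bag-of-words documents, a hierarchical Dirichlet
    process topic model is fitted on the resulting two-document corpus, and the
    similarity is the cosine of the two inferred topic distributions (the
    EmbedHDP metric). Ships comparator metrics (sentence-level BLEU, ROUGE-N,
    ROUGE-L, bag-of-words cosine), a sentence-length filter, a
    human-correlation benchmark harness, and a synthetic sentence-pair
    generator with simulated multi-rater scores for fully offline testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
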
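Package: pathocode
Title: Clinical Entity Recognition and Multi-Terminology Code Mapping for
    Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hybrid pipeline for extracting clinical entities (sample type,
    test performed, finding) from anatomopathological report text and
    normalizing each mention to SNOMED CT-, LOINC- and ICD-11-style codes.
    Combines a supervised softmax classification head with dense
    (character-n-gram hashing embeddings, cosine similarity) and sparse
    (Okapi BM25) terminology retrieval through a learned fusion rule with a
    confidence-based retrieval fallback. Includes BIO tagging and subword
    label alignment utilities, a seeded synthetic corpus and terminology
    generator with a long-tailed (Zipf) code distribution, and a statistical
    evaluation harness (precision/recall/F1, error rates, bootstrap
    confidence intervals, one-sample t-tests, Cohen's kappa, Matthews
    correlation, exact McNemar and permutation tests for paired model
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
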
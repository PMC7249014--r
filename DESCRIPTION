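Package: litriage
Title: Literature Question-Answer Mining and Physicochemical Triage for
    Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A question-answer text-mining pipeline for drug repurposing
    from a literature corpus, followed by cheminformatic triage of the
    extracted compounds.  Documents are tokenized into unique sentences,
    embedded with a deterministic hashed bag-of-ngrams encoder (with an
    adapter contract for pretrained sentence encoders), and ranked
    against a natural-language question by inner-product or directed
    Hausdorff similarity.  Retrieved answers are filtered by a siamese
    differential convolution network whose feature-space mean squared
    error yields a relevance score.  Candidate compounds are then triaged
    with Lipinski rule-of-five descriptors, Wildman-Crippen clogP, Ertl
    topological polar surface area, and a fingerprint-based linear
    support-vector machine for blood-brain barrier permeability.
    Includes seeded synthetic-data generators so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    e1071,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
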
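Package: abstate
Title: Ontology-Guided Consistency Analysis of Acid-Base State Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge-base driven construction of data-mining workflows for
    the system analysis of patients' acid-base state (ABS) during operative
    measures, together with the analysis methods the knowledge base selects.
    Provides a lightweight ontology engine (typed entity/axiom graphs with
    merging, restriction-path sub-ontology extraction, subsumption closure and
    conjunctive description-logic queries), a packaged data-mining core and
    medical domain knowledge base with a competency-question suite, CRISP-DM
    style workflow construction from a task requirement and a data profile,
    a synthetic ABS-like cohort generator with planted correlation blocks and
    missing-not-at-random gaps, k-nearest-neighbour imputation, the criteria
    function (a Mahalanobis-type quadratic form with branch-and-bound optimal
    feature-subset search), the Kupershtokh-Mirkin-Trofimov partition
    functional with threshold scans and critical-period detection, and exact
    Mann-Whitney group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
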
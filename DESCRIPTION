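Package: regphen
Title: Rule-Based Validation and Prediction of Regulatory Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating gene-product function annotations to
    loss-of-function phenotype annotations through the logical structure of
    bio-ontologies. Parses OBO ontologies with intersection_of logical
    definitions, decomposes phenotype classes into Entity-Quality pairs,
    indexes positively_regulates/negatively_regulates axioms, and derives
    correspondence rules linking regulation functions to regulatory
    phenotypes. The rules drive an annotation-consistency checker (exact
    and subclass-inferred matching), a rule-based phenotype predictor, and
    an evaluation stack with Resnik/Best-Match-Average semantic similarity,
    CAFA-style Fmax, and ROC-AUC interaction recovery. A synthetic-fixture
    generator emulates GO-like and MP-like ontologies, GAF and phenotype
    annotation files, and STRING-like interaction networks with planted
    structure, so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
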
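Package: nidmlm
Title: Linear Regression on Linked-Data (NIDM-Lite) Study Documents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits user-specified linear models to phenotype data stored in
    linked-data study documents serialized as RDF 1.1 Turtle under a small,
    documented "NIDM-lite" profile. Variables can be addressed by element
    identifier, by study-local variable name, or by the concept URL that
    annotates semantically equivalent variables across sites, so multi-site
    data with heterogeneous variable naming can be pooled into one regression.
    Supports interaction terms, five categorical contrast codings (treatment,
    simple, sum, backward difference, Helmert), ordinary least squares with
    full inferential output and joint contrast F-tests, and L1 (lasso) or L2
    (ridge) regularization with the penalty weight selected by 10-fold
    cross-validated held-out likelihood. Includes a synthetic multi-site study
    generator with known ground truth, and command-line front ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
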
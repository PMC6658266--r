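Package: smareg
Title: Secure Multiparty Linear Regression on Horizontally Partitioned Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a single linear model across several data-holding sites
    without pooling raw records. Each site selects features locally with the
    lasso and fits ordinary least squares on the jointly agreed feature set;
    the sites' binary selection vectors are merged by a secure majority
    (median probability model) protocol and the local coefficient vectors by
    a secure averaging protocol, both built on Paillier additively
    homomorphic encryption with a signed fixed-point encoding of reals.
    Includes a centralized (pooled-data) baseline, a synthetic-data generator
    for horizontally partitioned regression problems, sample-size advisory
    checks from distributed statistical computing theory, and a repeated
    train/test evaluation harness reporting mean squared error, R-squared
    and the centralized-to-distributed MSE ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    openssl,
    glmnet,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
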
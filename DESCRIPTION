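Package: ipclust
Title: Iterative Pruning PCA for Fine-Scale Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised detection of fine-scale population structure from
    SNP genotype panels by iterative pruning principal component analysis.
    Samples are recursively partitioned in principal-component space using a
    rotation-search gap splitter backed by a multivariate Gaussian mixture
    model with classification EM, with stopping rules based on minimum group
    size, Hudson's FST between candidate subgroups, and the log-gap spectrum
    of eigenvalues; small terminal clusters are reported as outlying
    individuals. Includes PLINK binary and delimited-text genotype input,
    median imputation, optional covariate regression, Hudson FST estimation
    (average and per SNP), top-discriminator SNP ranking, three-view PC
    plots, and a Balding-Nichols benchmark simulator with planted
    principal-component-space outliers.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
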
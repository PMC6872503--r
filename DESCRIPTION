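Package: neurocausal
Title: Deep Feature Selection and Causal Discovery for 3D Neuroimaging Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for interpretable deep-learning analysis of
    registered 3D brain volumes and genotype data: a VGG-style 3D convolutional
    network with global average pooling for case/control classification,
    occlusion-based (prediction difference) relevance mapping with
    multivariate-normal patch replacement, top-decile region-of-interest
    extraction, functional principal component summarisation of image regions
    and genes, and bivariate causal discovery with conditional generative
    adversarial networks and K-nearest-neighbour classifier two-sample tests.
    Includes a synthetic-data module (planted-signal volumes, Hardy-Weinberg
    genotypes, additive-noise cause-effect pairs) so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    class,
    splines,
    stats,
    utils,
    rlang,
    yaml,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
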
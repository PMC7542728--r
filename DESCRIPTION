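Package: cardiosynth
Title: Synthetic Cardiac MRI Generation, Similarity Auditing and Chamber Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic grayscale cardiac magnetic resonance frames with a
    progressively grown Wasserstein generative adversarial network, audits their
    statistical similarity to reference images with a multi-scale sliced Wasserstein
    distance over Laplacian-pyramid patch descriptors, and trains U-Net chamber
    segmentation networks on either synthetic or directly rendered images. Includes a
    seeded cardiac phantom generator (short-axis and four-chamber long-axis views with
    ground-truth left-ventricle, right-ventricle and right-atrium masks), segmentation
    quality metrics (Dice coefficient, percent area variation), paired Wilcoxon
    signed-rank comparison with median [IQR] reporting, and an end-to-end pipeline that
    contrasts synthetic-trained against directly trained segmentation models on a common
    held-out set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tibble,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
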
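Package: clustsim
Title: Monte Carlo Design Analysis for Unsupervised Clustering of Individuals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation machinery for a priori design analysis of unsupervised
    clustering on continuous indicators, as used in cognitive and psychological
    research. Generates multivariate-Gaussian cohorts with compound-symmetric
    correlation and one or two latent groups, clusters them with Gaussian
    mixture models (EM over six covariance parameterizations, BIC selection of
    1-5 components), partitioning around medoids, and complete-linkage
    hierarchical clustering (average-silhouette selection with the Duda-Hart
    one-cluster test), and scores power and false-positive risk via the
    proportion of correctly selected cluster numbers and the Rand index over a
    factorial scenario grid. Also provides the effect-size conversion, power,
    and median-split utilities that frame the design argument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
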
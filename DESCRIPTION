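Package: cervimorph
Title: Radiographic Phenotyping of Cervical Sagittal Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated extraction of four cervical sagittal alignment
    parameters (C3 sagittal vertical axis, C3-C7 lordosis, vertical length,
    and curved length) from polygon annotations of the C3-C7 vertebral
    bodies on lateral radiographs, followed by unsupervised k-means
    phenotyping with elbow, silhouette, Calinski-Harabasz and
    Davies-Bouldin model selection, and cluster-comparison statistics
    (one-way ANOVA, including reconstruction from published summary
    statistics, and Bonferroni-corrected pairwise post hoc tests).
    Includes a synthetic-data module that simulates phenotype cohorts and
    geometrically exact spine annotations with analytic ground truth, so
    the full pipeline is testable without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
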
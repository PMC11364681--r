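Package: perivene
Title: Volumetry of the Perivenous Diploic Space and Parasagittal Dura on 3D MRI
Version: 0.1.0
Authors@R:
    person("perivene", "developers", email = "perivene@example.org", role = c("aut", "cre"))
Description: Threshold-based volumetric measurement of the contrast-enhanced
    space surrounding the diploic veins and of the parasagittal dura on 3D
    contrast-enhanced T1-weighted head MRI, with intracranial-volume
    normalization and the accompanying nonparametric cohort statistics
    (Kolmogorov-Smirnov gated correlation and group tests, ICC(2,1)
    inter-rater reliability on Ln(x+1) volumes). Includes a synthetic cranial
    phantom and cohort generator with known ground truth so that every stage
    of the pipeline is testable without patient data, a minimal NIfTI-1
    reader/writer, and anisotropy-aware morphological primitives (Euclidean
    distance transforms, connected components, inscribed-disc diameter
    filtering) implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
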
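Package: subcortnet
Title: Mapping Shared Subcortical Components of Cortical Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A volumetric pipeline for locating the subcortical nodes shared by
    two cortical resting-state functional networks and characterising their
    structural and neurochemical embedding. Provides seed-median functional
    connectivity mapping, groupwise diffeomorphic functional alignment of
    correlation maps (stationary-velocity demons with local normalized
    cross-correlation), sign-flip permutation inference with threshold-free
    cluster enhancement, subcortical ROI extraction, streamline connectomics
    with degree and betweenness hub metrics, hemispheric lateralization tests,
    and spatial correlation of projection maps with annotation maps under
    variogram-matched surrogate nulls. Includes a synthetic-cohort generator
    with planted ground truth so the full pipeline is testable without real
    neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
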
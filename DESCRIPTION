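Package: scniche
Title: Reaction-Diffusion Models of Self-Confined Gene Expression in the
    Root Stem-Cell Niche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the spatial self-confinement of the BRAVO transcription
    factor in the Arabidopsis root stem-cell niche through attenuation of a
    diffusible WOX5-dependent activator. Implements four one-dimensional
    reaction-diffusion model variants (immobilization by sequestration, with
    and without a mobile intermediary, repression of the mobile activator,
    and a mixed model) solved both as stationary boundary-value problems and
    by explicit forward-Euler time integration; wild-type/mutant genotype
    transforms; compatibility observables and log-grid parameter-plane
    scans; a synthetic segmented root-layout generator with an Otsu/
    skeletonization segmentation routine; and a two-dimensional pixel-grid
    simulator with heterogeneous diffusion across cell walls and GFP
    reporter dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
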
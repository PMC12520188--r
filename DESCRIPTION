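Package: discfacet
Title: Quantitative Phenotyping of Intervertebral Disc and Facet Joint Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-motion-segment degeneration studies of
    the spine. Estimates nucleus pulposus T2 relaxation time from multi-echo
    magnitude decays with Rician noise-floor correction, T1 from two-point
    variable-flip-angle signals and the pre/post-contrast percent-T1-reduction
    trans-endplate diffusion metric; computes radiographic disc height index;
    extracts toe and linear compressive moduli, transition strain and creep
    strain from motion-segment load-displacement records via a continuous
    bilinear fit; inverts spherical-indenter Hertzian biphasic creep tests for
    facet cartilage compressive modulus, tensile modulus and hydraulic
    permeability; and stratifies cohorts by disc health with disc-facet Pearson
    correlation analysis. A synthetic-cohort generator with a latent
    degeneration severity reproduces the statistical structure the analysis
    assumes, so every stage is testable by parameter and sign recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
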
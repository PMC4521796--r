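Package: retinomap
Title: Retinal Tumor Mapping and Spatial Statistics for Retinoblastoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to represent retinoblastoma tumors in retinal polar
    coordinates (eccentricity, polar angle) on a 60-degree spherical-cap
    window, compute spherical tumor areas and centroids, build cumulative
    tumor-burden maps in the azimuthal equidistant projection, fit marked
    inhomogeneous Poisson point-process models of tumor-centroid density by
    age, size and mutation marks (Berman-Turner quadrature), run Ripley's K
    and CSR envelope diagnostics, nearest-neighbour and within-eye
    permutation analyses, and the cohort-level exact and rank tests.
    Includes a seeded synthetic-cohort generator emulating the statistical
    structure of a retinoblastoma MRI-mapping cohort so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    mgcv
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
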
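---
title: "Mapping and modeling retinoblastoma on the retinal sphere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and modeling retinoblastoma on the retinal sphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinomap)
```

## The coordinate system and its assumptions

A tumor on the retina is located by two angles: *eccentricity* ε, the
angular distance from the fovea, and *polar angle* θ, measured clockwise
from the superior vertical meridian (so θ = 90° points nasally in a right
eye; the optic disc sits near θ = 88°). The mapped retina is modeled as a
spherical cap of 60° radius about the fovea on the unit sphere, with ε
treated as arc angle at the sphere's center. Strictly, clinically measured
eccentricity is a visual angle at the lens, and the two differ in the far
periphery; the mapped coordinates are taken at face value, which is the
convention of the mapping workflow this package reimplements and is
internally consistent for all the statistics computed here.

For display and for point-process fitting, points are rendered in the
*azimuthal equidistant projection* `x = ε sin θ, y = ε cos θ`, which
preserves distance and direction from the fovea exactly (its defining
property, asserted in the test suite). Distances between two off-center
points are *over*estimated by the projection: the great-circle distance
`arccos(u·v)` never exceeds the projected Euclidean distance, with
equality only through the center. The package therefore exposes both
metrics (`nn_distances`), fits intensity models in the projection (where
polynomial trend surfaces are natural and the error is conservative for
clustering inference), and uses great-circle distances for all
within-eye separation analyses.

Left eyes are pooled with right eyes by reflecting across the vertical
meridian, `θ → 360° − θ`, preserving superior/inferior and aligning nasal
retina with nasal retina. The mirroring axis is stated ambiguously in the
source workflow ("inverted around the nasal-temporal axis"); the intent —
nasal-to-nasal alignment — is unambiguous, and the reflection across the
vertical meridian is the transformation that achieves it while keeping
superior up. This is the package's reading; the reflection is an
involution and area/centroid metrics are invariant under it (tested).

## Spherical areas and centroids

Tumor area and centroid are computed on the sphere, not in the flat
projection, to avoid projection distortion. For a closed boundary with
vertices joined by great-circle arcs (densified to ≤ 0.5° steps), the
enclosed solid angle follows from Stokes' theorem in the retinal-pole
parameterization,

&nbsp;&nbsp;&nbsp;&nbsp;A = ∮ (1 − cos ε) dθ,

which is exact for the densified polygon and reduces to the familiar
2π(1 − cos ρ) for a cap of radius ρ. Area is reported as a fraction of the
60° window. The area centroid uses the exact boundary identity
∫∫ u dA = ½ ∮ u × du: the integral of position over the enclosed region
equals a cross-product line integral around its (counterclockwise)
boundary, which is then normalized back to the sphere. Because polar angle
increases clockwise, a boundary that is positively oriented for the
θ-integral is negatively oriented for the cross-product integral; the
implementation orients the boundary by the sign of the computed area
before applying the centroid formula. Both integrals are validated against
closed forms for caps and against rejection-sampling Monte-Carlo oracles
(10⁶ uniform points) for irregular shapes.

Two centroid definitions coexist in the source description ("center of
mass of the mapped area" vs "of the tumor contour"). The area centroid is
primary here; a perimeter-only centroid (arc-length-weighted mean of
boundary points) is available via `spherical_centroid(mode = "perimeter")`.
For near-convex tumor outlines the two differ by well under a degree.

## Perimeter interpolation and rasterization

Measured perimeters are sparse ordered vertex lists. They are interpolated
with a closed periodic cubic spline in projected coordinates, parameterized
by cumulative chord length — the smoothing method of the original
hand-drawn maps is unstated, so the periodic spline is this package's
choice, and the interpolation deliberately runs in the projection (as the
hand-drawn maps did) while areas and centroids run on the sphere. Contours
that exit the window are clipped radially to its rim; self-intersecting
interpolants trigger a warning and an even-odd fill at rasterization.

Rasterization labels pixels whose centers fall on or inside the contour,
on a square grid of default pitch 0.25° (matching the effective fidelity
of the digitized maps, about 6500 pixels in the window at their scan
density). The spherical area of a pixel at projected radius r is
pitch² · sin(r)/r, so rasterized areas converge to the exact spherical
area as the pitch shrinks (observed ~O(pitch), tested). Cumulative burden
counts *distinct eyes* per pixel — multiple tumors in one eye count once —
and the per-age-quartile maps report the fraction of that quartile's
tumors overlapping each pixel.

## The point-process model

Tumor centroids form a marked point pattern in the 60° disc, with marks
for mutation type, tumor-area quartile and age-at-diagnosis quartile. The
intensity model is an inhomogeneous Poisson process with log-polynomial
intensity log λ(x, y) = Σ β·x^i y^j (total degree d, (d+1)(d+2)/2
coefficients). Fitting maximizes Σᵢ log λ(xᵢ) − ∫_W λ via the
Berman–Turner device: a 32 × 32 dummy-point grid clipped to the disc is
combined with the data points, each quadrature point carries a
counting-measure weight (cell area divided by points in the cell, cell
areas corrected for the disc boundary by subgrid integration and
normalized so the weights sum exactly to π·60²), and the problem becomes a
weighted log-linear Poisson regression. The degree-0 fit then reproduces
the homogeneous MLE n/|W| *exactly*, an identity the tests assert, and
simulated log-linear intensities are recovered within Monte-Carlo error
(200-replicate calibration in the acceptance suite).

Defaults: degree 2 (the source analysis does not state its degree; degree
is a parameter and AIC is reported for comparison), 32 × 32 quadrature,
and per-mark-level fits — by the marking theorem, a marked Poisson process
factors into independent intensities per mark level, which is equivalent
to a joint formula and far simpler to test.

Diagnostics follow standard practice: Ripley's K,
K̂(r) = |W|/(n(n−1)) Σ_{i≠j} e_ij 1[d_ij ≤ r], with translation edge
correction e_ij = |W| / |W ∩ W_shift| (closed form for a disc window),
compared against the CSR reference πr² with pointwise rank envelopes from
seeded CSR simulations (default 99). Kernel relative-density maps divide a
window-renormalized Gaussian kernel intensity estimate by the CSR-uniform
density n/|W|; under CSR the map is ≈ 1 everywhere (tested at n = 2000
within [0.9, 1.1]).

## The within-eye permutation test

Germline patients often carry several tumors in one eye. The test asks
whether such within-eye multiplets are *further apart* than chance: the
observed statistic is the mean within-eye nearest-neighbour great-circle
distance over eyes with ≥ 2 tumors; each of B null draws samples centroids
from the full cohort pool into groups matching the observed multiplet-size
multiset and recomputes the statistic; the one-sided p-value is
(1 + #{null ≥ observed}) / (1 + B). Sampling is without replacement within
a draw (the source leaves this unstated; a `replace` flag provides the
alternative). The test holds its nominal level on null-conforming data
(type-I error 0.05 ± 0.02 over 500 runs in the acceptance suite) and has
≥ 80% power against multiplets separated by ≥ 40°.

## The synthetic cohort: what it does and does not emulate

No patient data ship with this package; the generator draws cohorts whose
*structure* matches the cohort the analysis was designed for, so a green
test establishes that the machinery behaves correctly on data of that
structure — not that any biological claim holds.

Encoded structure (defaults, all configurable):

* 67 patients, 39 bilateral (all bilateral patients germline, as in the
  modeled cohort), 43 germline in total; 24 of 39 bilateral patients
  contribute a mapped fellow eye (≈ 91 eyes); germline eyes carry
  Poisson(38/67) extra tumors (≈ 129 tumors).
* Ages per mutation type are lognormal with medians 7.9 (germline) and
  21.6 (somatic) months, clipped to the observed ranges; spreads
  (sdlog 0.9 / 0.7) are chosen as realistic for age-at-diagnosis
  distributions. The printed group medians describe a *full* cohort while
  the printed mapped-cohort quartile boundaries (5.6 / 8.8 / 13.2 months)
  reflect an age-biased exclusion process that the generator does not
  model, so emergent quartile cuts land near but not at those values — a
  deliberate limitation, since modeling the exclusion process would
  invent unreported selection parameters.
* Per-age-quartile centroid densities are Gaussian-kernel mixtures whose
  centers encode the reported verbal cluster descriptions (Q1 macula +
  superonasal periphery; Q2 inferotemporal posterior pole; Q3 inferonasal
  quadrant; Q4 nasal + superotemporal periphery, more diffuse). The
  effect sizes are plausible stand-ins — no fitted values exist to copy —
  and are config, not constants.
* Tumor area decreases with age quartile and eccentricity (lognormal,
  medians 5.5%→1.8% of the window across quartiles, × exp(−0.015 ε)),
  truncated to fit the window: every tumor satisfies the exact
  constraint ε_centroid ≤ 60° − ρ(area).
* Within-eye repulsion: new tumors in an eye are placed ≥ 40° (great
  circle) from earlier ones where feasible. The value emulates the
  reported significantly-greater within-eye separations (distances
  concentrated around 30–80°); at this default, ~75% of seeded cohorts
  reject the permutation null at α = 0.05.
* Small fundoscopy-only tumors: ~50 per cohort among bilateral patients,
  84% anterior to the equator, with an inferior fraction rising across
  age quartiles.

Not emulated: the age-biased exclusion of unmappable eyes, tumor growth
or shape biophysics, ICRB-group correlations beyond marginal frequencies,
and MRI measurement error. Perimeters are star-shaped smooth outlines
(low-order Fourier radial noise), which is adequate for exercising the
geometry but simpler than real lobed tumors.

One global seed drives everything; cohorts are byte-identical across runs
for the same seed, and per-tumor sub-draws come from the same stream in a
fixed order.

## Numerical choices

* Angles are degrees externally, radians internally; default relative
  tolerance 1e-9.
* Boundary densification: 0.5° arc steps for area/centroid integrals,
  0.25° for margin distances (the stated resolution of margin estimates)
  and for interpolation resampling.
* The approximate size–eccentricity constraint 60(1 − √a) and the exact
  cap-inversion form agree at a ∈ {0, 1} and differ by at most ~1.05°
  over [0, 1] (asserted < 2° in tests).
* Quartile cuts use linear-interpolation percentiles (R type 7,
  selectable); values equal to a cut go to the lower quartile.
* Fisher's exact test reports the conditional-MLE odds ratio and the
  point-probability two-sided p — the convention under which the modeled
  cohort's printed OR of 4.5 (sample cross-product 4.56) reproduces.
* CSR envelopes are rank envelopes with a fixed seed; K's translation
  correction uses the closed-form disc–disc intersection area.
* Degenerate inputs fail loudly: < 3 distinct perimeter vertices,
  antipodally balanced centroid integrals, zero-margin contingency
  tables, empty rasterizations and infeasible tumor placements all raise
  typed errors or flags rather than returning silently.

## Known limitations

* The K-function operates in the projection, not on the sphere; this
  overestimates inter-point distances and is conservative for detecting
  clustering (and the discrepancy is itself measured by the
  nearest-neighbour comparison).
* Mixed-effects ANOVAs and post-hoc contrasts of centroid coordinates are
  out of scope (routine third-party fits whose inputs are not
  reproducible from printed values); the exact and rank tests that back
  the printed statistics are implemented.
* The generator's spatial cluster parameters are qualitative stand-ins;
  analyses of *real* mapped cohorts should treat them only as a test
  harness.
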
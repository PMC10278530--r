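---
title: "Methods: zoned tumor-stroma ratio quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zoned tumor-stroma ratio quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrzone)
```

# The measurement model

`tsrzone` treats a stained tissue section as a calibrated raster: an
H × W × 3 intensity array in [0, 255] with a physical pixel size
(microns per pixel, *mpp*). All geometry is done in physical microns
with the origin at the centre of the top-left pixel, x rightward and y
downward; pixel membership in any region is decided by the pixel
*centre*. Stating this once removes a whole class of off-by-one
ambiguities: a 1-mm band at 10 µm/px is exactly 101 pixel rows
(distances 0 to 1000 µm inclusive), and that is asserted in the tests.

The pipeline has four stages.

**1. Segmentation.** Intensities are converted to optical density,
`OD = -log10((I + 1) / 256)`, and unmixed with the conventional
haematoxylin/DAB basis (unit-norm stain vectors, completed to an
invertible 3 × 3 matrix by their normalized cross product). Two paths
produce the binary tumor mask:

- *threshold*: tumor where the DAB concentration is at least
  `dab_threshold` (default 0.5 — the midpoint between the stroma's ~0
  and the tumor's ~1 DAB load in rendered phantoms, far from both under
  realistic noise). Fully deterministic.
- *trained*: a scribble-trained ensemble, mirroring the interactive
  trainable-segmentation workflow. Features are per-channel OD plus
  Gaussian-smoothed OD and gradient magnitude at physical scales
  {0.5, 1, 2, 4} µm (spanning nest-edge to nest-body texture; scales are
  converted to pixels through mpp, so the classifier is
  resolution-aware). The learner is a bagged ensemble of depth-limited
  CART trees (default 25 trees, depth ≤ 8, ≥ 5 samples per node,
  mtry = ⌈√p⌉), fit with a fixed seed; an odd ensemble size means
  majority votes cannot tie, and prediction involves no randomness, so
  masks are idempotent under re-prediction. `refine_classifier()`
  retrains on the de-duplicated union of old and new scribbles with the
  same seed, so a refinement with duplicate or empty additions is a
  provable no-op.

The ensemble is implemented in the package rather than delegated,
partly because no tree-ensemble dependency is assumed, and partly
because the training loop (scribble → fit → inspect → add labels) is
the method being modelled and needs to be scriptable and deterministic.

**2. Zonation.** Boundary annotations are polylines in physical
coordinates with a `tumor_side` direction vector. For every pixel the
Euclidean distance to the polyline is computed (exact point-to-segment
distance, minimized over segments); the side of the *nearest* segment,
oriented by `tumor_side`, decides whether the pixel counts as tumor
side. Encoding the side as a geometric direction rather than a
left/right flag makes the distance raster invariant to reversing the
vertex order, which the tests assert. A band is the closed interval
[0, `band_width_um`] of tumor-side distance (default 1000 µm),
intersected with the raster frame. Euclidean (not geodesic) distance is
used deliberately: the bands are drawn relative to marked boundary
lines, not routed through tissue. For tumors thinner than 2 mm the two
bands may overlap; the package permits this and leaves interpretation
to the caller (cohorts typically exclude such sections).

**3. Field selection.** Candidate fields are axis-aligned
1.15 × 0.68 mm boxes (0.78 mm², the 20×-objective-equivalent area) on a
stride grid (default 50 µm — dense enough to approximate free placement
at phantom scale, cheap enough to brute-force-verify), in both
orientations, with the box inside the frame and its centre pixel inside
the band. A candidate is valid if each border strip of depth
`border_margin_um` (default 20 µm, roughly 2–3 cell diameters; the
protocol states the constraint but no tolerance) contains at least one
tumor pixel. Among valid candidates the `k = 3` with the smallest tumor
area fraction are returned, ties broken by scan order (row-major within
the first orientation, then the second), overlap permitted. Fractions
and border checks are computed from a summed-area table, and the whole
procedure is checked against an independent brute-force loop
implementation on small grids. Note the automated criterion is an
*exhaustive* lowest-density search; the manual procedure it models was
"as low as possible" under time pressure, so the automated fields can
only be stroma-richer.

**4. TSR.** Per field, TSR = tumor fraction × 100. The region TSR is
the arithmetic mean of the three field TSRs (full-precision fractions
are averaged; outputs are *displayed* at 2 decimals but never compared
after rounding, to avoid threshold flapping). Dichotomization:
`tumor_high` iff mean TSR ≥ 50 — the threshold itself is high, directly
from the "≥ 50%" group definition. The inner/ITF pair maps to the slide
pattern; `low_high` is emitted for logical completeness even though
only three patterns are commonly observed.

# The synthetic world

**Phantoms.** `generate_phantom()` builds the truth mask first and
renders it second, so the ground truth is exact by construction. The
tissue is organised top-to-bottom: surface stroma, the epithelial
origin line (80 µm from the top), the 1-mm inner band, a transition
region, the 1-mm ITF band ending at the invasive edge line (80 µm from
the bottom), then stroma. Tumor nests are random ellipses with
lognormal radii (mean 40 µm, log-sd 0.3, random rotation) placed by
rejection until each band reaches its target fraction; each nest is
clipped to its band's row window so the two targets are controlled
independently (the transition region is filled to the mean of the two
targets). Defaults: 640 × 500 px at 4 µm/px — a ~28× downsample of
scanner resolution (0.14 µm/px), chosen so a 2.5-mm phantom stays a
~300k-pixel raster; the geometry is resolution-independent because
everything is parameterised in microns. Rendering assigns stroma a
haematoxylin OD of 0.55 and tumor a DAB OD of 1.0 plus residual
haematoxylin 0.25, converts to RGB, and adds Gaussian intensity noise
(default sd 4; tests go to 8).

What the phantom deliberately does **not** emulate: irregular invasive
fronts (the generated boundary lines are straight, so the analytic
truth bands are independent of the zonation code they validate —
general polylines are tested against a brute-force oracle instead),
nuclei-level texture, staining artefacts, folds, or out-of-focus
regions. A green end-to-end test therefore establishes that the
geometry, selection and arithmetic are correct — not that segmentation
would survive real-world stain variability.

**Cohorts.** `simulate_cohort()` draws covariates independently with
the study population's marginal prevalences and gives each patient one
latent first event with exponential hazard
`baseline_hazard · exp(Σ x · log HR)`. Defaults: n = 114,
`baseline_hazard` 0.015/month (median time-to-event ≈ 46 months at
baseline, commensurate with the cohort's 52-month mean follow-up),
hazard ratio 4.34 on the ITF tumor-low indicator (the univariate
overall-survival estimate used as generative truth), ITF tumor-low
prevalence 51/114, censoring 30%. Censoring is exponential with
per-patient rate `λᵢ · c/(1 − c)`, which makes the censoring
probability exactly `c` for every patient regardless of their hazard.
Events are labelled death/relapse/metastasis with probabilities
38:15:25 (the cohort's printed event counts); OS counts deaths, DFS any
event, RFS censors metastasis, MFS censors relapse, and all four share
the follow-up time min(T, C). This overlap convention is a choice, not
a reported fact — the source protocol never defines it — and it is the
main caveat when comparing simulated endpoint analyses beyond OS/DFS.
Covariates are drawn independently, so the simulator reproduces
marginal prevalences and specified hazard structure but not the
real-world correlation between, say, invasion pattern and perineural
invasion.

# Statistics layer

Association tests on r × 2 count tables use the Pearson chi-square,
with the Yates continuity correction for 2 × 2 tables where the
corrected deviation |O − E| − 0.5 is floored at zero — that floor makes
p = 1 exactly attainable, which matters because the published baseline
table prints p = 1 twice. This convention was identified by verifying
that *all eighteen* printed baseline p-values reproduce to the printed
precision under it; the statistic is implemented directly in the
package and cross-checked against `stats::chisq.test` in the tests.
Survival analysis delegates to the `survival` package (Cox partial
likelihood, product-limit curves, log-rank) and logistic models to
`stats::glm`, matching the toolchain such cohort analyses actually use;
effects are reported as HR/OR with Wald 95% intervals (the conventional
summary output), and fits showing divergence symptoms
(|log effect| > 15 or SE > 10³) raise a separation/non-convergence
error rather than returning garbage. The significance convention is
two-sided p < 0.05 with no multiplicity correction, mirroring the
analysis being reproduced.

# Numerical and interface choices

- Closed band intervals and centre-pixel membership (above); stride
  grids subset cleanly (a 100-µm grid is a subset of the 50-µm grid),
  so finer strides can only lower the achievable minimum fraction.
- Degenerate inputs fail loudly with the stage name attached:
  zero-variance paired differences, constant Spearman input, single-arm
  log-rank, empty bands, unsatisfiable border constraints, untrained
  classifiers, missing calibration.
- Rasters are exchanged as plain-text NetPBM (P3/P2) with a JSON
  sidecar for mpp, because no image-codec package is assumed;
  calibration precedence is explicit override > sidecar > error. Masks
  round-trip exactly; images lose only the rounding to integer
  intensities on write.
- All generators take an explicit seed and restore the caller's RNG
  state, so phantom and cohort generation are bit-reproducible without
  side effects on the session.

# Known limitations

Beyond the phantom simplifications above: the pixel classifier is a
two-class model (no artefact class); windows are axis-aligned (no
rotation); the cohort simulator has no competing-risks structure; and
the acceptance surface reproduces printed *counts-derived* statistics
exactly but can only check the survival layer by parameter recovery,
since no patient-level data are available.
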
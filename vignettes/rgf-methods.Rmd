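---
title: "Radial glandular fraction analysis of breast CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial glandular fraction analysis of breast CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgfbreast)
```

## The problem

The fibroglandular tissue (FT) of the breast — the dense glandular and
fibrous component, as opposed to adipose tissue — can be spatially
*condensed* near the centre of the breast ("non-sparse") or *scattered*
through it in small islands ("sparse"). The two patterns behave very
differently under tissue segmentation and biomechanical modelling for
adaptive breast radiotherapy, so an automatic way of classifying the
pattern from a planning CT is useful. Note that the pattern is distinct
from the fibroglandular *composition* (FC), the overall fraction of
breast tissue that is fibroglandular: two breasts with identical FC can
have opposite patterns.

`rgfbreast` implements a full measurement-and-classification pipeline
for this problem:

1. **Geometry** — reorient the supine axial CT breast into a canonical
   coronal frame: resample to cubic 1 mm voxels, then rotate every
   axial plane about the superior–inferior axis so the breast axis
   (centre of breast to nipple) points anteriorly.
2. **RGF** — for each coronal slice, measure the *radial glandular
   fraction* RGF(r): the fraction of FT pixels on the circle of
   relative radius r centred at the slice's centre of mass, for one
   hundred radii r = 0.01 … 1. The unit radius R is the
   *area-equivalent breast radius*, πR² = breast area of the slice.
   The breast is split into posterior, middle and anterior thirds along
   the chest-wall-to-nipple axis, and each region is summarized by the
   pointwise mean RGF over five slices centred on the region's middle
   slice.
3. **Features** — thirteen summary statistics of each region curve
   (`rgf_feature_names()`): mean, standard deviation, regression slope
   versus r, radial position of the maximum, minimum, maximum, range,
   means of the inner (r ≤ 0.5) and outer halves and their difference,
   means of the highest and lowest 10 % of values and their difference.
4. **Statistics** — per-feature two-sided Wilcoxon rank-sum tests
   between the sparse and non-sparse groups, plus the same test on FC.
5. **Classification** — leave-one-out cross-validated SVMs (cost C = 1)
   with linear, order-3 polynomial, RBF (σ = 1) and sigmoid kernels, on
   the 13 features of each region and on all 39 combined.

A synthetic phantom generator stands in for patient data, which cannot
be redistributed; it produces breast-shaped label volumes with
controllable FT patterns so that every stage is testable end to end.

## The phantom generator

The breast is modelled as the anterior half of an ellipsoid attached to
a flat chest-wall plane. Its axis can be tilted in the axial plane by a
*nipple offset* angle; the whole half-ellipsoid (including the cut
plane) is rotated rigidly, so a tilted phantom is exactly the rotation
of its untilted counterpart and the geometry pipeline can be validated
against it. The nipple is the distal end of the breast axis and is
stored as a landmark; the surface-based auto-detector
(`detect_nipple()`) finds the breast voxel farthest from the
least-squares chest-wall plane and recovers the landmark to within a
few voxels at any tilt.

FT patterns are defined as functions of the breast's own coordinate
frame, so they co-rotate rigidly with the shape:

* **nonsparse** — voxels are ranked by `exp(-d / decay_scale)` where
  `d` is the distance from the breast axis in mm
  (`decay_scale = 15` mm by default), plus a small smooth jitter; the
  top `ft_fraction` of breast voxels become FT. The radial profile
  decays from centre to periphery and its regression slope is negative
  by construction.
* **sparse** — spheres of radius `cluster_radius_mm` (default 5 mm) are
  dropped at uniformly random positions inside the breast until the FT
  fraction reaches the target, giving a near-flat radial profile.
* **uniform** — a band-limited isotropic random field (cosine waves
  with 6–12 mm wavelengths) thresholded at the target fraction. This is
  deliberately *not* voxel-wise Bernoulli noise: isolated FT voxels are
  eroded by linear interpolation followed by re-binarization, which
  would make FC depend on the rotation angle; mm-scale blobs survive
  the geometry pipeline and are also closer to real tissue texture.
* **annulus / full / empty** — structured patterns used in tests.

`generate_cohort()` reproduces the study conditions: 15 non-sparse and
8 sparse subjects by default, with per-subject jitter of the half-axes
(± 10 %), nipple offset (± 20°), FT fraction (± 0.05, identically
distributed in both groups so FC does *not* separate the classes —
matching the observation that pattern and composition are distinct),
and the mode-specific pattern parameter (± 20 %). All randomness
derives from one master seed: subject seeds are drawn up front, so
each subject is reproducible.

What the phantoms do **not** emulate: CT physics (noise texture, beam
hardening, partial volume at tissue interfaces), skin and pectoral
muscle, non-ellipsoidal breast shapes, posture-dependent deformation,
and segmentation error in the input masks. Passing tests therefore
demonstrate the correctness and internal consistency of the
measurement pipeline, not clinical performance on patient CT.

## Numerical choices

* **Radial grid.** r = k/100 for k = 1…100. One hundred radii are
  measured per curve; r = 0 is excluded (its "circle" is a single
  pixel) and r = 1 included.
* **Circle rasterization.** The circle of radius rR is the one-pixel
  annulus of centre distances in [rR − 0.5, rR + 0.5). Unit-width
  closed-open annuli partition the plane, so every pixel has exactly
  one bin per radius and the implementation can be (and is) tested for
  *exact* agreement with a brute-force per-pixel oracle.
* **Denominator.** Only pixels inside the breast mask are counted, in
  both numerator and denominator: the breast is not circular, so outer
  circles exit it, and a fraction over air would not measure glandular
  fraction. A radius whose annulus misses the breast entirely is
  undefined (`NA`), never extrapolated; five-slice averaging skips
  undefined values and the feature extractor excludes them (rejecting
  curves with more than ten).
* **Resampling and rotation.** Separable linear interpolation onto the
  1 mm grid using the cell-centred convention (sample points at
  (i − 0.5) × spacing). With node-centred sampling, 1 mm targets fall
  exactly midway between 2 mm source samples, interpolated mask values
  tie at exactly 0.5, and the ≥ 0.5 binarization systematically
  dilates masks — a bias that inflates the FC of high-surface-area
  (sparse) patterns. Masks are interpolated as real fields,
  re-binarized at 0.5, and the FT mask is intersected with the breast
  mask so the subset invariant survives thresholding. Rotation is one
  global in-plane rotation about the in-plane centroid of the whole
  breast mask, applied to every axial plane; out-of-grid samples read
  as background.
* **Nipple angle.** Measured from the in-plane breast centroid to the
  nipple landmark. Measuring from the same point that serves as the
  rotation centre makes the procedure self-consistent: after rotation
  the nipple lies on the anterior axis through the centroid by
  construction. The angle is reported in (−90°, 90°], its sign
  encoding the rotation direction.
* **Feature conventions.** The slope is ordinary least squares of RGF
  on r. The radial position of the maximum takes the smallest radius
  attaining it (a deterministic tie-break; a constant curve reports
  r = 0.01). The inner 50 % is inclusive at r = 0.5. The highest and
  lowest 10 % are the ten largest and smallest order statistics of the
  100 values (proportionally fewer when some radii are undefined), not
  interpolated quantiles. The three difference features are computed
  from their parents, so their identities hold exactly.
* **Wilcoxon test.** Exact permutation distribution whenever the
  pooled sample size is ≤ 25 with no ties (always the case for the
  23-subject design on continuous features), normal approximation with
  tie and continuity corrections otherwise. Two-sided throughout. No
  multiple-testing correction is applied, matching per-feature
  reporting at α = 0.05; users should bear the 13-test family per
  region in mind.
* **SVM.** `e1071::svm` (libsvm) with C = 1 and no class weighting.
  Features are standardized to zero mean and unit variance using the
  training fold's statistics only — slopes and means live on very
  different scales and the RBF and sigmoid kernels are scale
  sensitive; computing the transform per training fold avoids leaking
  the held-out subject. "RBF with σ = 1" is mapped to
  k(x,y) = exp(−‖x−y‖²/(2σ²)); the plain exp(−‖x−y‖²/σ²) form is
  available via `kernel_spec(rbf_form = "plain")`. The polynomial and
  sigmoid secondary parameters are not pinned down by the study
  configuration; the defaults follow libsvm conventions
  (γ = 1/dimension; coef0 = 1 for the polynomial, 0 for the sigmoid)
  and are configurable.

## Problem sizes

The shipped tests run the pipeline on reduced phantoms (half-axes
18 × 28 × 20 mm on 1 mm and 2 mm grids, plus full-size 40–60 mm
phantoms where rotation fidelity is measured), with the study's group
sizes of 15 + 8 subjects; the rank-sum calibration uses 500 simulated
null cohorts. `scripts/acceptance.R` runs the full-size default study.
These sizes were chosen so the whole suite completes in about a minute
while every annulus still spans multiple pixels.

## Known limitations

* Extreme-value features (minimum, maximum, range, highest/lowest 10 %
  means) inherit the discretization of small annuli: the innermost
  radii hold only a few pixels, so a 5-slice-averaged bin moves in
  steps of about 1/15 when a single pixel flips between two
  voxelizations of the same object. Their stability under rotation is
  therefore marginal (changes of up to ~0.1 are possible for unlucky
  field realizations), whereas averaging-type features (mean, slope,
  half means) are stable to well under 0.05. Users comparing cohorts
  should prefer the averaging features when robustness matters.
* The sparse/non-sparse ground truth is an input label (in the
  original study, expert visual assessment); the package encodes the
  qualitative contrast in its phantom modes but does not attempt to
  define the boundary quantitatively.
* The FT segmentation adapter deliberately ships only trivial methods
  (fixed threshold, two-cluster k-means) for exercising the pipeline
  on rendered phantoms; production use assumes externally produced FT
  masks (`method = "precomputed"`, the default).
* Leave-one-out accuracy on 23 subjects has high variance; the
  classification grid is a comparison device, not a generalization
  estimate.

## A worked miniature

```{r mini, eval = FALSE}
study <- run_study(n_nonsparse = 15, n_sparse = 8, seed = 1)
print(study$experiment)
subset(study$tests, feature == "FC")
```

See the README for the printed output of this example and for how to
regenerate the full set of headline numbers with
`scripts/acceptance.R`.
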
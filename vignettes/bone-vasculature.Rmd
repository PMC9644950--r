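---
title: "Quantifying cortical-bone vascular microstructure in 3D"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical-bone vascular microstructure in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Growing long bones lay down fibrolamellar cortex around a network of blood
vessels. The geometry of that vascular network — how porous the cortex is,
how wide the canals are, and above all which way they run — carries a
signal about deposition rate and mechanical loading, and is one of the few
quantities that can be read from both modern and fossil bone. This package
implements a complete, testable 3D workflow for extracting that signal from
micro-CT stacks of the mid-diaphysis: segmentation of the vascular canal
network, scalar histomorphometry, length-weighted canal-orientation
indices, and the growth-statistics layer that relates those measures to age
and growth rate across an ontogenetic series.

Because raw synchrotron CT scans are enormous and rarely redistributable,
the package also contains a first-class synthetic phantom generator
(`phantom_spec()`, `build_phantom()`) that renders a hollow-cylinder
mineralised cortex with ground-truthed canals and osteocyte lacunae. Every
stage of the pipeline is validated against that ground truth.

## Segmentation model

A cortex volume is segmented in four steps (`segment_cortex()`):

1. **Thresholding.** The mineralised tissue is separated from pore space
   and background by minimum cross-entropy (Li) thresholding: the grey
   threshold minimises `-m0 log(mu0) - m1 log(mu1)` over a 256-bin
   histogram, where `m` and `mu` are the first moments and means of the two
   classes. The implementation minimises the objective exhaustively over
   all candidate splits, so it cannot be trapped by a local minimum of the
   iterative fixed-point scheme; foreground is strictly *above* the
   threshold, and the chosen value is recorded in the run log.
2. **Closing.** Canals are bridged by morphological closing with a
   Euclidean ball (default radius 8 voxels, i.e. 12.8 um at the 1.6 um
   voxels typical of the source material), implemented exactly through two
   distance transforms. The structuring radius must be at least the largest
   canal radius; it is a config parameter because the iteration counts used
   by any particular lab workflow vary. Cavities left fully enclosed are
   filled, so the cortex mask is solid. Out-of-volume voxels count as
   background for dilation and foreground for erosion, which keeps
   structures that touch the stack border from being eaten away.
3. **Pore extraction.** `pores = solid_cortex & !mineralised & !exclusion`,
   labelled with 26-connectivity (the solid phase uses 6-connectivity; the
   complementary pairing avoids topological paradoxes; the choice is a
   convention, as imaging workflows rarely state it). The optional
   exclusion mask implements manual removal of medullary bone. Components
   touching the volume border are retained, since cropped quadrants
   necessarily cut canals.
4. **Partition.** Components with volume strictly greater than 1000 um^3
   are vascular canals; the rest are osteocyte lacunae and are excluded
   from canal analysis. Volume is `voxel_count * voxel_size^3` with no
   partial-volume correction, and the boundary is read strictly ("larger
   than"), so a component of exactly 1000 um^3 is a lacuna.

## Morphometry

* **Porosity** is canal volume divided by the volume of the *filled*
  cortex mask (pore space included in the denominator).
* **Canal and cortical thickness** use the model-independent
  (Hildebrand–Ruegsegger) definition: the local thickness at a point is
  the diameter of the largest inscribed sphere containing it. We compute it
  from the Euclidean distance map via its distance ridge and sphere
  painting. Two discretisation conventions matter and are fixed as
  follows: a sphere centred at a voxel with distance-map value `d` *covers*
  voxel centres within `d`, while its *reported* diameter is `2 (d - 0.5)`
  — the half-voxel correction placing the structure surface between voxel
  centres. This makes an isolated voxel exactly one voxel thick and keeps
  lattice-aligned balls and cylinders within a voxel of their nominal
  diameters. The same definition, evaluated by brute force, is the oracle
  in the test suite, and the two agree voxel for voxel.
  For large cortices the thickness map may be computed on a strided grid
  (`downsample`); cortical walls are tens of voxels thick, so the strided
  estimate stays within a voxel of the full-resolution value.
* **Second moment of area** models the mid-shaft as a circular annulus:
  `I = pi/4 (r2^4 - r1^4)` with `r1 = r2 - cortical thickness`, in mm^4.
  `r2` normally comes from calliper input; `estimate_midshaft_radius()` can
  recover it from a full cross-section by circle fit. Porosity is ignored,
  so `I` is an overestimate, increasingly so in porous bone.

## Canal orientation

The canal mask is thinned to single-voxel centrelines and decomposed into
straight segments between skeleton branch points; each segment gets two
angles and a category, and the per-category indices are formed with length
weighting.

* **Skeletonisation** (`skeletonize()`) is a topology-preserving sequential
  thinning: border voxels are removed in order of increasing distance to
  background when they are simple points (removal preserves both
  foreground 26-connectivity and background 6-connectivity) and not curve
  endpoints. Three engineering details make it robust on tubes:
  directional subiterations (the six face directions are peeled in turn, so
  at most one border layer is removed per direction per iteration); one
  immortal anchor voxel per connected component (its distance-map maximum),
  so no canal can vanish — degenerate two-voxel-wide cores otherwise
  contract away under any sequential scheme, a failure mode shared by
  widely used reference thinning implementations; and endpoint
  re-extension, which walks each endpoint outward along its local tangent
  inside the original mask, restoring the roughly one-tube-radius of length
  that thinning eats from tube ends.
* **Segment decomposition** (`extract_segments()`) cuts the skeleton graph
  (26-adjacency) at junction clusters (voxels with three or more
  neighbours, collapsed to centroids) and reduces each branch to its
  end-to-end chord. Chord length (Euclidean, um) is the weighting length;
  the along-skeleton path length is recorded for diagnostics. Branches
  shorter than `min_length` (default 3 voxels) are discarded — this removes
  the single-voxel spurs thinning creates. Cycles are split at their two
  most distant voxels into two chords, since one chord cannot represent a
  ring.
* **Angles.** With z the bone's long axis: the longitudinal angle is
  `asin(|v_z|)` (90 degrees = parallel to the long axis). The radial angle
  is `asin(|v . rhat|)` where `rhat` points from the bone axis to the
  segment midpoint in the transverse plane — i.e. deviation from the local
  tangent plane of a circular cylinder fitted to the periosteal surface,
  which is exact for a circular cross-section. Directions are sign-free;
  all formulas use absolute dot products. For quadrant crops the bone axis
  lies outside the image; `estimate_center()` recovers it by a
  deterministic three-point consensus circle fit to the periosteal
  boundary of the mid-slice, refined by least squares on the inliers,
  which tolerates the straight cut faces of sector crops. Fits whose
  inliers are equally well explained by a straight line, or that explain
  under 35 percent of the boundary, fail loudly rather than return a
  meaningless centre.
* **Classification and indices.** Longitudinal if the longitudinal angle is
  in [67.5, 90] (any radial angle); else radial if the radial angle is in
  [67.5, 90]; else laminar if the radial angle is in [0, 22.5]; else
  oblique. Bounds are inclusive; longitudinal is tested first, so ties at
  67.5 resolve to longitudinal, and a radial angle of exactly 67.5 (with a
  smaller longitudinal angle) resolves to radial. Each index is the summed
  chord length of its category divided by the total chord length, which
  damps the influence of short junction fragments; the four indices sum
  to 1.

## The phantom: what it does and does not emulate

`phantom_spec()` describes a mineralised hollow cylinder (optionally a
sector, mirroring quadrant-cut specimens) with two grey levels, optional
additive Gaussian noise, tubular canals, and sub-1000-um^3 ellipsoidal
lacunae. Canals are drawn from a mixture over the four orientation
categories: longitudinal canals run along z, radial canals along the local
radial direction, oblique canals inside the oblique angle region — each
with uniform angular jitter (default 10 degrees) about the canonical
orientation, kept inside the category's angle box — and laminar canals are
circular arcs at fixed radius with an optional helical pitch, whose ground
truth is the end-to-end chord (the same abstraction the pipeline measures).
Voxelisation is by centre-of-voxel inclusion. Defaults (outer radius
600 um, wall 300 um, height 400 um, 2 um voxels, canal radius 8 um,
contrast 180/40) render in seconds and carry roughly the 2 percent porosity
of a moderately vascularised cortex. A `padding` margin (default 12 voxels)
frames the cylinder inside the field of view the way a scan would; without
background all around, boundary-condition artefacts of morphological
closing would contaminate the pore set.

Passing tests on phantoms demonstrates correct geometry and calibration of
every stage on idealised two-level data. Real scans differ in ways the
phantom deliberately does not model: reconstruction artefacts (rings,
phase fringes), intensity gradients, partial mineralisation, medullary-bone
texture, and canal networks with biological branching statistics rather
than independently placed tubes. Results on real material therefore still
need the usual visual QC of masks and skeletons.

## Growth and statistics layer

* **Age interpolation** (`interpolate_age()`) maps body mass linearly to
  age between anchor individuals of known age (typically day 1 and day 42,
  the near-linear portion of early growth). No extrapolation: masses
  outside the anchored window are an error.
* **Gompertz growth curves** (`fit_gompertz()`): `y(t) = A exp(-b e^{-kt})`
  fitted by Levenberg–Marquardt least squares. Initialisation: `A` at
  1.05 x max(y), `k` from a log-linearised regression, `b` from the first
  observation, plus ten jittered restarts (internal fixed RNG stream, so
  fits are deterministic); the best residual sum of squares wins. The
  growth-rate curve is the analytic first derivative, with inflection age
  `ln(b)/k` and maximum rate `A k / e`. Confidence bands are first-order
  (delta-method) 95 percent pointwise bands; the parameterisation and the
  band construction are conventions chosen here, as growth-fitting software
  differs in both.
* **Beta regression** (`beta_reg()`): proportion responses (porosity,
  orientation indices) are modelled as `Beta(mu phi, (1-mu) phi)` with
  `logit(mu) = X beta` and constant precision `phi`, fitted by BFGS on the
  log-likelihood with analytic gradients. Responses exactly 0 or 1 are
  shrunk by `(y (n-1) + 0.5)/n` as a safety net (the indices are strictly
  interior in practice). Inference: likelihood-ratio tests between nested
  models (`lr_test()`), and a pseudo R-squared defined as the squared
  correlation of the linear predictor with the logit of the response. The
  fit agrees with an independent maximum-likelihood implementation to
  machine precision in the test suite, and the LR test's type-I error is
  verified to sit at its nominal 5 percent level over a thousand null
  simulations.
* **Cohort layer** (`run_cohort()`): per species-and-bone Gompertz fits for
  length and mid-shaft diameter, radial growth rate evaluated at each
  specimen's age from the diameter fit, beta regressions of each proportion
  outcome on age and on radial growth rate, and Pearson correlations for
  unbounded outcomes. Raw p-values are reported and the number of fitted
  models is stated; no multiple-testing correction is applied, so readers
  can apply their own.

## Numerical choices and degenerate inputs

* Constant images cannot be thresholded (error, not a silent guess).
* Empty masks are degenerate for thickness, skeletonisation and indices —
  these error rather than return 0, because "no canals" and "isotropic
  canals" are different findings.
* The canal/lacuna boundary is strict (`> 1000` um^3 is a canal).
* Tie-breaks at category-box boundaries resolve longitudinal first.
* The segment minimum length (3 voxels) and the closing radius are config
  parameters with the defaults above.
* All pipeline stages are deterministic; `run_specimen()` writes
  byte-identical CSVs on re-runs, and a manifest hash of the configuration
  and package version accompanies every run log.

## Validation problem sizes

The test suite and the acceptance script validate on: a 200-canal phantom
at the default 0.6-mm geometry (~78 million voxels; index recovery within
0.05, porosity within 2 percent relative); balls and cylinders up to 64^3
for thickness oracles; a 0.1-degree grid (811,801 points) for the
classification truth table; 200 replicate Gompertz fits at 2 percent noise;
and 1000 null simulations for LR-test calibration. These sizes were chosen
so the whole validation runs on a laptop-class single core in minutes while
leaving the statistical checks well powered.

## Known limitations

* The annulus model for the second moment of area ignores porosity and
  non-circular cross-sections.
* Chord-based segment lengths undercount the length of strongly curved
  canals; the recorded path length can be used to quantify the difference.
* The radial angle is defined against a circular-cylinder surface model;
  strongly elliptical shafts would need a generalised surface fit.
* Thinning-based skeletons fragment where many canals intersect; length
  weighting keeps the indices stable (validated on phantoms), but
  per-segment counts should not be over-interpreted at high porosity.
* The phantom's canal placement is independent and uniform; it does not
  reproduce the spatial clustering of real vascular networks.
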
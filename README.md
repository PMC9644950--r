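# bonevasc

3D cortical-bone vascular microstructure and growth analysis in R.

Cortical bone in growing birds (and other tetrapods) is deposited around a
network of vascular canals. How porous the cortex is, how wide the canals
are, and which way they run — circumferentially (laminar), along the shaft
(longitudinal), like wheel spokes (radial), or in between (oblique) — track
bone deposition rate and mechanical loading through ontogeny, and are among
the few growth signals readable in both extant and fossil bone. `bonevasc`
turns a micro-CT stack of a mid-diaphyseal cortex into those numbers, and
relates them to growth across a specimen series:

* **Segmentation** — minimum cross-entropy (Li) thresholding of the
  mineralised tissue, morphological closing into a solid cortex mask, pore
  extraction, and partition of pore components into vascular canals
  (> 1000 µm³) and osteocyte lacunae (`segment_cortex()`).
* **Morphometry** — cortical porosity; mean canal and cortical thickness by
  model-independent sphere fitting; second moment of area of the mid-shaft
  annulus, `I = π/4 (r₂⁴ − r₁⁴)` (`porosity()`,
  `local_thickness_mean()`, `second_moment_of_area()`).
* **Orientation** — topology-preserving 3D skeletonisation, decomposition
  into straight canal segments at branch points, longitudinal and radial
  angles per segment (90° = parallel to the long axis; 90° = purely radial,
  respectively), classification into the four categories, and
  length-weighted orientation indices that sum to 1 (`skeletonize()`,
  `extract_segments()`, `orientation_indices()`).
* **Growth statistics** — Gompertz growth curves `y(t) = A e^{−b e^{−kt}}`
  with growth-rate curves (maximum `A·k/e` at age `ln(b)/k`), linear
  age-from-mass interpolation, beta regression with a logit link for
  proportion outcomes (LR tests, pseudo-R²), and Pearson correlations
  (`fit_gompertz()`, `beta_reg()`, `run_cohort()`).
* **Synthetic phantoms** — a ground-truthed generator of hollow-cylinder
  cortices with controllable canal orientation mixtures, lacunae, contrast
  and noise, so the whole pipeline is testable without scan data
  (`phantom_spec()`, `build_phantom()`).

## Worked example

Build a noisy phantom whose canal population is 40 % laminar,
30 % longitudinal, 20 % radial and 10 % oblique, then run the full
per-specimen pipeline on its grayscale stack:

```r
library(bonevasc)

spec <- phantom_spec(outer_radius = 300, cortical_thickness = 150,
                     height = 300, voxel_size = 2, noise_sd = 8)
ph <- build_phantom(60, mixture = c(0.4, 0.3, 0.2, 0.1), n_lacunae = 40,
                    spec = spec, seed = 7)
ground_truth_indices(ph$canals)
#> <orientation_indices> (length-weighted)
#>   laminar 0.648  longitudinal 0.206  radial 0.073  oblique 0.073
#>   59 segments, total weighted length 8085 um

cfg <- run_config(voxel_size = 2, closing_radius = 6,
                  specimen_id = "PH-7", species = "duck", bone = "femur",
                  age_days = 24)
run <- run_specimen(ph$grayscale, cfg)
run
#> <specimen_run>
#>   porosity 0.0261, canal thickness 13.56 um, cortical thickness 148.2 um
#> <orientation_indices> (length-weighted)
#>   laminar 0.657  longitudinal 0.209  radial 0.067  oblique 0.066
#>   94 segments, total weighted length 8044 um
```

The recovered length-weighted indices match the generator's ground truth
within 0.01 even though the skeleton fragments the 59 canals into 94
segments at their crossings — length weighting is what makes the indices
robust to that. Porosity (0.0261) is the canal volume over the filled
cortex volume; canal thickness (13.6 µm) is the sphere-fitting mean for
16-µm-diameter canals sampled at 2-µm voxels; cortical thickness recovers
the phantom's 150-µm wall within a voxel. The summary row also carries the
mid-shaft radius estimated from the periosteal boundary (`r2_mm = 0.2991`
for the 0.3-mm phantom) and the annulus second moment of area
(`I_mm4 = 0.00588`).

Growth curves work the classic modelling way:

```r
t <- seq(0, 60, length.out = 20)
y <- 100 * exp(-4 * exp(-0.1 * t))   # noise-free Gompertz sizes, mm
fit <- fit_gompertz(t, y)
fit
#> Gompertz growth curve  y(t) = A exp(-b exp(-k t))
#>   A = 100   b = 4   k = 0.1 /day
#>   inflection at 13.86 days, maximum rate 3.679 per day
predict(fit, 20, interval = "confidence")
growth_rate(fit, 0:60)
```

Proportion outcomes (porosity, orientation indices) against age or growth
rate use `beta_reg(porosity ~ age_days, data)` with `lr_test()` and the
pseudo-R² reported by `summary()`. `run_cohort()` assembles the whole
statistics layer over a tidy specimen table.

A thin command-line wrapper over these functions ships in
`inst/cli/bonevasc.R` with `phantom`, `run` and `cohort` subcommands.

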
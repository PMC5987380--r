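# tibiamorph

Whole-tibia micro-CT morphometry for comparing long-bone shape and mass
between mouse cohorts — for example an osteoarthritis-prone strain against
its healthy parental control across ages and sexes. The package implements
the full measurement chain on 3D image stacks and pairs it with a
parametric bone phantom whose morphometry is known in closed form, so
every stage is validated without scan data:

- **Trabecular morphometry** in a landmark-anchored metaphyseal ROI
  (the slice where the two primary-spongiosa islands connect, plus 5% of
  bone length): BV/TV, Tb.N, Tb.Th, Tb.Sp and mean-intercept-length
  degree of anisotropy.
- **Whole-bone cortical geometry** at every percentile of length: CSA,
  Ct.Th, principal second moments of area
  (I<sub>min</sub>, I<sub>max</sub>), polar moment
  J = I<sub>min</sub> + I<sub>max</sub>, ellipticity
  I<sub>max</sub>/I<sub>min</sub>, plus calibrated tissue mineral density
  at the 37% site and intracortical porosity.
- **Curvature statistics**: the per-slice moment arm about the
  proximal–distal chord and the normalized curvature lever arm
  arm(50%) / r<sub>eq</sub>, with a clearly labelled beam-theory stress
  surrogate σ = P/CSA + P·e·c/I.
- **Statistical surface**: per-percentile three-way factorial ANOVA
  (genotype × sex × age, Type III, sum-to-zero contrasts) with the banded
  significance map red p < 0.001, yellow 0.001 ≤ p < 0.01, green
  0.01 ≤ p < 0.05, blue p ≥ 0.05, model R², residual screens and group
  means with 95% CI.
- **Preprocessing** for real stacks: 16-bit TIFF + JSON-sidecar I/O,
  minimum thresholding (Otsu suggestion), fibula removal by per-slice
  component tracking with seeded splitting of fused slices, and
  principal-axis or landmark alignment.

The phantom generator (`phantom_spec()`, `generate_cohort()`) produces
curved, tapered, hollow elliptical shafts with optional fibula rod,
connected trabecular lattices with a recorded bridge slice, calibration
rods, blur + noise grayscale, and full 2 × 2 × 3 factorial cohorts with
per-animal parameter effects and seeds — with analytic ground truth for
every derived quantity.

## Worked example

A curved circular tube (outer radius 1 mm, wall 0.2 mm, sagitta 0.5 mm)
voxelized at 25 µm, profiled and measured:

```r
library(tibiamorph)

spec <- phantom_spec(
  length_mm = 10, voxel_um = 25,
  outer_a = function(z) rep(1, length(z)),
  wall = function(z) rep(0.2, length(z)),
  curvature_sagitta_mm = 0.5
)
gen  <- generate_bone(spec, grayscale = FALSE)
bone <- aligned_bone(gen$binary)
prof <- profile_whole_bone(bone)              # 10-90% of length
arms <- moment_arm_profile(prof, aligned = bone)
mid  <- prof[prof$percent == 50, ]
```

which prints

```
CSA 1.1225 mm^2 (annulus closed form 1.1310)
J   0.9215 mm^4 (closed form 0.9274)
Ct.Th 0.194 mm, ellipticity 1.000
midshaft arm 0.501 mm, lever arm 0.502
```

— the voxel measurements sit within ~1% of the annulus closed forms, and
the chord-based moment arm recovers the constructed 0.5 mm sagitta, giving
a normalized lever arm of 0.50.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end on a
synthetic 60-animal cohort (2 genotypes × 2 sexes × 3 ages, n = 5) and
write their tables under `results/`:

1. `01_simulate_cohort.R` — cohort + one grayscale showcase stack.
2. `02_preprocess_showcase.R` — read, threshold, de-fibula, align, anchor
   the trabecular ROI, measure TMD. On the shipped seed it reports:
   `threshold 151.7; fibula voxels removed 126531; length 17.25 mm;
   bridge slice 40; TMD 1.195 g/cm^3; ROI BV/TV 36.7%`.
3. `03_trabecular_metrics.R` — per-animal trabecular table + factorial
   ANOVA per metric.
4. `04_cortical_profiles.R` — per-percentile geometry, moment arms and
   surrogate stress; mean lever arm by group (OA-prone males carry the
   largest curvature: 0.60 vs 0.37–0.48 in the other groups).
5. `05_statmap.R` — significance maps for Ct.Th, CSA and ellipticity
   (SVG heatmaps + CSV), midshaft group summaries.
6. `06_reproduce_demo.R` — one-call pipeline rerun
   (`reproduce_demo()`) plus a byte-identity audit of a repeated run.

`run_pipeline()` exposes the same chain as a single config-driven call
with a resolved-config, log and provenance record in the run directory.

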
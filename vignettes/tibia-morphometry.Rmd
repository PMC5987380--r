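---
title: "Whole-tibia micro-CT morphometry: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-tibia micro-CT morphometry: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tibiamorph implements the image-analysis and statistical chain used to
compare long-bone morphology between mouse strains that differ in
osteoarthritis susceptibility: trabecular morphometry in a
landmark-anchored metaphyseal region of interest, cortical cross-sectional
geometry profiled at every percentile of bone length, curvature
(moment-arm) statistics, and per-percentile three-way factorial ANOVA
significance maps. Because such studies rarely deposit raw scans, the
package pairs every stage with a parametric voxel phantom whose
morphometry is known in closed form; all validation in the test suite runs
against those closed forms.

## The phantom model

A bone is modelled as a hollow shaft with elliptical cross-section. At
normalized length $z \in [0,1]$ (proximal $z=0$) the outer boundary has
semi-axes $a(z), b(z)$ (mm) and the inner boundary is the concentric
scaled ellipse $(a-t, b-t)$ with wall thickness $t(z)$. The section
centroid follows a circular arc whose maximum perpendicular deviation from
the proximal–distal chord (the sagitta $s$) sits at midshaft, in a
configurable plane. The closed forms used as oracles are the elliptical
annulus results

$$\mathrm{CSA} = \pi(ab - a_i b_i), \qquad
I_x = \tfrac{\pi}{4}(a b^3 - a_i b_i^3), \qquad
I_y = \tfrac{\pi}{4}(a^3 b - a_i^3 b_i),$$

with $I_{\min}, I_{\max}$ the sorted pair, $J = I_{\min} + I_{\max}$ and
ellipticity $I_{\max}/I_{\min}$. For a circular arc of chord $L$ and
sagitta $s$, the deflection at chord position $u$ is
$\sqrt{R^2 - u^2} - (R - s)$ with $R = s/2 + L^2/(8s)$, so the midshaft
moment arm equals $s$ by construction and the normalized lever arm is
$s / \sqrt{a(0.5)\,b(0.5)}$ (area-equivalent outer radius).

Binary voxelization uses centre-point inclusion, keeping voxel-count
oracles exact. The grayscale channel models partial volume by a one-voxel
Gaussian blur, adds Gaussian noise, clamps at zero (attenuation is
nonnegative) and snaps to the 16-bit storage grid, so a written stack
reads back identically. Two calibration rods with known attenuation are
placed outside the bone for the density calibration.

The trabecular compartment is a periodic lattice clipped to the medullary
cavity: `plates`, `rods`, `spheres-removed`, or the default `plate-rod`
(plates plus struts along the normal). The last is the only 3D-connected
family and is what whole-bone phantoms use: a pure plate stack is
disconnected along the axis and pure rods are mutually disconnected, so
neither can express the anatomical landmark the ROI anchoring needs — the
slice where two proximal trabecular islands first connect ("bridge").
Proximal of the bridge plane the lattice is split into two islands by a
gap; the plate phase is aligned to the bridge plane so the first
connecting structure sits exactly at the recorded bridge slice. The
realized (voxel-count) BV/TV is recorded as ground truth alongside the
target.

### Cohorts

`generate_cohort()` builds a full 2 × 2 × 3 factorial (genotype × sex ×
age at 10/20/40 weeks), five animals per cell by default (60 bones).
Each animal's parameters are the baseline plus additive or multiplicative
factor effects plus Gaussian biological noise; one master seed is split
deterministically per animal and recorded in the covariate table. The
baseline approximates an adult mouse tibia: 17 mm long, mid-shaft outer
semi-axes ≈ 0.7 × 0.55 mm, 0.25–0.3 mm cortical wall, 0.25 mm sagitta,
and a metaphyseal compartment with 35% BV/TV — deliberately on the high
side, matching a high-bone-mass strain model, and thick enough
(element ≈ 0.12 mm) that elements span several voxels at the working
resolutions. No quantitative effect sizes are available for strain-related shape
differences, so the demonstration effect map (`demo_effect_map()`)
encodes the qualitative pattern of interest at magnitudes chosen once as
plausible: age growth of
size and wall, higher cortical and trabecular mass in the OA-prone
genotype, larger males, and a genotype-by-sex interaction that raises
proximal (30–40%) ellipticity and curvature in OA-prone males only.
Biological noise acts on whole-bone parameters, which makes per-percentile
residuals smoothly correlated along the bone — as animal-to-animal
variation is in reality.

## Preprocessing conventions

* **Thresholding** is a global minimum threshold; `suggest_threshold()`
  offers Otsu's value. The study's numeric threshold is unknown, so it is
  an explicit parameter.
* **Fibula removal** tracks per-slice connected components (8-connectivity
  in 2D, 26 in 3D, everywhere) from the largest most-proximal component.
  Components inside the filled tibia contour are tibia by definition
  (trabecular islands are not fibula); where tibia and fibula fuse into
  one component, the component is split by seeded region growing from the
  previous slice's footprints and the affected z-range is logged.
* **Alignment** rotates the principal inertia axis of the voxel cloud (or
  a landmark chord) onto z, resampling binary masks with nearest
  neighbour. Misalignments up to 0.5° are accepted as aligned without
  resampling: NN resampling fragments thin trabeculae, and generator
  output is already canonical. Per-slice NN jitter after a genuine
  rotation is a few percent on individual slices while profile averages
  are conserved to ≲0.5%.
* **Endosteal envelope**: the cortical shell is isolated by a 3D ball
  opening (two distance transforms) with radius midway between the
  trabecular element half-thickness and the wall half-thickness
  (`open_radius_for_spec()` computes `(t_px + wall_px)/4`); the envelope
  is the filled shell minus the shell, regularized by a union over ±2
  neighbouring slices because plate–wall junction collars pinch the raw
  envelope. For connectivity analysis the envelope is additionally eroded
  by a 2-voxel rim so endosteal segmentation residue cannot
  short-circuit the two islands.
* **ROI anchoring**: the reference slice is the most proximal slice at
  which the two largest intramedullary components become 26-connected;
  the ROI spans the next 5% of bone length towards the diaphysis. On
  binary phantoms the detected slice equals the recorded bridge slice;
  under blur and noise the thinnest connecting structure can drop below
  threshold and the detection then lands on the next (or an adjacent)
  connecting plate — a partial-volume effect the demonstration makes
  visible rather than hiding. A manual reference slice can be supplied.

## Trabecular metrics

BV/TV is the plain voxel ratio. Tb.Th is sphere-fitting local thickness:
each voxel carries the diameter of the largest inscribed sphere containing
it. Sphere radii come from the Euclidean distance transform; the reported
diameter is $2\,\mathrm{EDT} - 0.5$ voxels with coverage extended half a
voxel to the phase boundary. The −0.5 correction recentres the
centre-to-centre distance bias and was validated against slab and annulus
closed forms (slabs measure within 0.5 voxel, annulus wall within ~1.5%).
The residual is phase-dependent: structures whose medial axis falls
between voxel centres (e.g. even-diameter rods) can under-measure by up to
~1.3 voxels — the intrinsic quantization limit of sphere-fitting at these
scales. An isolated voxel reports one voxel. Tb.Sp is the same measure on
the marrow phase; it is reported in mm (a separation in inverse
millimetres, as sometimes printed, is taken to be a typographical slip).
Tb.N uses the direct model $(\mathrm{BV/TV})/\mathrm{Tb.Th}$, with the
inverse-spacing alternative behind a flag.

The degree of anisotropy comes from mean intercept length over 512
quasi-uniform directions (Fibonacci sphere, randomly rotated as a set
under the seed). Three choices matter and are deliberate:

1. sampling is restricted to the inscribed sphere of the volume, so
   boundary terminations are isotropic and the fabric is
   rotation-invariant;
2. line runs terminated by the sampling boundary count as segment ends
   (otherwise the in-plane MIL of plate structures is unbounded and the
   ellipsoid fit loses positive definiteness);
3. intercepts are debounced — a phase change must persist 1.5 voxels —
   suppressing staircase aliasing of digitized oblique interfaces, which
   otherwise inflates intercept counts of rotated structures (DA shifted
   by up to 0.45 without it, ≤0.05 with it).

The fabric tensor is fitted by least squares on
$1/\mathrm{MIL}^2(\mathbf n) = \mathbf n^\top A \mathbf n$; the MIL
ellipsoid radii are the fabric eigenvalues and
$\mathrm{DA} = 1 - \lambda_{\min}/\lambda_{\max} \in [0,1)$ by default
(the classical $\lambda_{\max}/\lambda_{\min}$ convention via a flag).

## Cortical geometry, TMD, porosity

Per slice: CSA from the pixel count; second-moment tensor about the
centroid with the per-pixel self term $h^4/12$ per axis (so small sections
are not systematically underestimated); eigen-decomposition gives
$I_{\min}, I_{\max}$ and the principal angle; $J = I_{\min} + I_{\max}$ is
the polar moment used as "predicted resistance to torsion" (the true
torsional constant of non-circular sections is out of scope and
documented as such); ellipticity is $I_{\max}/I_{\min}$ (monotone in the
axis ratio and free — the axis-ratio square root is a flag); Ct.Th is the
mean 2D inscribed-disc diameter. Profiles run 10–90% of bone length in 1%
steps, percent measured from the proximal end; empty slices are flagged
and more than 10% empty aborts.

TMD maps attenuation to density through the two calibration-rod pairs and
averages over the bone voxels of 100 slices centred at 37% of length,
after a 2-voxel surface erosion — the usual guard against partial-volume
dilution (without it the 1-voxel-blur phantom reads ~12% low at 40 µm;
with it ~1% low). Total porosity fills the outer contour per slice,
excludes the largest enclosed void (the medullary cavity) and reports
pore voxels over shell voxels pooled across 10–90%; slices without an
enclosed cavity (breached or trabecular-filled) are flagged.

## Curvature and the beam surrogate

The moment arm is the perpendicular distance of each slice centroid to
the chord through the most proximal and most distal occupied slices of
the bone (not the ends of the 10–90% profile — against the shorter chord
the recovered sagitta would be biased low); a supplied loading axis
replaces the chord for landmark-based replication. The curvature lever
arm is the midshaft arm divided by the area-equivalent outer radius
$\sqrt{\mathrm{filled\ area}/\pi}$ (the outer semi-major axis is a flag).
The stress output is an explicitly labelled beam-theory surrogate, not a
finite-element solution: $\sigma = P/\mathrm{CSA} + P\,e\,c/I$ with $e$
the arm, $c$ the extreme in-plane fibre distance along the bending
direction and $I$ the second moment about the bending axis. It reduces
exactly to $P/\mathrm{CSA}$ for a straight bone, and exists to let the
shape statistics be read in load terms (homogeneous tissue at 17 GPa,
Poisson 0.3).

## Statistical mapping

At every percentile, a full-factorial linear model genotype × sex × age
(age categorical at 10/20/40 weeks) with sum-to-zero contrasts and Type
III sums of squares gives seven p-values (three main effects, three
two-way, one three-way) and the model $R^2$; for the balanced designs
generated here Type I and Type III coincide, which the suite checks.
Shapiro–Wilk and Bartlett residual screens are recorded as flags while
the analysis proceeds. Significance is banded exactly as red
$p < 0.001$, yellow $0.001 \le p < 0.01$, green $0.01 \le p < 0.05$,
blue $p \ge 0.05$. No multiplicity adjustment is applied across the 81
percentiles by default — interpretation rests on wide contiguous bands,
not isolated cells — with Benjamini–Hochberg per effect behind a flag.
Group summaries are cell means with t-based 95% CI ($n-1$ df);
single-animal cells are flagged with undefined intervals.

## Problem sizes and determinism

The shipped analyses and tests use scaled-down resolutions chosen so that
every structure spans enough voxels for its estimator: cohort geometry at
50 µm voxels (wall ≥ 4–5 voxels, ~340 slices per bone, 60 bones in about
two minutes), the grayscale showcase bone at 25 µm (trabecular elements
≈ 5 voxels, robust under blur + noise + thresholding), lattice validation
cubes at 20 µm with 60³ voxels, and the type-I simulation at 1000
replicates. The 5 µm default voxel size in `phantom_spec()` mirrors the
scanner resolution the phantom emulates and is practical for single-bone
oracle work. Every random element is seeded (master seed split per
animal, seeded MIL direction sets, seeded noise), and `reproduce_demo()`
run twice produces byte-identical numeric outputs.

## What passing tests do and do not show

The phantom validates the measurement chain, not the biology. It contains
no scanner artefacts (beam hardening, rings), its trabecular network is
periodic rather than irregular, its cortical wall is a smooth offset
ellipse without canals at generation time (porosity is validated by
drilling known canals), and its noise is stationary Gaussian. Passing the
oracle suite therefore demonstrates that geometry, thickness, fabric,
curvature and mapping are computed correctly at known signal-to-noise and
resolution — it does not certify segmentation behaviour on pathological
scans. Known limitations worth restating: sphere-fitting thickness has a
phase-dependent quantization error up to ~1.3 voxels in the worst case;
NN resampling after large rotations adds per-slice jitter and can
fragment structures near one voxel thick; and grayscale bridge detection
can shift to an adjacent connecting structure under partial volume.
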
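---
title: "Methods: chest fat quantification in a standardized anatomic space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chest fat quantification in a standardized anatomic space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatsas)
```

This vignette documents the models, conventions and numerical choices
behind `fatsas`, and what the synthetic phantom cohort does and does
not establish.

## 1. Segmentation model and conventions

**Thoracic region.** The analysis region runs from 15 mm superior to
the lung apex to 5 mm inferior to the lung base. Margins convert to
whole slices by rounding outward (`ceiling(mm/dz)`), clipped to the
acquired stack; slices are never resampled. The z index increases
cranially; slice `k` (1-based) sits at `z_origin + (k-1) * dz` mm.

**Body.** Voxels above a soft-tissue/air threshold (default −300 HU,
tunable) form the initial mask; below-threshold regions not 4-connected
to the lateral border of their axial slice are filled. Per-slice 2D
filling is deliberate: 3D filling would close the trachea into the
background through the volume ends.

**Fat window.** The closed interval `[−170, −40]` HU. Closedness at
both ends is a contract: a voxel at exactly −40 HU is fat, at −39 HU it
is not. Monotonicity follows: enlarging the window never shrinks the
fat mask.

**SAT/VAT split.** The interface mask (interior surface of the rib
cage, clipped at the diaphragm) is an *input*, mirroring the manual
delineation step in practice; the pipeline never infers the diaphragm.
VAT = per-slice opening of (fat window ∩ interface); SAT = total fat
minus VAT, so SAT ∩ VAT = ∅ and |SAT| + |VAT| = |fat| hold by
construction. The opening uses a per-slice disc, radius 1 voxel by
default ("remove isolated pixels" is a 2D, pixel-scale operation);
radius 0 disables it. Whether opening should be 2D or 3D is not settled
by the source description, so both the radius and the marrow-correction
placement are exposed as configuration.

**Marrow pseudo-fat.** Medullary bone contains fat-window voxels. The
correction subtracts the per-slice *closing* of the cortical bone mask
from the fat mask (default disc radius 2). We intentionally do not
hole-fill the closed bone: filling the rib-cage annulus' interior would
engulf the entire thoracic cavity and delete VAT. Closing bridges
medullary cavities up to twice the radius wide while never extending
the skeleton outward into adjacent genuine fat. The correction is
applied to the fat mask before the SAT/VAT split and to the VAT mask.

## 2. Standardized anatomic space (SAS)

Landmarks are vertebral mid-levels T2…T10 (n = 9). Calibration maps
each reference subject's landmark positions affinely to `[0, 1]`
(first landmark → 0, last → 1) and averages per landmark across
references, yielding mean locations `M_1…M_n`. The affine
normalization (our choice; the upstream method leaves it unstated)
removes subject height and table position while preserving relative
spacing, and makes calibration invariant to scaled/translated copies.

The subject-to-standard map is piecewise linear between `(L_i, M_i)`
pairs; beyond the first/last landmark it extrapolates with the adjacent
segment's slope, which is needed because the thoracic region extends
beyond the T2–T10 span. Slice selection inverts the map and takes the
*nearest acquired slice*; an exact tie resolves to the more cranial
slice. Reporting granularity is the 17 half-level grid (each landmark
plus each between-landmark midpoint).

A deliberate consequence of never resampling: the selected slice's true
anatomic coordinate deviates from the target by up to `dz/2` (2.5 mm at
5 mm slices). That exceeds nothing at whole-vertebra granularity
(inter-landmark gap ≈ 13 mm, decision margin ≈ 6.6 mm) but is
commensurate with the *half*-level decision margin (≈ 3.3 mm), so
label-constancy claims for the SAS method are made — and tested — at
whole-vertebra granularity, which is also how the linear-baseline
contrast is reported in the source figure.

The linear baseline interprets a fraction proportionally between the
first and last slices of the trimmed volume. Because subjects' landmark
spans occupy very different fractions of their stacks, the baseline
scatters across vertebral levels while SAS stays put; the acceptance
battery reproduces exactly this contrast.

## 3. Quantification

The normalizing length `L` is the Euclidean diagonal of the tight
physical bounding box of the thoracic skeleton mask, with whole-voxel
extents (a single voxel of spacing (1, 1, 5) mm has
`L = sqrt(27) ≈ 5.196` mm). Volumes divide by `L³`, areas by `L²`,
making measures dimensionless and exactly invariant under isotropic
rescaling of the whole subject.

Histogram parameters: `H_m` mean, `H_md` median, `H_lq`/`H_uq`
quartiles via linear interpolation between order statistics (R type 7;
the convention is not prescribed by the source), and `H_p` the center
of the fullest 1-HU-wide integer-centered bin (CT attenuation is
near-integer; bin width configurable), ties resolving to the most
negative bin. Whether the source's mode was binned or raw is unknown;
binned is the stable choice. Empty masks yield a zero measure and an
absent histogram with a logged message — empty slices legitimately
occur above the apex margin.

## 4. Cohort statistics

Correlations are computed on normalized measures. `pcc`/`scc` refuse
constant input by design (silent NA correlations hide degenerate
columns); the cohort-level report instead flags such rows as missing.
The best-slice search is exhaustive over all `C(17, k)` label
combinations (k ≤ 3, combinations need not be contiguous), objective
`ρ(Σ areas, volume)`; exact ties resolve to the most cranial
(lexicographically smallest) tuple. An independent brute-force loop
re-derives the optimum in the test suite on every run. Note the
maximized ρ is *not* monotone in k: the best pair may correlate
slightly less than the best single slice, since the pair's sum is
forced to include a second, noisier level.

Group comparisons: two-sided unpaired t-test, pooled variance by
default with Welch as an option (the source does not say which it
used), plus a Mann–Whitney U test via the normal approximation with
tie correction (no continuity correction). Two constant equal groups
give p = 1 by convention, logged. No multiple-testing correction is
applied anywhere; the report carries raw values only.

Repeatability uses Jaccard precision `|S1∩S2| / |S1∪S2|`. Since the
operator-dependent step is the interface delineation, the pipeline's
precision table perturbs the interface (erosion/dilation by 1 voxel) as
a stand-in for repeated manual trials; this emulates, not reproduces,
human intra-/inter-operator variability.

## 5. The synthetic phantom: what it emulates

Each subject is an elliptical body cylinder with z-varying radii;
posterior lung ellipsoids; an inset (65 %) rib-cage interface capped
inferiorly by a diaphragm dome, so the sub-diaphragmatic exclusion rule
is exercised through the pre-clipped interface; a cortical bone annulus
whose *interior* carries marrow pseudo-fat (excluded from the bone
mask, so the closing-based correction provably removes it); a
subcutaneous fat ring; and an anterior mediastinal VAT blob. Fat HU
values are truncated normals restricted to the fat window, so analytic
truncated-normal moments are exact oracles for histogram recovery, and
100 % of truth-fat voxels lie in the window by construction. No
fat-window voxels are placed below the diaphragm inside the cavity:
with them, the fat-minus-VAT subtraction would silently absorb
abdominal fat into SAT and ground truth could not be exact.

**Stated-world defaults** (chosen once, not revisited): grid 64×64×40
voxels at (4.5, 4.5, 5) mm (5 mm is the source's slice thickness;
in-plane is coarser than clinical CT to keep desk-scale runtimes);
SAT HU −100 ± 20, VAT HU −70 ± 8; soft tissue 40 ± 10 HU, lung −800,
bone +700; 2 % marrow fraction; group B VAT shift −7 HU with
per-subject attenuation-mean SD 5 HU (matching the magnitudes and
per-group SDs of the reported group difference, −73 ± 6 vs −66 ± 5);
40 subjects, groups alternating A/B.

**Landmark variability.** Equally spaced unit-axis positions are warped
per subject by a monotone quadratic-plus-cubic perturbation of
magnitude `warp_strength` (default 0.3; monotone for < 0.45), gaps get
5 % multiplicative jitter, and the landmark span occupies a widely
varying fraction (0.80 ± 0.10, truncated to [0.60, 0.93]) of the lung
extent — the inferior landmark's position in the stack varies by
several vertebral levels across subjects, as real cohorts show.

**Planted coupling.** At the configured standardized level (defaults:
T8 for SAT, T7 for VAT) the slice area is set to
`volume × c × (1 + ε)` with cohort-constant `c` (≈ 1/150 mm⁻¹ SAT,
1/80 mm⁻¹ VAT — the reciprocal effective extent, keeping the planted
area commensurate with its neighbors) and `ε ~ N(0, coupling_noise)`
(default 2 %). The self-referential definition (the coupled slice
contributes to the volume) is resolved by a short fixed-point
iteration. Other levels carry independent per-landmark relative noise
(default 15 %), linearly interpolated along the axis so neighboring
slices stay smoothly related and a ±1-slice selection offset degrades
the coupling only partially. `simulate_cohort_table()` exposes exactly
this statistical model without voxelization; the acceptance battery's
50-cohort recovery study runs on it, while voxelized cohorts are
checked end-to-end separately (rasterization adds ~1–3 % area
quantization noise on top of ε).

**What the phantom does not emulate:** scanner noise, beam hardening,
partial-volume mixtures at tissue boundaries, respiratory motion,
anatomically realistic organ shapes, or genuinely continuous HU
textures. A green test therefore establishes the *operators and their
contracts* — thresholds, morphology, mapping, normalization, search,
statistics — not clinical segmentation accuracy on real CT.

## 6. Numerical and engineering choices

- Quantiles: type 7; mode: 1-HU bins, most-negative tie-break.
- Nearest-slice ties: more cranial slice, both in SAS inversion and in
  the linear baseline.
- `pcc` uses the n−1 covariance convention (cancels in the ratio).
- Pipeline config serializes as JSON (no YAML dependency in the target
  environment); seeds are mandatory and all randomness derives from
  them, so identical config + seed gives byte-identical result CSVs and
  manifest checksums. Volumes/masks persist as RDS between stages,
  tables as CSV, model/manifest as JSON.
- The morphology is pure vectorized R (shift-and-combine over disc
  offsets); grids are small enough that compiled code is unnecessary,
  and the test suite holds it to *exact* agreement with voxel-loop
  oracles.

## 7. Known limitations

- The interface mask must be supplied (or generated); no automatic
  rib-cage delineation.
- Landmarks are inputs; no vertebra detection from HU.
- Whole-vertebra granularity is the resolution limit for label-constancy
  claims at 5 mm slices (see §2).
- The precision table emulates operator variability morphologically; it
  is not a human repeatability study.
- Abdomen/thigh phantoms are single-slice caricatures used to exercise
  the 2D path and the cross-region correlation plumbing, not realistic
  cross-sections.
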
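---
title: "Head measures from T1-weighted MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head measures from T1-weighted MRI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calvaria)
```

## The problem

Skull bone mineral density (BMD) is clinically measured by DXA, and
subcutaneous adiposity by dedicated body-composition imaging. Neither is
available in most neuroimaging studies — but a T1-weighted head MRI is, and
it covers the calvaria and the scalp incidentally. `calvaria` extracts four
proxies from a T1 image plus a six-class tissue segmentation (grey matter,
white matter, CSF, skull, soft head tissue, background — the c1…c6 output of
unified segmentation):

* **proxy BMD** — the negated WM-normalized mean skull intensity of the
  occipital region. Fattier bone marrow in the diploë is *brighter* on T1
  and corresponds to *lower* mineral density, so any strictly decreasing
  transform of normalized intensity is a valid proxy; negation is the
  simplest. The proxy is relative — it is deliberately not calibrated to
  DXA units.
* **bone thickness** — per skull voxel, the sum of the Euclidean distances
  to the CSF and to the soft head tissue, aggregated over the occipital
  sector.
* **IAP** (intensity-based adiposity proxy) — the weight-averaged Gaussian
  peak intensity of the soft-head class over the WM reference. More
  subcutaneous fat means a larger share of bright voxels and a higher
  composite.
* **TAP** (thickness-based adiposity proxy) — mean soft-head-tissue
  thickness over occipital scalp voxels.

The occipital default follows the measure-selection result of the approach
this package implements: occipital skull intensity is the most informative
region for head BMD, and the same regional choice is applied to the other
measures.

## Pipeline stages and their assumptions

### Skull correction

Unified segmentation often assigns bright diploë marrow to the soft head
tissue class. The correction (a) reclaims head-labelled voxels inside the
morphological closing of the skull (Euclidean ball, default radius 3 mm)
when they do not belong to an *outer* head component and are brighter than
the cortical-bone floor (5th percentile of current skull intensities); (b)
fills head/background cavities fully enclosed by skull; (c) prunes skull
islands smaller than 100 mm³. Brain classes are never touched and each
voxel keeps exactly one label, so the operation conserves voxel count and
is idempotent.

Two details are deliberate design choices, because the source method lists
its operators without radii, ordering or connectivity:

* mm-based radii and volumes make behavior resolution independent;
* a 6-connected head component counts as *outer* (scalp) when at most half
  of its voxels lie inside the skull closing. A simpler rule — "touches the
  background class" — misclassifies marrow whose cut face is exposed at the
  truncated inferior boundary of real (defaced, limited-FOV) scans; the
  majority vote is robust to both that and to scalp patches dipping into
  the closing.

The correction does not move dark skull voxels back to scalp: whether the
original method does this is not documented, so it is left out rather than
guessed.

### Thickness maps

Distances are exact Euclidean distance transforms computed in mm with
per-axis spacing. The raw sum `d_inner + d_outer` between the bounding
classes overestimates the thickness of an axis-aligned slab of `n` voxels
at spacing `h` by exactly one spacing (it measures center-to-center through
both boundaries), so the mean spacing is subtracted: slabs then measure
exactly `n·h` at every voxel, which is the package's anchor test. On curved
shells the estimator carries a small curvature/discretization bias
(≈ 0.2–0.4 mm at 1–1.2 mm resolution for a 7 mm shell), well inside the
±0.5 mm acceptance band.

Head (scalp) thickness applies two exclusions: voxels more than 30 mm from
the skull, and voxels on axial slices below the lowest slice of the bone
mask — the quantitative reading chosen here for the unquantified "lower
portions of all brain scans" exclusion. The 30 mm rule is applied to the
voxel's own distance-to-skull, not along a surface normal (the alternative
reading; documented, not implemented).

Probability segmentations are hardened by argmax (ties broken by the fixed
class order GM > WM > CSF > skull > head > background) before any
distance transform: the thickness definitions are set-based.

### Mid-skull surface

The percentage position map `p = d_CSF / (d_CSF + d_head)` is 0 at the
inner bone boundary and 1 at the outer one; degenerate voxels (both
distances zero) are set to 0.5 and QC-flagged. The `p = 0.5` level set is
triangulated by marching tetrahedra on the Kuhn 6-tetrahedra cube
decomposition — all tetrahedra share the cube diagonal, so the
triangulation is conforming across cubes and a closed level set yields a
closed 2-manifold (the test suite checks Euler characteristic 2 on closed
shells). The largest connected component is kept; normals follow the
gradient of `p` (outward), which is intrinsic and independent of mesh
ordering.

Per vertex, `n_samples = 7` trilinear T1 samples span `[-t/2, +t/2]` along
the normal (`t` = local bone thickness; 7 samples resolve a three-layer
skull at 1 mm without oversampling noise). Sampling is strictly inside the
bone span — whether the original method samples beyond the bone edges is
unknown, so it is not done. The cortical intensity is the profile minimum;
the marrow intensity is the distance-weighted average with triangular
weights `w(o) = max(0, 1 − |o|/(t/2))`. The weighting function is not
specified by the source; the triangular kernel is the simplest
"distance-weighted" choice that peaks on the midline and annihilates the
cortical plates at the profile ends.

### Calvarial sector atlas

The reference atlas was drawn manually on CT data and is not distributable,
so the package builds a procedural stand-in: every voxel is labelled by its
angular sector about the head center (elevation split at 10°, azimuth
split at 45°/135°): frontal (anterior–superior), parietal L/R
(lateral–superior), occipital (posterior, all elevations), temporal L/R
(lateral–inferior), sphenoid (anterior–inferior). The defacing-safe bone
mask covers frontal + parietal + occipital only — temporal and sphenoid
bones are thin and defacing-prone. Sector bounds are explicit documented
constants, *not* an inference about the manual atlas; a real atlas volume
can be passed instead (`--atlas`). Mapping to individual grids is
nearest-neighbor through the linear (affine) transform only. When no
template transform is available the sectors are built directly on the
subject's own corrected skull (centroid-centered), which is equivalent to
an exactly-matched template.

TAP needs a region for scalp voxels, which are not in the atlas: each scalp
voxel inherits the sector of its nearest skull voxel (deterministic
nearest-bone propagation).

### Intensity model

The WM reference is the median T1 intensity over high-confidence WM voxels
(probability > 0.9 or the WM label; at least 100 voxels). The median is
robust to partial volume and residual bias; the original normalization
estimator is not documented.

The soft-head intensity composite fits a K = 4 univariate Gaussian mixture
(the usual Gaussian count for the soft-head class in unified segmentation)
by EM with deterministic quantile initialization. For speed the EM runs on
a 1024-bin histogram of the (optionally subsampled) intensities with bin
counts as case weights — at this bin resolution parameter recovery is
indistinguishable from per-voxel EM at the tested tolerances (weights
±0.02, means ~0.1%). A component whose weight collapses below 1e-4 triggers
a refit with K−1 and a QC flag. IAP < 0.5 raises a
`possible_fat_suppression` QC warning (fat-suppressed protocols invert the
fat contrast); no correction is attempted.

### Evaluation statistics

Retest reliability uses ICC(A,1): two-way model, absolute agreement,
single measure — one coefficient per measure for two sessions, the variant
matching "2-way-mixed, absolute agreement" with a single value per session.
The p-value is the F = MSR/MSE test and the 95% CI follows McGraw & Wong.
Exactly zero between-subject variance returns ICC 0 with a flag. Validity
panels use Spearman correlations (average ranks on ties; exact p for
n ≤ 10 without ties, t-approximation otherwise) with Holm step-down
adjustment across the panel.

## The phantom: what it emulates, and what a green test does not establish

`phantom_spec()` builds a layered head: WM core and GM rind of an
ellipsoidal brain, a CSF gap, dark inner table, bright diploë, dark outer
table, and a scalp drawn from a muscle/fat two-component mixture. Layer
membership is defined by exact Euclidean distance from the brain mask, so
nominal layer thicknesses hold in every direction, for ellipsoids and
under rotation. Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| grid, spacing | 128³, 1 mm | typical 1 mm isotropic T1 protocols |
| skull layers | 2 / 3 / 2 mm | adult calvaria: two cortical tables around diploë |
| CSF gap | 2 mm | subarachnoid space at the vertex |
| scalp | 6 mm | adult scalp thickness |
| tissue means (a.u.) | CSF 80 < bg 10 … cortical 130 < GM 280 < muscle 300 < WM 400 < diploë 450 < fat 600 | T1 ordering: bone tables darkest, fat brightest, diploë bright (marrow fat) |
| `diploe_intensity` | 450 | the BMD-linked dial: brighter marrow = fattier = lower BMD |
| `fat_fraction` | 0.3 | scalp fat share; the adiposity dial |
| `noise_sd` | 20 | SNR (WM/σ) = 20, a conservative 3T figure |
| noise model | Gaussian (Rician optional) | Gaussian suffices at this SNR; Rician available for realism |
| bias field | off by default; `1 + a·poly₂(x,y,z)` | smooth multiplicative inhomogeneity when enabled |
| inferior quarter | open | emulates defacing / limited FOV; exercises the lower-cut exclusion |

Truth labels are hard (a voxel belongs to the layer containing its center);
probability maps are produced by 1 mm Gaussian smoothing of the binary
classes and renormalization, giving both hard and soft test paths.

The phantom does **not** emulate cortical folding, sutures, partial-volume
fractions at class boundaries, chemical-shift artifacts, k-space effects, or
realistic defacing geometry. Green tests therefore establish the numerical
correctness and internal consistency of the pipeline — exact distances,
slab-exact thickness, monotone response to planted marrow brightness,
adiposity and thickness, recovery of planted segmentation defects,
reliability under noise — and *not* the cohort-level validity of the
proxies against DXA or body-composition measures, which requires restricted
clinical data.

The simulated retest experiment draws per-subject anatomy around the base
spec (geometry ±10%, layer thicknesses ±25–30%, diploë intensity
350–550, scalp fat 0.15–0.45), generates two acquisitions with independent
noise, and — important — plants a session-specific marrow misclassification
(30% of diploë) before each run, so the correction stage contributes
realistic variance. Without that, label-driven measures would be trivially
identical across sessions and their ICC meaningless. A per-session
intensity offset (`protocol_shift_sd`) is available to demonstrate ICC
degradation under protocol mixing; harmonization itself is out of scope.

## Numerical choices

* Distance transforms: exact (Felzenszwalb–Huttenlocher), anisotropy-aware;
  verified against brute-force nearest-neighbor search.
* Morphology: ball structuring elements realized as thresholded distance
  maps — exact Euclidean balls at any radius/spacing.
* Argmax ties: fixed class order (GM first), deterministic.
* EM: histogram-weighted, tol 1e-10 on the log-likelihood, max 500
  iterations, σ floored at 1e-6; component collapse < 1e-4 triggers K−1.
* Degenerate position-map voxels (`d_CSF + d_head = 0`): set to 0.5,
  QC-flagged.
* Anisotropy > 20% between voxel axes raises a QC flag (the h̄ correction
  uses the mean spacing).
* All seeds are explicit; every stage is bit-reproducible given its seed.

## Known limitations

* Proxy BMD is relative; between-protocol offsets are not harmonized.
* The sector atlas is a geometric stand-in — regional labels approximate
  anatomy only as well as angular sectors can.
* Thickness is a two-sided distance estimate, not a streamline model; very
  high curvature (petrous, skull base) is out of scope (calvaria only).
* NIfTI support covers NIfTI-1 (.nii/.nii.gz); oblique affines are carried
  through bookkeeping but phantoms and atlas construction assume
  axis-aligned grids.
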
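---
title: "Stitching brain and spinal-cord diffusion MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching brain and spinal-cord diffusion MRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diffusion MRI of the brain and of the cervical spinal cord are acquired as
separate fields of view (FOVs): the cord needs a small, distortion-resistant
FOV, the brain a large one, and the two acquisitions share only a band of
slices around the brainstem. Tractography run inside either FOV alone stops
at the FOV boundary, so fibers that physically continue from the cortex into
the cord are reconstructed as short fragments. `dtistitch` estimates the
rigid relation between the two stacks from their non-diffusion-weighted (b0)
images, fuses them into one continuous volume, and quantifies the result
two ways: a Dice coefficient on thresholded fractional-anisotropy (FA) maps
across the overlap, and the distribution of streamline lengths, which should
grow once fibers can cross the seam.

## Registration model

The relation between the two stacks is modelled as a through-slice integer
offset `z*` plus one in-plane rigid transform `(theta, dx, dy)`: the slice
planes of the two acquisitions are taken as parallel (both are axial stacks
of the same session), so no out-of-plane rotation is estimated. The
similarity is cross-correlation of b0 intensities; the package computes
both the raw double sum `CC = sum_xy A(x,y) B'(x+dx, y+dy, theta)` and, by
default, its zero-mean unit-norm (Pearson) form, which is invariant to the
different intensity scales of the two acquisitions.

Estimation proceeds in the order a human operator would work:

1. **Masking.** Correlation is computed on nervous tissue only. Surrounding
   neck tissue shares no structure between the FOVs and biases the
   similarity, so each b0 is zeroed outside a nervous-system mask before any
   scoring. The mask threshold is found hierarchically: Otsu's threshold
   separates tissue from background, then a second Otsu on the
   within-tissue histogram separates the bright nervous system; this is the
   automated counterpart of an operator nudging an intensity threshold.
   Additionally, all scored pixels are restricted to the in-plane footprint
   of the (smaller) cord FOV — pixels the moving acquisition never imaged
   carry no alignment information.
2. **Reference slice.** One distinctive brain slice anchors the slice
   search; `auto` mode picks the highest-variance slice in the inferior
   quartile of the brain stack (where the brainstem sits), `manual` accepts
   an operator's index.
3. **Slice localization.** Every cord slice is scored against the reference
   by its *best* correlation over the rotation grid and translation search
   (a stride-2 translation grid followed by a ±1 refinement around the
   coarse optimum, which restores the exact per-slice peak at a quarter of
   the cost). This transform-invariant profile matters: a plain per-slice
   correlation is reliable only when the two stacks are already in-plane
   aligned, and we measured mislocalizations of up to 19 slices at a 6 mm
   shift when the plain profile drives the offset. The plain profile
   remains available as `correlation_profile()` (mode `raw` reproduces the
   double sum exactly).
4. **Offset consensus.** The provisional transform from the peak slice is
   applied to the whole cord b0 once, and candidate offsets within ±5
   slices of the peak are re-scored by the mean slice-wise correlation over
   the entire overlap. One slice pair carries little signal compared to
   interpolation noise; thirty pairs decide the offset unambiguously.
5. **Per-slice refinement and aggregation.** `refine_rigid()` runs on every
   overlapping slice pair: for each angle in the grid the moving slice is
   rotated about its centre (bilinear, zero fill) and integer translations
   are scored exhaustively — by default across the full ±`max_shift`
   window, and inside the estimator across a ±5-voxel window centred on
   the provisional transform from the localization stage (the translation
   is already known there to a voxel or two). The global transform is the
   coordinate-wise median over the pairs whose score exceeds the 25th
   percentile — a robust aggregate that tolerates a few poorly structured
   slices. Per-slice parameters are kept for QC.

Ties in the search are broken deterministically (smallest `|theta|`, then
smallest `|dx|+|dy|`, then lexicographic), and nothing in the stitch draws
random numbers, so repeated runs are bit-identical.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| rotation grid | 7 angles, −12° … 12° | degrees | seven evenly spaced angles across the plausible head-to-neck twist; the grid is the resolution of `theta` |
| `max_shift` | 10 | voxels | exhaustive integer search bound; ±10 mm at native 2 mm resolution covers positioning differences |
| correlation mode | normalized | — | raw double sum is brightness-biased when the FOVs differ in gain |
| `min_overlap_slices` | 5 | slices | fewer matched pairs than this is treated as a failed stitch |
| blend | feather | — | linear ramp across the overlap avoids a visible seam; `brain_priority` / `cord_priority` keep one source verbatim |
| b0 threshold | 50 | s/mm² | vendors store b=0 as small nonzero values; qualifying frames are averaged |
| FA threshold (QC) | 0.35 | — | isolates coherent white matter; boundary is inclusive (FA = 0.35 is in) |
| tracking step | 0.1 | mm | deterministic Euler step well below voxel size |
| angular threshold | 90 | degrees | effectively "follow the eigenvector wherever it bends"; tighter values available |
| length bounds | 10–1000 | mm | discards seed debris and runaway loops |
| seed density | 0.5 / voxel | — | capped at 50,000 seeds; jitter comes from one integer seed (default 17) |

## Fusion of the two q-spaces

The two acquisitions generally use different gradient schemes, so fused
diffusion frames are never averaged: the stitched volume stores one
feathered b0 plus both DWI blocks verbatim with a merged gradient table,
and a frame-coverage matrix records which frames exist on which slices.
The tensor fit consumes that matrix, fitting each slice from whichever
frames cover it (cord-only slices from the cord block, brain-only from the
brain block, overlap slices from both). Outside the overlap the fused data
equal their source bit-exactly.

When the in-plane transform is applied to the moving diffusion volume, each
gradient direction is premultiplied by the rotation's 3D embedding about
the slice axis, keeping directions consistent with the resampled frames.
Whether this rotation was applied in the original workflow is not
documented; a flag (`rotate_bvecs = FALSE`) disables it.

## Tensor fit, FA, tracking

The reconstruction is a standard single-tensor fit — a deliberate
substitution for the generalized q-sampling reconstruction used in the
source workflow, since only FA and the principal direction feed the tracker
and the QC. The fit is log-linear least squares with one reweighting pass
(weights `S²`), eigenvalues clipped at zero before
`FA = sqrt(3/2 · Σ(λ−λ̄)² / Σλ²)`, and a deterministic sign convention for
the principal eigenvector. On noiseless forward-simulated signals the fit
is exact to solver precision (the tests assert 1e−9 on the tensor and
1e−10 on FA rotation-invariance).

Tracking is deterministic FACT-style Euler integration, bidirectional from
each seed, with trilinear interpolation of the eigenvector field under
per-corner sign alignment. Stopping: FA below threshold, mask exit, turning
angle above the limit, length cap. The adaptive FA threshold is Otsu's
threshold on the in-mask FA histogram clamped to [0.08, 0.35]; the exact
adaptive rule used interactively in the source workflow is not published,
so this construction is ours. Runge-Kutta integration was considered and
left out: at 0.1 mm steps on voxel-scale fields the Euler error is far
below the interpolation error.

Fiber-length summaries report n, median, mean and IQR. "Stitching makes
fibers longer" is operationalized as a one-sided Mann–Whitney rank test at
α = 0.05 on per-streamline lengths, stitched vs each single FOV — the
source reports medians without naming a test, and a rank test matches the
skewed, bounded nature of length distributions.

## Dice QC

For each overlapping slice pair the two FA maps are binarized at 0.35,
reduced to the largest 8-connected component nearest the image centre
(components within 10% of the largest area compete on centroid distance —
"largest" and "most central" are otherwise two criteria), and scored with
`Dice = 2|A∩B|/(|A|+|B|)`. The subject-level value is the mean over slices
where both masks are nonempty; the slice-to-subject reduction is not
specified in the source, and the mean is the least surprising choice. Both
empty masks define Dice = 1 with a warning. The comparison is brain-FOV FA
vs transformed cord-FOV FA (rather than fused-vs-source); both modes are
reachable through `dice_report()`'s explicit slice indices.

## The phantom

`generate_pair()` builds both FOVs as resampled views of one analytic
world-space scene, which makes the stitching problem well posed by
construction and gives every test an exact ground truth. The scene is:

* a "cord/brainstem" tube along z — elliptical cross-section (8 × 5 mm
  semi-axes) with an attached 3 mm side lobe that breaks rotational
  symmetry the way the midbrain outline does, widening linearly by ×1.9
  from the caudal to the cranial end so that every axial slice has a unique
  scale (this is what makes slice localization identifiable);
* an ellipsoidal isotropic "brain" blob in the cranial region;
* an isotropic "neck/head tissue" cylinder around the tube. This
  compartment is essential for realistic FA behaviour at edges: FA is
  invariant to signal scaling, so against empty background a
  partial-volume voxel keeps the tube's full anisotropy and thresholded FA
  masks dilate with every interpolation pass. With tissue around the cord,
  edge voxels mix anisotropic and isotropic signal and lose anisotropy, as
  they do in vivo.

Diffusion inside the tube has eigenvalues (1.7, 0.3, 0.3)×10⁻³ mm²/s along
the tube axis (healthy white-matter values, FA ≈ 0.80); blob and tissue are
isotropic at 0.7 and 1.0×10⁻³ mm²/s. The cord FOV is sampled through the
inverse of the true transform, so recovery targets are exact; noise is
Rician (magnitude MRI), with SNR defined on the tube-interior b0, and the
default is noise-free because the phantom's role is ground-truth testing.
Default dims (brain 48×48×40, cord 32×32×48 at 2 mm) keep the full
pipeline at about 45 s.

What the phantom does **not** emulate: susceptibility and eddy-current
distortion (external tools are hooked, not simulated), cardiac/respiratory
motion, coil-profile bias fields, crossing fibers, and anatomical detail
beyond one tube and one blob. Passing tests therefore demonstrate the
correctness of the estimation and evaluation machinery under the modelled
conditions, not performance on distorted in vivo data.

## Problem sizes in the tests and acceptance script

Rigid recovery is exercised over the full 7 × 11 × 11 grid of ground
truths (angle grid × shifts −5…5 voxels in x and y), with the through-slice
offset cycling over 5…20; phantoms for this grid carry 2 diffusion
directions since only the b0 images are consumed. The end-to-end pipeline
(upsampling, stitch, three tensor fits, three tracking runs, Dice QC) runs
on the default phantom with 16 directions per FOV and is executed twice to
assert bit-identical outputs. Tracking produces roughly 10⁴ streamlines
per condition at the default seed density — the same density as the source
workflow, at desk scale rather than 10⁶ tracts.

## Known limitations

* The transform model is in-plane rigid; a tilted cord relative to the
  brain stack (out-of-plane rotation) is not corrected and will depress
  the Dice score rather than fail loudly.
* Slice localization assumes the through-slice spacing of the two stacks
  matches; resampling to a common slice thickness must happen upstream.
* Exactly two FOVs are fused; chaining more segments (e.g. thoracic cord)
  would need a composition layer that does not exist yet.
* The motion-correction registration (frame-to-b0 mutual information,
  coarse grid + Nelder–Mead) is adequate for the small perturbations it is
  tested on (≤5°, ≤4 voxels); large motion should be handled by the
  external distortion-correction tools it complements.
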
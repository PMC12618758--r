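# dtistitch

Stitching brain and cervical spinal-cord diffusion MRI fields of view into
one continuous volume, with the downstream machinery to prove the stitch
worked.

Brain and cord diffusion acquisitions are separate stacks that overlap only
at the brainstem. Tractography confined to either field of view (FOV)
truncates every pathway at the FOV boundary. `dtistitch` estimates the
rigid relation between the two stacks from their b0 images by
cross-correlation — a through-slice offset `z*` plus one in-plane transform
`(θ, Δx, Δy)`, with `θ` searched over seven angles spanning −12°…12° and
translations searched exhaustively — applies it to the diffusion frames
(rotating the gradient directions accordingly), and fuses the stacks with
linear feathering across the overlap:

```
CC(z)        = Σx Σy A(x,y) · B(x,y,z)                 (slice localization)
CC(θ,Δx,Δy)  = Σx Σy A(x,y) · B'(x+Δx, y+Δy, θ)        (in-plane refinement)
Dice(A,B)    = 2|A∩B| / (|A| + |B|)                    (alignment QC on FA ≥ 0.35)
```

Evaluation layers: a weighted log-linear diffusion-tensor fit with FA maps,
deterministic streamline tractography (0.1 mm steps, 90° angular threshold,
10–1000 mm length bounds), per-FOV fiber-length statistics with a
Mann–Whitney comparison, and slice-wise Dice QC on thresholded FA. A
deterministic synthetic phantom generates paired FOVs with known ground
truth for all of it.

## Worked example

```r
library(dtistitch)

# two overlapping FOVs of one synthetic subject; the cord FOV is rotated 4°
# and shifted (3, -2) voxels with a 12-slice overlap offset
pair <- generate_pair(phantom_spec())

res <- run_pipeline(list(out_dir = "stitch_out"))
res$transform
#> RigidParams2D: theta = 4 deg, shift = (6, -4) vox, z_offset = 24, score = 0.9850765
res$dice
#> DiceReport: aggregate 0.9515 over 72 slices (FA >= 0.35)
sapply(res$lengths$stats, `[[`, "median")
#>    brain     cord stitched
#>     80.1     96.0    104.0
```

The recovered transform is the phantom truth on the upsampled grid (the
pipeline upsamples by 2 first, so 4°, (6, −4) voxels, offset 24 ≡ (3, −2)
voxels and 12 slices at native resolution). The Dice report says the
brain-FOV and transformed cord-FOV FA masks agree to 0.95 across the
72-slice overlap. The medians tell the scientific story: fibers tracked in
either FOV alone stop at its boundary (80 and 96 mm), fibers tracked in the
stitched volume cross the seam (104 mm); `res$lengths$tests` holds the
Mann–Whitney p-values.

For real data, point the pipeline at NIfTI + FSL-dialect gradient tables:

```r
run_pipeline(list(
  input = list(mode = "files",
               brain_image = "brain.nii.gz", brain_bval = "brain.bval",
               brain_bvec = "brain.bvec",
               cord_image = "cord.nii.gz", cord_bval = "cord.bval",
               cord_bvec = "cord.bvec"),
  out_dir = "out"))
```

A thin command-line front end with subcommands
`stitch | track | qc | phantom | pipeline` lives at
`inst/cli/dtistitch.R` (exit codes: 0 ok, 2 validation, 3 stitch failure,
4 external tool).

## Layout

- `R/` — volume I/O and containers, preprocessing (upsampling, masks,
  mutual-information motion registration, external topup/eddy hooks), the
  stitcher, tensor/tracking, Dice QC, phantom, pipeline orchestration
- `src/` — RcppArmadillo kernels: rigid resampling, exhaustive CC search,
  trilinear interpolation, connected components, tensor fit, tracker
- `vignettes/stitching-methods.Rmd` — the model, its assumptions, every
  tunable, and what the phantom does and does not emulate
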
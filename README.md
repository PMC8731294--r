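# spinereg

Deformable registration and segmentation toolkit for spine MRI, built around
three pieces of machinery and the evaluation metrics that tie them together:

* a **cubic B-spline free-form deformation** transform — displacement fields
  interpolated from a control-point lattice by the cubic basis polynomials
  `R0..R3`, with analytic second derivatives;
* **mutual-information similarity** — `MI(A,B) = K(A) + K(B) − K(A,B)` from a
  hard-binned joint intensity histogram, cross-checked against the equivalent
  double-sum form — combined with a **bending-energy penalty**
  (mean summed squared second derivatives of the displacement field) into the
  registration objective `α₁·(−MI) + α₂·V`, minimized by a deterministic
  multiresolution greedy optimizer;
* a compact **U-net segmenter** (contraction/expansion paths with skip
  connections, ReLU convolutions, per-pixel softmax) trained with a
  **soft-Dice objective**, implemented directly on matrix operations so it
  trains in minutes on one CPU;
* **Dice / Jaccard / mean target registration error** evaluation, with the
  exact identity `D = 2J/(1+J)`.

Patient data for this anatomy is not publicly available, so the package ships
a **synthetic spine phantom generator** — stacked bright vertebral bodies,
disc bands, a vessel tube, controllable Gaussian noise, and ground-truth
B-spline deformations drawn from the package's own transform model — and all
quantitative claims are verified against that known ground truth. The target
audience is researchers in medical image analysis who need a transparent,
fully testable reference implementation of this classic registration stack.

## Worked example: recovering a known deformation

```r
library(spinereg)

# a 64x64 spine phantom (5 vertebrae, disc bands, vessel, noise sd 5)
cfg <- phantom_config(shape = c(64, 64), seed = 42)
ph  <- generate_phantom(cfg)
ph$volume
#> <image_volume> 64 x 64 voxels, spacing (1, 1) mm, origin (0, 0) mm
ph$mask
#> <label_mask> 64 x 64 voxels, labels {0, 1, 2, 3, 4, 5, 6, 7}

# deform it by a known random B-spline field (up to 3 mm) and register back
gt        <- random_deformation(cfg, max_displacement = 3)
reference <- warp_image(gt, ph$volume)
res       <- register(reference, ph$volume, registration_config())
res
#> <registration_result> 3 level(s), final cost -4.407833 (MI = 4.407837 bits), converged: TRUE

# landmark error at the vertebra centroids, before vs after
lm <- landmark_set(ph$landmarks$points, transform_point(gt, ph$landmarks$points))
mean_tre(NULL, lm)           # 1.480 mm  (pre-registration)
mean_tre(res$transform, lm)  # 0.082 mm  (post-registration)

# mask overlap against the ground-truth deformed mask
M_ref <- warp_image(gt, ph$mask)
overlap_report(M_ref, warp_image(res$transform, ph$mask))
#> <overlap_report> Dice = 0.9928, Jaccard = 0.9856 (|Q| = 2290, |W| = 2265, |QnW| = 2261)
```

The fitted transform reduces the centroid landmark error from 1.48 mm to
0.08 mm — about 6% of the initial misalignment — and raises whole-mask Dice
to 0.99.

Segmentation works the same way at desk scale: `train_unet()` on a list of
(volume, mask) pairs from `generate_phantom()`, then `segment()`; training is
seed-deterministic. See the methods vignette
(`vignettes/spinereg-methods.Rmd`) for the models, parameter defaults, and
the design rationale.

A thin command-line front end (`inst/cli/spinereg`) exposes `simulate`,
`register`, `evaluate`, `segment-train` and `segment` subcommands over NIfTI
files for shell pipelines.

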
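# mdefov

Extended field-of-view (EFOV) lensless in-line holography with multi-depth
phase retrieval, in R.

## The problem

Lensless in-line (Gabor) holography records, directly on an image sensor,
the interference between the light scattered by a sample and the unscattered
illumination. It delivers quantitative amplitude and phase with no imaging
lens — but two artifacts of the geometry limit it:

* the **field of view** is capped by the sensor die, and
* in-line reconstruction is degraded by the **twin image**, the defocused
  conjugate that overlaps the true image and washes out contrast.

`mdefov` implements the joint computational remedy: tiles recorded while the
sample is scanned laterally on a serpentine path are registered and
**stitched** into one extended hologram per sensor depth, and holograms
recorded at several axial depths feed a **multi-depth amplitude-constrained
phase retrieval** that recovers the wavefront phase and suppresses the twin
image before object-plane reconstruction.

The package is pure computation: a full synthetic forward model (bar
targets, blob phantoms, scanned multi-depth hologram sets with manifest)
stands in for the acquisition hardware, so every stage is testable without
recorded data.

## The method in brief

* **Propagation.** Scalar fields propagate by the angular spectrum method:
  the spectrum is multiplied by
  `H(f; dz) = exp(i 2π dz √(1/λ² − f_x² − f_y²))`,
  zero on the evanescent domain, with an automatic band-limited variant
  when `|dz|` exceeds the sampling bound `N p²/λ`.
* **Stitching.** Adjacent-tile overlap ROIs (±10% search margin) are
  matched by windowed normalized cross-correlation; per-pair displacements
  pass a median gate plus 2-D histogram vote; global positions solve an
  integer least-squares over all pair constraints; tiles are feather-blended
  by `P(x,y) = Σ Pᵢ Wᵢ / Σ Wᵢ` and auto-cropped to the largest fully covered
  rectangle (bounds shared across depths).
* **Retrieval.** With K co-registered stitched holograms `H₁…H_K` at
  distances `z₁…z_K`, the field starts at the reference plane as
  `H_r·exp(i·0)` and sweeps `r→K→1→r` each iteration, propagating between
  planes and replacing the modulus with the measured amplitude at each;
  convergence is tracked by the RMSE at the reference plane and its
  per-iteration difference ΔRMSE (10 iterations by default).
* **Analysis.** Reconstruction is back-propagation to the object plane;
  resolution is judged by Michelson fringe contrast
  `(I_max − I_min)/(I_max + I_min)` on three-bar chart elements with the
  MTF10 criterion (resolved ⇔ contrast ≥ 0.10), plus the closed-form system
  parameters: resolution `λ√(4z² + L²)/(2L)`, `NA = (L/2)/√(z² + (L/2)²)`,
  depth of field `λ/NA²`, overlap ratio `1 − step/L`, area gain
  `(L_stitched/L_single)²`.

## Worked example

The desk-scale demo world (`desk_config()`): He-Ne illumination (632.8 nm),
2 µm pixels, 256 px tiles, a 3×3 serpentine scan with 0.23 mm steps
(55.1% overlap), five sensor planes at z = 4…5 mm (0.25 mm spacing),
reference plane 3. The object combines three-bar chart elements
(G4E4 = 22.1 µm, G5E2 = 13.9 µm, G6E2 = 7.0 µm line widths) with
absorbing/phase blobs.

```r
library(mdefov)
out <- run_pipeline(desk_config(), "demo", seed = 1)
out$retrieval$trace$rmse
#  [1] 0.010554 0.007664 0.006294 0.005487 0.004994 0.004688 0.004484
#  [8] 0.004339 0.004232 0.004148
out$report
#   group element linewidth_um  contrast resolved
# 1     4       4    22.097087 0.4627406     TRUE
# 2     5       2    13.920292 0.8524540     TRUE
# 3     6       2     6.960146 0.5921172     TRUE
```

The RMSE trace is the convergence of the 10 retrieval sweeps; its last
step is |ΔRMSE| = 8.4·10⁻⁵, i.e. converged. The contrast table comes from
line profiles across each element of the **MD-EFOV** reconstruction; for
comparison, the same profiles on the single-plane EFOV back-propagation
(no phase retrieval) give 0.382 / 0.415 / 0.279 — lower on every element,
the twin-image suppression at work. All pair shifts during stitching equal
the 115 px ground truth, and the stitched planes match a directly simulated
full-field hologram to ~4·10⁻¹⁷ RMS.

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/mdefov.R run --out demo --seed 1
Rscript inst/cli/mdefov.R stitch --manifest demo/manifest.csv --plane 3 \
        --out stitched_z3.tsv
```

## Layout

* `R/optics.R` — field/config types, angular-spectrum kernel, propagation
* `R/simulate.R` — bar targets, phantoms, hologram and scan simulation
* `R/stitch.R` — topology, ROI matching, shift voting, alignment, blending
* `R/retrieve.R` — multi-depth stack, amplitude constraint, retrieval loop
* `R/analyze.R` — reconstruction, fringe contrast, system formulas
* `R/io.R`, `R/pipeline.R` — formats, config, manifest, pipeline driver
* `vignettes/mdefov-methods.Rmd` — models, assumptions, parameter choices
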
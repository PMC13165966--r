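---
title: "Methods: extended-FOV lensless holography with multi-depth phase retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extended-FOV lensless holography with multi-depth phase retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models the package implements, the assumptions
behind them, and the choices made where the design was genuinely open. It
states no empirical number that the test suite or the acceptance script
does not itself compute.

## 1. Physical model

A thin sample is modelled as a complex transmission map `t(x, y)` under
unit plane-wave illumination; the field leaving the sample is `t` itself.
Free-space propagation over a distance `dz` is the exact scalar angular
spectrum method (ASM): multiply the 2-D spectrum by

```
H(f_x, f_y; dz) = exp(i 2 pi dz sqrt(1/lambda^2 - f_x^2 - f_y^2))
```

for propagating frequencies (`f_x^2 + f_y^2 < 1/lambda^2`) and zero on the
evanescent domain. This choice (over a Fresnel kernel) is exact at any
numerical aperture the sampling supports, is unitary on the propagating
support, and satisfies `H(dz) H(-dz) = 1` — the invariants the test suite
checks at 1e-10.

**Sampling validity.** The plain kernel is alias-free only for
`|dz| <= N p^2 / lambda` (`N` the smaller image side, `p` the pitch). The
reference bench geometry (z around 114–118 mm at p = 2 um) violates this
badly at full tile size, and even the desk-scale test geometry (z = 4–5 mm
at 256–486 px) exceeds it by a factor of a few. `propagate()` therefore
defaults to `band_limited = "auto"`: beyond the bound it applies the
band-limited transfer function (per-axis local-frequency cutoff
`f_lim = 1 / (lambda sqrt((2 dz df)^2 + 1))`). The physical reading is a
finite effective NA: a round trip through the band-limited kernel is a
low-pass projection, not the identity, which is why sharp bar edges ring
in reconstructions at these distances. `"off"` keeps the plain kernel and
warns instead.

**Amplitude vs intensity.** Recorded holograms are treated as *amplitude*
(`|U|`). The simulator emits amplitude; the reader's
`as = "intensity"` flag applies a square root on load so data calibrated
as `|U|^2` is covered too. The recording convention of a real sensor is
left to the user because the two conventions differ only by that square
root at the I/O boundary.

**Units.** SI metres everywhere internally; human-facing files use
nm/um/mm and are converted on ingest. Arrays are indexed (row, col) with
row = +y downward; frequency grids put the zero frequency at the array
origin, matching `stats::fft()`.

## 2. Synthetic forward model (what a green test establishes)

`simulate_scan()` propagates the full object *once* per depth and crops
each tile at its stage offset. This is physically equivalent to shifting
the sample under fixed plane-wave illumination, and it guarantees exactly
the property pairwise registration relies on: adjacent tiles agree
*bitwise* on their geometric overlap when noiseless. The manifest records
the ground-truth inter-tile shift `step / pitch` for test oracles.

The desk-scale stated world (`desk_config()`): 256 px tiles, 2 um pitch,
632.8 nm, five planes from 4 mm with 0.25 mm spacing, a 3 x 3 serpentine
scan with 0.23 mm steps (115 px, about 55% overlap). These values scale
the bench geometry (3552 px, 114 mm, 1 mm spacing, 7 x 7, 3 mm steps,
57.7% overlap) down to something a laptop simulates in seconds; the bench
geometry remains expressible through the same config with band-limited
propagation.

What the generator does *not* emulate: sensor MTF and pixel crosstalk,
illumination non-uniformity (beyond an optional vignette hook), stage
positioning error (stage steps are exact integer pixels), shot noise
(noise is additive Gaussian on amplitude, clipped at zero; a Poisson
variant would be a straightforward extension). A green stitching test
therefore establishes the correctness of the registration/blending
*machinery*, not robustness to optical flat-field error; a green retrieval
test establishes convergence of the projection loop on consistent data,
not performance under detector noise (which the noise knob lets you probe
separately). Periodic FFT boundaries also mean edge tiles contain wrapped
diffraction — consistent between simulation and oracle, but not physical.

Noise levels are free parameters (the reference system's detector noise is
not quantified); the defaults are noiseless because the acceptance
properties are exactness properties.

## 3. Stitching

The per-plane driver follows four stages.

* **Topology** from stage coordinates: all 4-neighbour pairs of the
  rows x cols lattice.
* **Overlap ROIs**: the theoretical overlap strip widened by a 10% search
  margin (default, configurable) on the free edge, clamped to the tile;
  equal sizes on both tiles.
* **Matching**: pluggable. The default `match_patches_ncc()` takes a grid
  of 64 px templates from ROI A and locates each in ROI B by fast
  normalized cross-correlation (FFT cross-correlation over integral-image
  local statistics). NCC was chosen over whitened phase correlation after
  observing the failure mode of the latter on this data class: defocused
  holograms of sparse objects are smooth and locally self-similar, and
  spectral whitening lets a small-displacement pseudo-peak beat the true
  alignment; NCC strongly prefers the exact-copy alignment (peak 1.0 on
  noiseless overlaps). Phase correlation remains available
  (`match_patches_phasecorr()`) as a faster alternative for fringe-rich
  content. A dense learned matcher can be dropped in as any function
  returning the same match-set contract.
* **Shift statistics**: per-correspondence displacement vectors pass a
  median gate (outlier radius `max(3 MAD, 5 px)` — the 5 px floor keeps
  the gate meaningful when MAD is 0 on clean data), then a 2-D histogram
  vote with 1 px bins; ties break toward the median. Templates that
  straddle the edge of the true overlap produce systematic outliers — this
  is expected and is precisely what the gate + vote absorb.
* **Global alignment**: pair constraints `pos_b - pos_a = (dy, dx)` are
  solved by least squares per axis with the upper-left tile anchored at
  (0, 0), then rounded to integers. Least squares (rather than a single
  chain of compositions) reconciles the redundant loops of an n x m grid;
  on consistent shifts it reproduces them exactly.
* **Blending**: `P = sum(P_i W_i) / sum(W_i)` with a separable linear
  feather `w(i) = min(i, n + 1 - i, plateau) / plateau` (plateau 32 px).
  The ramp starts one step above zero at the edge pixel so single-coverage
  regions never divide by zero; where exactly one tile contributes, the
  tile's pixels are copied through bit-for-bit rather than multiplied and
  divided by the same weight (guards a 1-ulp wobble). Tiles are blended in
  the units they carry (amplitude, in this pipeline).
* **Auto-crop**: the largest axis-aligned rectangle of full coverage
  (maximal rectangle over the binary coverage mask, per-row histogram +
  stack). The reference plane's crop bounds are reused for all other
  planes so the multi-depth stack stays pixel-co-registered.

Integer-pixel alignment only: the stage step is an integer multiple of the
pitch in both the bench and the simulator, so subpixel refinement is out
of scope in this version.

If a pair's matching support (winning votes / all correspondences) falls
below 0.2, the driver falls back to the manifest-derived nominal shift
with a warning — stage coordinates are trustworthy to a few pixels, and a
wrong confident match is worse than a nominal one.

## 4. Multi-depth phase retrieval

Given K co-registered amplitude holograms at increasing distances, the
loop initialises the field at the reference plane r (the middle plane by
default) with the measured amplitude and zero phase, and each iteration
sweeps `r -> r+1 -> ... -> K -> K-1 -> ... -> 1 -> 2 -> ... -> r`,
propagating by ASM between consecutive planes and replacing the modulus by
the measured amplitude at every visited plane (phase retained; pixels with
exactly zero field get phase 0 by convention). The full visiting order
among the planes is not pinned down by the reference description beyond
the first step; the symmetric down-up sweep was chosen so every plane
constrains the field once per pass (interior planes twice), and the
turnaround planes are constrained once per visit. Convergence is measured
*at the reference plane only*: after each sweep, the RMSE between the
measured reference amplitude and the modulus of the returning field, both
first normalized to unit maximum (normalization by the per-image maximum —
the convention preserves the zero background of amplitude images), and its
difference `dRMSE_M = RMSE_M - RMSE_(M-1)`. The loop stops at the
iteration cap (10 by default, matching the reference practice) or when
`|dRMSE| < tol` (1e-6), whichever first. The returned field is
`H_r exp(i phi_f)`: measured amplitude, retrieved phase. There is no
randomness anywhere; runs are bitwise reproducible.

Two facts the tests pin down: a stack generated from a single true field
has that field as a fixed point of one sweep (to 1e-8), and on the
noiseless desk-scale world `|dRMSE|` falls below 1e-4 within the 10-sweep
default.

## 5. Analysis and the resolution decision

Object-plane reconstruction is back-propagation of the retrieved field by
`-z_ref`. Resolution is quantified on three-bar chart elements by a line
profile across the bars: light 3-sample smoothing, plateau-aware local
extrema, then the three-bar geometry selects the features — the 3 deepest
troughs are the bars, the 2 highest peaks strictly between the outer bars
are the gaps — and the Michelson contrast
`(I_max - I_min) / (I_max + I_min)` of their mean levels is reported.
Restricting to the geometric features (rather than averaging all detected
extrema) keeps background ripple from diluting both means. Fewer features
than the geometry demands raise an error rather than being padded. A
constant profile is reported as contrast 0, not resolved (degenerate, not
an error). Contrast is computed on amplitude images by default; passing an
intensity image changes only the numbers, not the machinery, and the
MTF10-style decision `resolved <=> contrast >= 0.10` treats the boundary
as resolved (a documented convention; the threshold marks "near the
limit").

One expectation worth flagging: on this synthetic world, Michelson
contrast is *not* monotone from coarse to fine elements in the MD-EFOV
reconstruction — wide bars of the coarsest element trap residual
low-frequency twin background inside the bars, while the band-limit
ringing at fine bars sharpens their gaps. The properties that do hold, and
are tested, are the orderings that carry the scientific claim: per-element
contrast of the multi-depth reconstruction is at least that of the
single-plane back-propagation, and the set of resolved elements is at
least as fine.

The closed-form system parameters — theoretical resolution
`lambda sqrt(4 z^2 + L^2) / (2 L)`, effective NA
`(L/2)/sqrt(z^2 + (L/2)^2)`, depth of field `lambda / NA^2`, overlap ratio
`1 - step/L`, area gain `(L_s/L_1)^2` — are pure arithmetic on the
geometry and are what the acceptance targets exercise against the bench's
printed values.

## 6. Numerical choices and degenerate inputs

* Tolerances: propagation invariants at 1e-10 (double-precision FFT round
  trips); stitching oracle at 1e-6 RMS (exact modulo blending arithmetic);
  retrieval fixed point at 1e-8; contrast closed forms at 1%.
* Normalization dialect: division by the maximum, chosen over min-max
  because it preserves zero backgrounds; all-zero images are an error.
* Zero-amplitude pixels in the constraint step take phase 0 (arbitrary but
  fixed).
* `dRMSE[1]` is NA (no predecessor), and the stopping rule only consults
  `|dRMSE|` from the second iteration on.
* Histogram vote ties break toward the median estimate; equidistant ties
  fall back to first-found (deterministic given input order).
* Degenerate matching inputs (constant ROIs) yield an explicit empty match
  set; the caller decides the nominal-shift fallback.

## 7. Known limitations

* Pure translation model; no rotation/scale registration (the stage
  geometry justifies this, a tilted sensor would not be handled).
* Integer-pixel registration; no subpixel refinement or pixel
  super-resolution.
* No flat-field correction beyond feathered blending.
* Band-limited propagation trades wrap-around artifacts for a reduced
  effective NA; quantitative contrast at distances far beyond the sampling
  bound reflects that filter as much as the optics.
* Multi-wavelength retrieval, support/positivity priors, and learned
  matchers or retrieval networks are out of scope; the matcher interface
  is the intended extension point.
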
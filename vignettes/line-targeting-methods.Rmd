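---
title: "Selecting, planning and validating a line-scanning fMRI target"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting, planning and validating a line-scanning fMRI target}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linetarget)
```

## The problem

Line-scanning fMRI trades spatial coverage for resolution: by omitting the
phase-encoding gradient and suppressing signal outside a narrow band with
outer-volume-suppression (OVS) pulses, a single line of cortex is sampled
every ~100 ms at ~250 um along the line. That resolution is only useful if
the line is (1) placed on the neural population the experiment is about and
(2) oriented perpendicular to the cortical sheet, so that each voxel along
the line samples one cortical depth rather than a mixture. `linetarget`
implements the offline workflow around such an acquisition: target
selection from functional and anatomical criteria, conversion of the target
into console-ready placement parameters, cleaning of the acquired line time
series, population receptive field (pRF) modelling, and quantitative
validation of how well the line hit its target.

Everything runs end to end on synthetic data with known ground truth; no
scanner, surface-reconstruction or registration software is required to
exercise or test the package.

## Target selection

A target vertex is selected on a cortical surface mesh from three criteria,
applied in `eligible_vertices()` and `select_target_vertex()`:

* **Region**: the search is restricted to a named label, typically `"V1"`.
* **pRF criteria**: eccentricity of the vertex's fitted pRF center below a
  threshold (default 3 degrees of visual angle) and variance explained
  above a subject-dependent threshold (commonly 0.35–0.7). The threshold is
  an input, never auto-selected.
* **Flatness**: among eligible vertices, the one with minimal *absolute*
  mean curvature wins. We interpret "minimal curvature" as minimal |H|
  because flat cortex is what makes a perpendicular line placement
  meaningful; a signed minimum would prefer the bottoms of deep sulci.
  `use_abs = FALSE` restores the signed criterion for users who want it.

Mean curvature is computed with the cotangent Laplace–Beltrami operator
with mixed Voronoi areas; vertex normals are angle-weighted averages of
incident face normals. Both converge to analytic values on spheres,
cylinders and sinusoidal sheets (tested at 5% and 1 degree respectively).
Boundary vertices have no defined curvature (`NaN`), and degenerate
one-rings fall back to uniform Laplacian weights. A smoothing knob is *not*
applied by default: curvature is used only through an argmin, which is
insensitive to the monotone distortions smoothing introduces on clean
meshes.

## From vertex to console parameters

The target's coordinate lives in the surface (TKR) frame and is converted
to scanner RAS via the anatomical volume's two voxel-to-world matrices
(`tkr_to_scanner()`). Between-session registrations are applied to the
coordinate as full homogeneous transforms and to the normal through the
rotation block only (`map_target_between_sessions()`); the mapping
direction of a registration file is always declared by the caller, never
guessed, because the forward/inverse convention is tool-specific. ANTs/ITK
transform files are LPS and are converted to RAS on read; every transform
carries source and destination frame tags, and composing mismatched frames
is an error rather than silent wrong geometry.

The line direction is the vertex normal. `plan_line()` reports:

* the angles between the (unoriented) line and the three cardinal axes,
  `acos(|n_i|)` folded into [0°, 90°] — a physical line has no polarity,
  so the folded angle is also what the coronal/sagittal rule uses;
* the base slice orientation: coronal unless the angle to the left–right
  axis exceeds 45° (then sagittal); exactly 45° stays coronal;
* two angulation rotations about the base slice's in-plane axes that take
  the slice's frequency-encoding axis onto the line. The console-facing
  quantities are the cardinal angles and the base-orientation rule; the
  two-angle decomposition itself is this package's parameterization and is
  validated purely by its round-trip property (direction reconstructed
  from `(orientation, angulation)` within 1e-6 rad on randomized normals,
  with the direction never leaving the chosen slice plane by more than
  45°).

The nominal line — the unsuppressed band between the OVS pulses — is a
binary mask on the slice grid: `round(gap / phase_resolution)` central
voxels along the phase axis at full frequency-axis extent (16 voxels for
the default 4 mm gap at 0.25 mm). `round()` is R's round-half-to-even;
when the band cannot be centered exactly the extra voxel goes on the
lower-index side. Both choices are arbitrary but fixed and tested.
Back-projecting this mask onto the surface (`vertices_in_volume_mask()`)
is the anatomical validation: the target vertex must fall inside it.

## The signal chain

`preprocess_line_series()` runs a fixed-order chain; the order is
structural (recorded in the result's `chain` descriptor) and not
user-configurable:

1. **SVD denoising** per coil and echo on the position x time matrix:
   singular values from the scree elbow onward are zeroed. The elbow is
   the point of maximal perpendicular distance to the chord joining the
   first and last singular values; ties break toward retaining more
   components, and a spectrum with no interior deviation retains
   everything. Complex (k-space) and magnitude data are handled
   identically.
2. **Coil combination**: `sqrt(sum_c w_c |x_c|^2)` with
   `w_c = (tSNR_c |s_c|)^2`, normalized to sum 1 per position so the
   uniform case reduces to the root mean square (set
   `normalize = FALSE` for the unnormalized variant). tSNR defaults to
   being computed from the denoised data; this ordering is a choice, since
   either order is defensible.
3. **Echo combination**: root sum of squares over echoes.
4. **Drift removal**: regression against DCT-II basis functions below
   0.01 Hz (constant term excluded, so temporal means are preserved).
5. **aCompCor tailored to line data**: PCA on the standardized WM/CSF
   time courses inside the nominal line mask; the first 5 component scores
   (configurable) are high-pass filtered above 0.18 Hz — slightly below
   the respiratory frequency, so task-band power is not regressed out —
   and then removed from every position.
6. **Percent signal change** against the mean of the empty-screen frames
   when a design is supplied, else the full-series mean.
7. **Savitzky–Golay smoothing**, window 11 samples, order 3, with edges
   handled by polynomial fits of the terminal windows.
8. **Iteration averaging** across repeats of the stimulus sequence.

Percent signal change precedes smoothing; the two low-pass decisions
(smooth-then-average) mirror the order the steps are usually described in
for this kind of acquisition.

## pRF model and fitting

The pRF is an isotropic 2-D Gaussian `(x0, y0, sigma)` in visual degrees.
The predicted response is the stimulus–pRF dot product per frame convolved
with a double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, sampled at
the design frame interval and pluggable — the line TR of 0.105 s versus a
whole-brain TR of 1.5 s changes only the kernel sampling). Convolution is
causal, zero-padded, truncated at the series end.

Fitting is two-stage: an exhaustive coarse grid (defaults: 13 steps over
± half the grid extent for the centers, 6 log-spaced sigmas from 0.1
upward) with amplitude and baseline solved per candidate in closed form,
then bounded L-BFGS-B refinement of the three spatial parameters. Grid
ties break by smallest residual, then smallest sigma, then lexicographic
center. Cross-session comparison uses `crossval_r2()`: amplitude and
intercept are refit by OLS to a fixed prediction shape, so cvR² equals
the squared Pearson correlation and is non-negative — chosen so that
negative-amplitude refits are not penalized asymmetrically. The
spatially-invariant null model (`block_null_prediction()`) is the
"any stimulus on screen" indicator convolved with the HRF.

## The synthetic generators

The generators define the conditions every recovery test runs under:

* `make_folded_sheet()`: a sheet `z = a sin(2 pi x / lambda)` (defaults
  a = 2 mm, lambda = 20 mm — a gyrus-like fold) with analytic normals and
  curvature attached, and a central `"V1"` band.
* `make_retinotopy()`: eccentricity linear along one surface axis, polar
  angle along the other, pRF size growing with eccentricity, seeded noise
  on variance explained — a smooth caricature of V1's retinotopy.
* `simulate_line_session()`: per-position BOLD = the ground-truth pRF
  prediction normalized to unit peak, times a depth factor interpolating
  2 (superficial) to 1 (deep) — the simplest shape consistent with the
  roughly two-fold superficial amplification seen in depth-resolved
  acquisitions. Added to it: a linear drift (0.02 units/s), cardiac
  (1.0 Hz) and respiratory (0.3 Hz) sinusoids shared across all tissue,
  and white thermal noise per coil sample. WM and CSF positions carry
  noise and physiology but no task. Coils see smooth sensitivity
  profiles; echoes scale as `exp(-TE / T2*)` with T2* = 28 ms (typical
  gray matter at 7 T; only the relative weighting matters). Because the
  task amplitude is unit-peak, `bold_amp / thermal_sd` *is* the thermal
  SNR; the default 1 / 0.2 = 5.
* `make_transform_jitter()`: rigid transforms with centered per-axis
  rotation/translation noise, emulating repeated-registration dispersion
  and run-to-run motion.

Every generator is a pure function of its seed (bit-reproducible, RNG
state restored afterwards). What the generators do **not** emulate:
imperfect OVS contamination from outside the line, non-rigid motion,
vascular depth profiles, T1-related transients, or spatially correlated
thermal noise. Passing recovery tests therefore demonstrates the
correctness and internal consistency of the chain, not its performance on
any particular scanner's data.

## Numerical choices and degenerate inputs

* Frames with no stimulus are exact zeros in the design; a bar wider than
  the grid is an error.
* An all-constant time series fits with `r2 = 0` and is flagged
  unreliable; zero-variance data give `cvR² = NaN` with a warning, a
  zero-variance prediction gives 0.
* In a noise-free simulation the chain is run without the SVD step: the
  data are exactly low rank, there is no noise floor, and the scree elbow
  would fall before the task component and delete it. tSNR weights are
  uniform there for the same reason (tSNR is undefined on constant
  series). This is the one condition-dependent switch in the validation
  runs.
* With fewer than three singular values the elbow rule degenerates to
  "retain the first component".
* aCompCor errors informatively when no WM/CSF positions exist, and warns
  (identity) when their time courses are all constant.

## Problem sizes used in the shipped validation

The end-to-end recovery (`synthetic_recovery_run()`) uses a 60 x 16 vertex
sheet at 0.5 mm spacing, a 2-orientation x 2-direction x 2-width bar
paradigm at 0.105 s frames (~4.7 min, 2708 frames, 25 x 25 aperture
pixels), 4 coils x 3 echoes, and 32 line positions (8 CSF, 16 GM, 8 WM).
Twenty seeds at thermal SNR 5 give a median pRF center error of ~0.02
degrees, and in the noise-free condition the matched vertex lies within
one vertex spacing of the target — far inside the
`sqrt(4^2 + 2.5^2) / 2 ≈ 2.36 mm` half-diagonal of the nominal line
footprint, the scale at which a match still counts as "the line sampled
what it aimed at".

## Known limitations

* Geodesics are graph-Dijkstra distances along mesh edges, an upper bound
  on exact polyhedral geodesics; the overestimate is bounded by mesh
  anisotropy and negligible at mm scales on the meshes used here.
* Only the isotropic Gaussian pRF is implemented (no
  difference-of-Gaussians, compressive or normalization variants), and
  the HRF is fixed rather than estimated.
* The mid-gray target coordinate is the given mesh's vertex; if separate
  white and pial surfaces are available the caller should average them
  before selection.
* Scanner-side concerns — pulse sequences, OVS physics, registration
  estimation, real-time operation — are out of scope; transforms and
  surfaces are consumed as files.
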
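---
title: "Surrogate-driven respiratory motion modelling and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-driven respiratory motion modelling and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Abdominal tumours move with breathing. Respiratory-correlated 4D MRI
(4DMRI) resolves that motion into a handful of phase-binned 3D volumes, but
it averages many breathing cycles and cannot show cycle-to-cycle or
day-to-day variation; time-resolved 2D cine-MRI shows every cycle but only
on one plane at a time. Global respiratory motion models bridge the two: a
motion model built from a 4DMRI is driven at estimation time by a
low-dimensional surrogate signal extracted from the cine frames, producing
a full time-resolved 3D volume for any observed respiratory state.

`respmotion` implements such a model together with the imaging study design
used to validate it: two sessions on different days, each with two 4DMRIs
(R1, R2) and one interleaved sagittal/coronal cine series, giving seven
evaluation scenarios that separate intra-fraction (within-session),
cycle-to-cycle, and inter-fraction (between-session) variability. Because
no patient data ship with the package, a synthetic abdominal breathing
phantom with exact ground-truth deformation plays the role of the study
data; every validation layer can therefore be checked against truth, not
only against itself.

## The motion model

The model is the classic DVF-library construction:

1. **Building.** Bin 0 of the building 4DMRI (end-exhale, the most stable
   state) is the reference. Deformable registration of the reference onto
   every other bin yields a library of backward-mapping deformation vector
   fields (DVFs) $u_k$, one per bin, with $u_0 \equiv 0$ by construction.
2. **Surrogate normalisation.** A high-contrast structure (diaphragm
   analogue) is tracked on the sagittal slice of each bin; the largest SI
   excursion across bins, `building_peak_mm`, defines amplitude 1.
3. **Estimation.** A respiratory state is the pair (phase $\varphi \in
   [0, n_{\text{bins}})$, amplitude $a \ge 0$). With $k = \lfloor \varphi
   \rfloor$ and $w = \varphi - k$,
   $\hat u(\varphi, a) = a\,\big[(1-w)\,u_k + w\,u_{(k+1) \bmod n}\big]$,
   and the estimated volume is the reference warped by $\hat u$.
4. **Baseline update.** For inter-fraction use, the reference is first
   registered to the end-exhale volume of the testing day; the resulting
   baseline DVF warps the reference once, and respiratory DVFs are applied
   to this updated reference (two sequential warps).

Assumptions worth stating: breathing motion is assumed to scale linearly
and uniformly with breath depth (one global amplitude multiplies the whole
interpolated field); phase interpolation is piecewise-linear on the
circular phase coordinate — the simplest scheme consistent with a
"interpolate then scale" model, with spline interpolation an obvious
extension; and the respiratory library is *not* re-expressed in the
updated reference frame after a baseline update. The last point is a
deliberate approximation: it keeps the library in the frame it was
measured in, at the cost of a first-order error where the baseline
deformation gradient is large — which is exactly where the inter-fraction
scenarios report their higher errors.

## Deformable registration

The registration is a multiresolution free-form method of the same family
as B-spline/FFD algorithms: a dense displacement field refined from coarse
to fine grids (3 levels by default, downsampling by two per level where
the axis permits), driven by mean-squared intensity difference forces
(appropriate for same-modality MRI; a z-normalised variant stands in for
normalised cross-correlation via `metric = "ncc"`). Regularisation is
Gaussian: each update is smoothed at the control scale
(`control_spacing_mm`, default 10 mm at the finest level, doubling per
coarser level) and the accumulated field receives a light diffusion pass.
This plays the role of a stiffness/bending penalty, and in practice keeps
every estimated deformation fold-free (the Jacobian-plausibility analysis
below verifies, rather than assumes, this). The optimisation is
deterministic — no random initialisation — so registrations are
bit-reproducible.

Numerical conventions, fixed package-wide:

* **Backward (pull) mapping.** A field $u$ on the fixed grid warps a
  moving image as $I'(x) = I(x + u(x))$; one interpolation pass, no
  scattering.
* **Geometry.** Axis-aligned grids only, axes ordered (AP, SI, RL), world
  coordinate = origin + 0-based index × spacing, all user-facing lengths
  in mm. Out-of-domain samples clamp to the edge (the phantom's DVFs are
  compactly supported, so this only touches background).
* **Jacobian determinants** use central differences in physical mm,
  one-sided at boundaries; the identity map gives exactly 1, affine fields
  match the closed-form determinant to numerical precision.

## The synthetic breathing phantom

The phantom is an analytic scene — a liver slab under a curved
high-contrast diaphragm dome, a spherical tumour, ~30 Gaussian-blob
vessels for texture, darker lung above and soft tissue below — deformed by
a separable motion model: displacement = (smooth spatial envelope) ×
(waveform value × per-cycle amplitude) × (unit vector with SI dominant and
an AP component `ap_fraction` times the SI one). Because volumes are
sampled analytically at deformed coordinates, every generated state is
*exactly* the reference warped by the stored ground-truth DVF; no
numerical simulation error separates data from truth.

Defaults mirror a realistic abdominal protocol: 96 × 96 × 25 voxels at
1.33 × 1.33 × 5 mm (a 12.5 cm sagittal slab), 8 phase bins, cine frames
every 230 ms for 30 s, mean period 4 s, 12 mm peak SI diaphragm excursion,
AP fraction 0.3. Free breathing dwells at exhale, so the waveform is a
time-warped $\sin^4$ with the peak at elapsed-fraction `1 −
exhale_fraction` (default 0.6). Variability knobs, chosen once as
field-realistic values: per-cycle amplitude multipliers N(1, 0.1)
truncated positive, per-cycle periods N(4 s, 0.3 s), a 3 mm SI
inter-session baseline shift by default, additive Gaussian intensity noise
at 2% of the dynamic range (a magnitude-image approximation at moderate
SNR). Binned 4D volumes are the continuous deformation at bin-centre
phases with per-bin amplitude multipliers shrunk by √6, emulating the ~6
cycles a retrospective sorting mixes into each bin; phase (not amplitude)
binning was chosen, with bin 0 at end-exhale. An optional session-2 local
change region (altered intensity plus an independent displacement bump)
mimics bowel-filling changes that registration cannot fully compensate.

Two generator choices deserve their rationale. First, the envelope's
cosine ramps have peak slope (π/2)/width, so ramp widths scale with
`si_amplitude_mm` (factor 2.4); this guarantees the ground-truth
deformation itself never folds — a phantom whose truth violates the
plausibility criterion the package tests for would be self-defeating.
Second, the envelope is anatomy-following between sessions (shifted with
the baseline), so session-2 truth DVFs remain exact in session-2's frame.

What the phantom does **not** emulate: MR physics (no bSSFP banding,
susceptibility, or slice-profile effects), retrospective sorting artefacts,
oblique geometry, hysteresis (inhale and exhale follow the same spatial
path, distinguished only by phase), and spatially incoherent organ motion.
Passing tests therefore demonstrate that the pipeline is correct and
self-consistent under controlled conditions; they do not certify accuracy
on patient data, where registration error against unknown truth is the
dominant uncertainty.

## Surrogate signal

The surrogate is the SI displacement of a diaphragm-analogue edge, tracked
on sagittal cine frames by exhaustive normalised cross-correlation within
a bounded window (integer argmax, smallest displacement on ties, parabolic
sub-pixel refinement; matches below a score threshold are flagged and
excluded — if no frame beyond the first matches, the extraction fails the
way an unusable clinical surrogate does, and the affected scenario is
recorded as skipped rather than failing the study). The exact
phase/amplitude procedure is a package design: end-exhale troughs are
local minima with prominence ≥ 20% of the peak-to-peak and separation ≥
half the mean period; amplitude is the trough-baseline-corrected
displacement divided by `building_peak_mm`, clipped at 2 to cap
extrapolation; phase is the elapsed fraction of the current trough-to-
trough cycle mapped linearly to $[0, n_{\text{bins}})$, which assigns
distinct phases to inhale and exhale samples of equal depth and agrees
with the equal-phase-increment convention of the building bins. Coronal
frames are deliberately not used for the surrogate (they serve the 2D
validation); sign ambiguity of the tracked displacement is resolved by
making the dominant excursion from the signal median positive, since free
breathing dwells at end-exhale.

## Validation layers

* **DIR validation** compares registrations — the end-inhale library
  field per session and the inter-session baseline field — by detecting
  3D scale-space keypoints (difference-of-Gaussian extrema over space and
  scale, contrast and Hessian-ratio rejection, octant gradient-histogram
  descriptors; no rotation invariance, which only adds noise at these
  small deformations) in the fixed and warped-moving volumes, matching
  them with a ratio and mutual-consistency test, and reporting the median
  (IQR) of matched 3D distances. On phantom data the voxelwise error
  against the truth field is reported alongside, and reports label which
  route produced which number.
* **3D validation** estimates each testing bin from its surrogate sample
  and reports keypoint distances (estimate vs truth volume), tumour
  centre-of-mass distances (reference mask warped by the estimated DVF
  with nearest-neighbour interpolation — grid-native and unambiguous —
  vs the truth bin mask), and the truth-correspondence error; range-of-
  motion rows (end-inhale vs reference) quantify the motion the model must
  compensate, so every error can be read against it.
* **2D validation** estimates a 3D volume per cine frame, extracts the
  co-located slice, and tracks the frame-0 landmark templates on both the
  cine frame and the estimated slice (template matching only; keypoint
  detection is kept to 3D): `cine_error` is the in-plane distance between
  the two tracked positions, `cine_motion` the maximum landmark
  displacement from the end-exhale reference slice, `fourD_motion` the
  landmark displacement range across the building bins' slices.
* **Jacobian plausibility** closes the loop: the fraction of voxels with
  non-negative Jacobian determinant is computed for *every* estimated DVF
  of every scenario, and the suite reports the minimum.

All summaries use median and IQR with quartiles by linear interpolation
between order statistics (type-7), fixed so that reported numbers are
bit-reproducible.

## Problem sizes and runtime

The default study — two sessions × (two 8-bin 4DMRIs + 130-frame cine) on
the 96 × 96 × 25 grid — builds two motion models (14 deformable
registrations) plus one baseline registration and runs all seven scenarios
in roughly six minutes on one CPU. Unit tests exercise the same code paths
on a 48 × 48 × 13, 4-bin study, which keeps a full test run near one
minute apart from the full-size acceptance checks. These sizes are the
package's chosen desk-scale defaults; everything scales to larger grids at
the obvious cost.

## Known limitations

The registration is a single intensity-driven method; no multi-metric or
discontinuity-preserving options are provided. The surrogate is a single
tracked structure — no multi-structure fusion or external surrogates. The
model itself is the global interpolate-and-scale construction: it cannot
represent cycle-to-cycle *shape* variation (only depth), hysteresis, or
spatially varying amplitude, and inherits every bias of the DIR. The
2D-validation landmark on the diaphragm dome illustrates a generic
template-matching caveat: on a smooth edge the template can slide along
the edge direction, inflating apparent motion on planes where the edge is
flat; blob-like landmarks (vessels, tumour) do not suffer from this.
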
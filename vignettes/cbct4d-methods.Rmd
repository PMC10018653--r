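---
title: "Simulated rapid thoracic CBCT with motion-compensated FDK: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated rapid thoracic CBCT with motion-compensated FDK: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Image-guided lung radiotherapy wants a respiratory-resolved (4D) cone-beam CT
before each treatment, but a respiratory-correlated reconstruction needs a
slow scan (minutes) so that every phase bin accumulates enough gantry angles.
Fast ring-gantry systems acquire a full 3D scan in under 20 s — too fast for
respiratory correlation (only 4–5 breathing cycles fit in the scan), yet the
projection data contain all respiratory phases. Motion-compensated FDK
(MCFDK) reconstructs each phase from *all* projections by warping
phase-binned reconstructions into a common reference phase with deformation
vector fields (DVFs) derived from a prior planning 4DCT.

`cbct4d` is a self-contained simulation of that comparison: it generates a
10-phase digital thorax, simulates a conventional (1320 projections / 240 s,
16.5 breaths/min) and a rapid (491 projections / 16.6 s, 16.1 breaths/min)
full-fan acquisition over a 200° arc (source–isocenter 1000 mm,
source–detector 1536 mm), reconstructs four arms — conventional 4DFDK, rapid
3DFDK, rapid 4DFDK, rapid MCFDK — and scores them against the ground-truth
4DCT with CNR, tissue interface width (TIW), RMSE and SSIM, per patient and
over a seeded cohort with paired t-tests. The conventional breathing rate
makes the phase allocation exact: 240 s at 16.5 breaths/min is 66 cycles, 20
projections per cycle, hence exactly 132 projections in each of the 10 bins.

# The digital thorax and its motion model

The phantom is parametric and analytic: every structure is an ellipsoid or
sphere with a linear attenuation (mm⁻¹), voxelized by innermost-structure
membership at voxel centers (`supersample = 2` averages a 2×2×2 sub-voxel
grid instead, producing partial-volume edges like a real CT; the study
pipeline uses this). Attenuations are water-referenced so that
`to_hu()` gives lung ≈ −800 HU, soft tissue 0 HU, heart +50 HU, liver
+75 HU, tumor +30 HU.

Anatomy: a torso column (a body ellipsoid strongly elongated along z, so the
body extends past the imaged field of view like a real torso — there are no
horizontal body–air edges in the volume); two lungs; a heart/mediastinum
ellipsoid carved between them; a liver under the right lung and a
stomach/spleen region under the left, each bounded above by a
superior–inferiorly translating diaphragm plane; a stomach gas bubble; a
spherical tumor in the left lung; and a dozen vessel/nodule blobs inside the
lungs, placed deterministically from the seed and kept clear of the metric
ROIs.

All motion follows one smooth cyclic waveform

$$w(p) = \tfrac{1}{2}\left(1 - \cos 2\pi (p - p_0)\right),$$

zero at peak inhale (maximum lung volume, the reference phase) and one at
peak exhale. Moving parts and defaults, chosen from free-breathing
literature values and drawn per patient in cohort mode:

| structure | default excursion | cohort range |
|---|---|---|
| both hemidiaphragms (SI) | 15 mm | 10–20 mm |
| tumor (3D) | (0, 2, 10) mm | SI 5–15 mm |
| heart (SI, with small AP) | 6 mm | 4–10 mm |
| gas bubble | rides the left dome | — |
| lung density (ventilation) | +60 HU inhale→exhale | — |

The ventilation term models the air-content change of the parenchyma over
the cycle; it is a density change, not a displacement, so no DVF can
compensate it — a deliberate, physiological limit on how well MCFDK can do.

The phantom's DVFs are analytic: each moving structure contributes a
displacement equal to its own motion inside its support, blended smoothly
(raised-cosine windows) to zero outside, with the tumor and heart overriding
the diaphragm field inside their supports so every structure follows its own
trajectory exactly. Window widths are chosen so the displacement Jacobian
stays below one at the largest amplitudes, which guarantees the fixed-point
inversion converges. Where a smooth falloff crosses a static boundary (lung
walls, deep organ surfaces) the field is deliberately imperfect — the
analogue of registration error in a real planning-4DCT pipeline.

The planning scan is emulated by `mismatch(phantom, amplitude_scale,
drift_mm)`: the same anatomy with all motion amplitudes scaled and the whole
patient rigidly offset (different-day setup). The study draws the scale from
U(0.75, 1.25) and each drift component from U(−5, 5) mm per patient.

# Acquisition and reconstruction

The projector computes exact line integrals through the voxelized phantom by
fixed-step sampling (step = half the smallest voxel spacing) with trilinear
interpolation, after clipping each ray to the volume's bounding box.
Projections are noiseless; the simulation isolates sampling and motion
effects, which is also why CNR behaves differently here than on real data
(below). Each projection selects the phase volume whose bin matches the
respiratory phase at its timestamp — 10 discrete states, no intra-phase
interpolation, and the same respiratory signal is used for simulation and
reconstruction.

FDK follows the standard flat-panel pipeline: cosine preweighting
`sdd/√(sdd² + u² + v²)`; Parker-style short-scan weights computed for an arc
of `π + 2γ'` with `γ' = (arc − π)/2`, so the 200° arc's over-scan beyond the
minimal short scan is absorbed into the transition regions and conjugate-ray
weights sum to one (a 360° arc degenerates to flat 0.5); Ram-Lak ramp
filtering with the exact spatial-domain taps, FFT convolution zero-padded to
the next power of two above twice the row length; and voxel-driven
backprojection with the `(sid/U)²` distance weight. Weights are normalized
so a complete short scan reconstructs absolute attenuation.

Per-projection angular weights are the local half-gaps to the angular
neighbours, *clamped at the angle set's mean spacing*. For a uniform scan
this is exactly the uniform spacing. For a phase-binned subset it is a
density compensation with a missing-data convention: a projection bordering
a large unmeasured wedge (the sparse rapid bins cover only 4–5 angular
clusters) must not extrapolate into the wedge, otherwise each sparse bin
degenerates into an effective two-view reconstruction and the MCFDK average
inherits those streaks. The clamp leaves conventional bins and full scans
numerically unchanged; rapid 4DFDK volumes remain (by design) badly
undersampled and are flagged. A consequence of the missing-data convention
is that sparse-bin volumes (and the MCFDK average built from them) are
attenuation-biased low by a global factor; all metrics affine-window the
reconstruction onto the ground truth first — the same device the original
evaluation uses because CBCT absolute values are unreliable — so the bias
cancels in every comparison.

The study pipeline reconstructs with a Hann apodization of the ramp
(`study_config(hann = TRUE)`, the default there; the low-level FDK functions
default to the bare ramp). Clinical FDK reconstruction apodizes, and at the
4 mm desk-scale voxels the bare ramp's streak and edge-ringing error is
large enough to bury the motion-blur differences between arms that the
study exists to measure.

MCFDK implements the warp–average–inverse-warp pipeline: 4DFDK of the rapid
scan; rigid translation registration (normalized cross-correlation, coarse
integer-voxel grid search ±15 mm then two sub-voxel grid refinements) of the
rapid 3DFDK to the planning 3DCT (mean of the planning 4DCT); conjugation of
the planning DVFs with that translation — for a pure translation this
reduces to resampling the field, `d'(x) = d(x − t)`, so a zero field stays
zero and the output remains in the treatment frame; pull-convention
trilinear warping (`out(x) = in(x + d(x))`, clamp-to-edge sampling so no
zero halos enter the body) of each phase volume to the peak-inhale
reference; equal-weight averaging; and finally the fixed-point-inverted
fields (`d⁻¹(x) ← −d(x + d⁻¹(x))`, iterated to 0.01 voxel with the
composition residual reported) map the reference volume to the other nine
phases. NCC was chosen for the rigid step because it is invariant to the
affine intensity differences between a CBCT reconstruction and a CT prior;
equal phase weights (rather than projection-count weights) follow the plain
reading of averaging warped phase volumes.

# Image-quality metrics

All metrics are computed on the HU scale within ROIs placed automatically
from the known phantom geometry (the real study drew them manually on each
patient): a contrast foreground cube in homogeneous liver (21 mm), a
background cube in homogeneous upper right lung (11 mm), a 5×5-voxel column
through the diaphragm interface with a 60 mm run, and a large thoracic
similarity box inscribed in the body cross-section and kept inside the
lateral and cone-angle field of view. At 1 mm spacing these reproduce
21³ / 11³ / 5×5×60-voxel boxes. If the diaphragm column leaves the grid the
case is flagged and CNR/TIW are non-computable (the cohort average then
skips them).

* **Affine windowing**: least-squares `a·x + b` of the reconstruction onto
  the ground truth over the subvolume (per subvolume, since the values
  being compared are the subvolume's), applied before RMSE and SSIM. It can
  only reduce RMSE.
* **CNR** `(μ_FG − μ_BG)/σ_BG`, sample standard deviation.
* **TIS/TIW**: each SI run of the interface column is min–max normalized,
  flipped if needed so intensity rises from lung to tissue, and fitted with
  a logistic `1/(1 + exp(−k(z − z₀)))` by bounded Levenberg–Marquardt
  (`0 < k ≤ 10` per voxel; deterministic initialization from the 10–90%
  crossing distance). TIS is the mean fitted *rate* k — the only reading
  consistent with `TIW = 2w·ln 9 / TIS`, which is then exactly the 10–90%
  width of the mean sigmoid in mm. Runs without an edge (dynamic range
  below a quarter of the box's, or a fit with R² < 0.5) are excluded; more
  than half excluded is an error, which the pipeline records as a
  non-computable metric.
* **RMSE** over the similarity box, after windowing.
* **SSIM**: the single global statistic over the subvolume (not a sliding
  window — the metric is printed as one formula over subvolume moments),
  with `c1 = (0.01L)²`, `c2 = (0.03L)²` and `L` the joint dynamic range of
  both subvolumes.
* **Cohort statistics**: phase-averaged metrics per patient (mean over
  computable phases), cohort medians/quartiles, and two-sided
  paired-samples t-tests between arm pairs.

# Study conditions and problem sizes

`study_preset()` fixes the scales. The physical geometry, arc, projection
counts, timing and breathing rates are identical at every preset; only the
voxel/detector pitch changes, preserving the angular and respiratory
sampling structure that the study is about:

* `"full"` — 1 mm voxels, 500×400 detector (clinical scale).
* `"desk"` — 4 mm voxels, ~84×56×88 grid, 125×100 detector. Used for the
  study runs and the acceptance script; one patient (two simulated scans,
  four reconstruction arms, evaluation) takes on the order of two minutes
  on one CPU.
* `"mini"` — 8 mm voxels, used by the unit tests (~30 s per patient).

The packaged analyses run cohorts of 3–4 desk-scale patients; cohort size
is a free parameter of `study_config()` and the summaries are medians, so
larger cohorts refine but do not change the qualitative comparisons.

# What the simulation does and does not show

The phantom reproduces the *mechanism* under study: phase-frozen
conventional 4DFDK with mild view-sharing streaks; motion blur across both
hemidiaphragms, the heart border, the bubble and the vessels in rapid
3DFDK; limited-angle collapse of rapid 4DFDK; and MCFDK's dependence on the
fidelity of its planning motion model (amplitude mismatch, setup drift,
uncompensable ventilation). On it, the package reproduces the qualitative
orderings of the real-patient study — TIW and RMSE: conventional 4DFDK <
MCFDK < rapid 3DFDK, with rapid 4DFDK unusable.

It does not emulate CT noise or texture, scatter, beam hardening, detector
lag, hysteresis (phases k and 10−k are identical by symmetry of the
waveform), or irregular breathing. The most visible consequence is CNR: in
a noiseless simulation the background standard deviation is artifact
texture only, which differs across arms by construction, so the
near-equality of CNR across arms seen on real (noisy) data does not
transfer to this phantom. The packaged acceptance checks treat that
sub-check accordingly: the CNR medians are reported, and their spread is
expected to exceed a few percent here.

Deformable registration is intentionally out of scope: planning DVFs are
analytic (or user-supplied via `read_dvf()`), and the planning-vs-truth
mismatch parameters stand in for the unreported registration accuracy of
the original workflow.
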
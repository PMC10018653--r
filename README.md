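# cbct4d

Simulation study of respiratory-resolved thoracic cone-beam CT (CBCT) on a
fast-rotating gantry: can the projection data of a **rapid 3D scan**
(491 projections in 16.6 s) support a usable **4D, motion-compensated
reconstruction**, approaching the quality of a conventional respiratory-
correlated scan (1320 projections in 240 s)?

The package is aimed at medical-physics researchers working on 4D CBCT
reconstruction. It contains the whole experiment in code — no external data:

* a parametric **4D digital thorax** (torso column, lungs, heart, liver and
  stomach under two moving hemidiaphragms, gas bubble, lung vessels, a lung
  tumor) with a smooth cyclic motion model
  `w(p) = (1 − cos 2πp)/2` and **analytic deformation vector fields**;
* a ray-driven **cone-beam projector** (full fan, 200° arc, source–isocenter
  1000 mm, source–detector 1536 mm) with the two clinical protocols;
* **FDK filtered backprojection** — cosine preweighting, Parker short-scan
  weights, Ram-Lak ramp (optional Hann), voxel-driven backprojection — as
  3DFDK, respiratory-correlated **4DFDK** (only each phase's projections),
  and **MCFDK**: 4DFDK volumes are warped to peak inhale with planning DVFs
  (rigidly re-registered to the scan), averaged, and mapped back through the
  inverted fields;
* image quality metrics: **CNR** `(μ_FG − μ_BG)/σ_BG`, **tissue interface
  width** `TIW = 2w·ln 9 / TIS` (TIS = mean fitted logistic rate across the
  5×5 diaphragm-interface runs), **RMSE** and global **SSIM** (constants
  `c1=(0.01L)²`, `c2=(0.03L)²`) after affine windowing, with phase
  averaging, cohort medians and paired t-tests.

## A worked example

One simulated patient at the desk scale (4 mm voxels, 125×100 detector;
both protocols keep their clinical projection counts and timing — about two
minutes on one CPU):

```r
library(cbct4d)
cfg <- study_config(preset = "desk", n_patients = 1, seed = 1)
rep <- run_patient(cfg, 1)
print(rep$summary, digits = 4)
```

```
          arm    cnr    tiw   rmse   ssim insufficient
1  conv_4dfdk 289.78  6.481  51.65 0.9897        FALSE
2 rapid_3dfdk 296.21 14.866  77.50 0.9758        FALSE
3 rapid_4dfdk  33.87  8.557 173.19 0.8711         TRUE
4 rapid_mcfdk 110.50  9.033  73.04 0.9791        FALSE
```

Reading it: the conventional-acquisition 4DFDK is the sharpest and most
accurate arm (diaphragm interface width 6.5 mm, RMSE 51.7 HU over the
thoracic box). The rapid 3DFDK blurs everything that moves (TIW 14.9 mm,
RMSE 77.5). MCFDK, reconstructed **from the same 16.6-s rapid scan**,
recovers most of the lost sharpness (TIW 9.0 mm, RMSE 73.0) — between the
conventional and rapid extremes, which is the study's core claim. The rapid
4DFDK arm is reconstructed from 4–5 angular clusters per phase and is
flagged `insufficient`. The contrast-to-noise ratios of the two
motion-frozen full-coverage arms agree, but MCFDK's is lower and, more
generally, CNR behaves differently in a noiseless simulation: σ_BG is
artifact texture, not image noise (see the methods vignette).

`run_cohort()` repeats this over seeded patients (varied anatomy, breathing
amplitudes, and planning-vs-truth motion mismatch), writes per-phase and
cohort CSVs, and computes paired t-tests between arms.

A thin command-line wrapper over the same function is installed as
`inst/scripts/run_study.R` (`Rscript run_study.R --config study.yaml --out dir`).

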
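# limbstat

Static link-segment analysis of sagittal human postures from 2D pose
keypoints.

`limbstat` answers a classic question of sports biomechanics: given a single
sagittal-plane snapshot of a person holding a posture, what ground reaction
forces (GRFs) and joint loads keep that posture in static equilibrium? It was
built for postures extracted with markerless pose estimators (the BODY_25
25-keypoint layout), where the only available information is keypoint pixel
coordinates plus an assumed anthropometric model — for example, stances
depicted in historical artwork, coaching photographs, or single video frames.

## The model

The body is a 2D chain of rigid segments in the sagittal plane (x along the
facing direction, y up, ground at y = 0, moments counterclockwise-positive):
per leg a foot, shank and thigh, plus a single lumped head–arms–trunk (HAT)
mass. An anthropometric model scaled to stature *H* and mass *M* supplies
segment lengths (0.24 / 0.48 / 0.50 m at *H* = 1.85 m), mass fractions
(1.7 / 4.7 / 10.7 % of *M*) and centre-of-mass locations (43.4 / 42.0 /
43.9 % of segment length from the proximal end).

The pipeline solves, in order:

1. **Whole-body centre of mass** — the mass-weighted mean of the seven mass
   points, CoM = Σ mᵢ pᵢ / Σ mᵢ.
2. **Ground reaction forces** — in double support, moment equilibrium about
   one contact gives the vertical split
   GRFy₁ = P · L₂ / (L₁ + L₂), with P = M g the body weight and L₁, L₂ the
   horizontal CoM–contact lever arms; horizontal components are
   friction-coupled, GRFx₁ = C₀ · GRFy₁ = −GRFx₂ (C₀ = 0.3 by default,
   a sand surface). In single support the centre of pressure lies directly
   under the CoM and carries (0, P).
3. **Joint loads** — a distal-to-proximal free-body recursion
   (foot → shank → thigh). For each segment the unknown proximal joint force
   closes ΣF = 0 and the joint moment is the unique couple closing ΣM = 0
   about the segment CoM, with action–reaction sign flips between segments.

Every solved free body (and the whole body) is re-checked by an independent
brute-force equilibrium oracle before a report is accepted.

## Worked example

A synthetic "readiness" stance (double support, 185 cm / 100 kg figure,
68.76 % of the weight on the hind foot) ships with the package:

```r
library(limbstat)
fx <- system.file("extdata", "readiness_synthetic_pose.json",
                  package = "limbstat")
analyze(fx)
```

```
  support: double, facing +1
  CoM: (0.3050, 1.0556) m
  hind-leg share of vertical load: 68.76%
GRF solution (Ptotal 981.00 N, hind share 68.76%)
  hind  contact x 0.1331 m: GRF (202.351, 674.504) N
  front contact x 0.6831 m: GRF (-202.351, 306.496) N
Limb solution (hind leg):
  ankle F = (-202.351, -657.827) N   M = -77.3717 N m
  knee  F = (-202.351, -611.720) N   M = -47.0349 N m
  hip   F = (-202.351, -506.753) N   M = -195.7845 N m
...
  equilibrium check: all free bodies balanced
```

Reading the numbers: the hind foot carries 674.5 N of the 981 N body weight
(68.76 %) and a 202.35 N propulsive friction force (0.3 × 674.5), mirrored on
the front foot so the stance is static. Joint forces grow from ankle to hip
as each segment's weight is added; negative moments are clockwise in the
world frame (e.g. the hind ankle moment plantar-flexes against the forward
lean). The swing-leg counterpart of a kick stance can be produced with
`generate_scene(scene_params("kick"))`.

Synthetic scenes with exact ground truth, keypoint noise studies and file
round-trips are available through `scene_params()` / `generate_scene()` /
`perturb_scene()`; see the methods vignette (`vignettes/limbstat-methods.Rmd`)
for the modeling decisions and their rationale.

## Command line

```sh
Rscript inst/scripts/limbstat simulate --preset readiness --seed 7 --out-dir out/
Rscript inst/scripts/limbstat analyze --pose out/pose_readiness_seed7.json \
        --out out/report.json --csv out/loads.csv
Rscript inst/scripts/limbstat validate --report out/report.json
```

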
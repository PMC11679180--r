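---
title: "Static link-segment analysis with limbstat: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static link-segment analysis with limbstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbstat)
```

## The problem

Given a single sagittal-plane posture — described only by 2D pose keypoints
and an assumed anthropometric model — `limbstat` computes the ground
reaction forces (GRFs) and the joint forces and moments at the ankle, knee
and hip that hold the posture in static equilibrium. This is the
quasi-static limit of inverse dynamics: all accelerations are zero, so the
only external loads are gravity and the ground reactions, and every free
body must satisfy ΣFx = 0, ΣFy = 0 and ΣM = 0 about any point.

The world frame is fixed throughout: x along the facing direction, y up,
ground at y = 0, moments counterclockwise-positive. If a figure faces the
−x direction the mechanics are unchanged; only `facing_sign` in the report
records the orientation, so a reader can map the signs onto an image that
faces the other way. No internal computation ever flips conventions.

## The anthropometric model

The body is reduced to seven rigid pieces: foot, shank and thigh per leg,
plus one lumped head–arms–trunk (HAT) point mass.

| parameter | foot | shank | thigh | unit |
|---|---|---|---|---|
| length (at 1.85 m stature) | 0.24 | 0.48 | 0.50 | m |
| mass fraction of body mass | 0.017 | 0.047 | 0.107 | – |
| CoM, fraction from proximal end | 0.434 | 0.420 | 0.439 | – |

The default subject is a 1.85 m, 100 kg athlete. Choices that the input
tables leave open, decided once here:

* **g = 9.81 m·s⁻².** The reference leg loads for this subject sum to
  674.5038 + 306.4962 = 981.0 N, which for 100 kg forces g = 9.81; we adopt
  it as the default.
* **The HAT lump.** Normative tables cover only the leg segments
  (2 × 17.1 % of body mass); the remaining 65.8 % is carried as a single
  residual mass. Without it the vertical GRFs could not sum to body weight,
  violating the whole-body force balance. The lump sits at the *trunk
  anchor*, the midpoint of the neck and mid-hip keypoints — a deliberate
  simplification: the GRF distribution depends only on total weight and the
  CoM's horizontal position, and stylized figures rarely yield reliable
  distal arm keypoints.
* **Stature scaling.** Segment lengths are absolute defaults for 1.85 m and
  scale linearly with stature; mass and CoM fractions do not scale.
* **Bilateral symmetry.** Left and right legs share one segment
  specification.
* **Friction coefficient C₀ = 0.3**, representative of a sand surface. It
  is a configuration value, warned about (not rejected) outside [0, 1].
* **Foot axis.** The foot segment runs ankle → big toe (its CoM fraction is
  measured from the ankle); the heel keypoint only contributes contact
  geometry. A per-segment "% from proximal end" needs exactly one axis, and
  ankle → toe is the conventional one.

## Calibration of pose keypoints

Input files are the BODY_25 JSON dialect of common pose estimators
(per-person flat arrays of 75 numbers; confidence 0 marks a missing
keypoint). Calibration applies, in order: a y-axis flip (pixels are
y-down), one isotropic meters-per-pixel scale, and a vertical shift placing
the lowest heel/toe point on the ground line y = 0.

* **Scale from the shank.** The scale is the model shank length divided by
  the pixel knee–ankle distance, averaged over legs that pass the
  confidence threshold (default 0.3). Stature-based scaling would hinge on
  head keypoints, which are the least reliable on stylized figures.
* **Support state.** A foot is grounded when both its heel and toe lie
  within the ground tolerance (default 0.02 m — generous against sub-pixel
  noise at plausible scales) of the ground line. Both grounded ⇒ double
  support; exactly one ⇒ single support; none ⇒ an error. A caller can
  *force* a state (e.g. the readiness preset's interpretive choice that
  both feet are planted even if the rendering suggests otherwise); forcing
  tolerates foot-height discrepancies up to a relaxed bound of 0.1 m but
  still refuses a clearly airborne foot.
* **Hind/front labeling** is by x-order of the midfoot against the facing
  sign, which is itself inferred from the heel→toe direction of grounded
  feet; labeling is therefore invariant under mirroring.

## Ground reaction forces

**Double support.** With contact points at x₁ (hind) and x₂ (front) and the
CoM at x_c between them, moment equilibrium about one contact gives

GRFy₁ = P · L₂ / (L₁ + L₂),  GRFy₂ = P − GRFy₁,

with P = M g, L₁ = |x_c − x₁|, L₂ = |x₂ − x_c|. Horizontal components are
friction-coupled and self-cancelling: GRFx₁ = C₀ · GRFy₁ on the hind foot
(propulsive, along the facing direction) and GRFx₂ = −GRFx₁. A CoM outside
[x₁, x₂] is rejected (`out-of-base`): with unilateral contact the ground
cannot pull, so no static solution exists, and the solver never clamps a
negative vertical GRF silently.

Where exactly a flat foot transmits its load is not observable from
keypoints; the contact point is configurable (`heel`, `midfoot`, `toe`),
defaulting to the midfoot (heel–toe midpoint). Joint moments depend on this
choice, which is why it is exposed rather than hard-coded.

**Single support.** Statics fixes everything: the centre of pressure lies
directly under the CoM, the contact carries (0, P), and the horizontal GRF
is zero (with one contact, ΣFx = 0 admits nothing else; a "lateral
stabilization" force would be a dynamic effect outside this model's scope).
The CoP must fall within the stance foot's heel–toe extent.

## The limb recursion

Each limb is solved distal-to-proximal (foot → shank → thigh). For each
segment the loads are: its weight at its CoM, the reaction of the previous
segment at the shared joint (force and couple, signs flipped), the ground
reaction (foot only), and the unknown proximal joint force and couple. The
joint force closes ΣF = 0; the joint moment is the unique couple closing
ΣM = 0 about the segment CoM, with every moment computed as the scalar
cross product r × F under the single CCW-positive convention.

The published per-segment moment equations that motivated this design mix
sign patterns that cannot all hold under one convention as literally
printed; `limbstat` therefore implements the *principle* those equations
express — the net moment of all loads on each free body is zero — and
guards correctness with two independent re-derivations:

1. the synthetic generator's ground truth is computed by distal-chain
   aggregation with moments taken about the joint itself (a different
   formulation sharing no code with the recursion), and
2. the brute-force equilibrium oracle re-sums every free body's loads.

Because a joint "moment" is a free couple, its value is independent of the
reference point once the forces balance; the test suite asserts the
recursion and the about-the-joint formulation agree to 10⁻⁹.

## The equilibrium oracle

`check_scene()` rebuilds every free body (and the whole body, as ground
reactions plus the gravity of all seven mass points — deliberately not via
the CoM) by direct summation and reports net force and net moment against
absolute tolerances of 10⁻⁸ N and 10⁻⁸ N·m. Tolerances are absolute, not
relative, because the loads are O(10²–10³) N and O(10¹–10²) N·m, leaving
about nine orders of magnitude of headroom over double-precision error.
`analyze()` runs the oracle on every result and marks the report failed
(rather than raising) if any body is out of balance.

## The synthetic scene generator

The generator is the package's test bed: it builds postures by forward
kinematics and attaches ground-truth loads that have themselves passed the
oracle. It emulates two stance families of a sagittal combat posture:

* **readiness** — double support, stance width 0.55 m, hind knee flexed
  ~33°, front leg nearly straight, and the hind foot carrying
  674.5038 / 981 ≈ 68.76 % of body weight (the generator's default
  `com_bias`). The trunk anchor is placed in closed form from the
  mass-point system so the whole-body CoM realizes exactly that share; an
  infeasible request (trunk anchor further than 0.6 m from the hips) is
  rejected.
* **kick** — single support on a near-vertical stance leg (shank tilt 3°),
  the swing leg extended forward at roughly hip height with the foot
  dorsiflexed so the heel leads; the CoM target is the stance midfoot.

The preset tilt angles were fixed once, from a small survey at design time,
so that each preset's stance-knee moment magnitude lands near the
reference values for these posture families (readiness hind knee ≈ 47 N·m,
kick stance knee ≈ 66 N·m) while respecting the stated stance descriptions.
They are descriptive choices, not fitted parameters, and the package never
asserts the reference moments numerically — those depend on unpublished
artwork geometry and are checked only as orderings (kick stance knee above
readiness hind knee; swing ankle the smallest of its limb).

What the generator does *not* emulate: image rendering, perspective or
vase-curvature distortion, occlusion, asymmetric anthropometry, and any
dynamic effect. A green parameter-recovery test therefore establishes that
the pipeline inverts its own rendering (file format, y-flip, scaling,
ground shift, support inference) exactly — not that pose-estimator output
on real imagery is unbiased. Keypoint detection error is studied separately
through `perturb_scene()`, which jitters rendered pixels with seeded
Gaussian noise and recomputes a consistent ground truth for the perturbed
geometry; the induced load error is continuous in the noise level and
vanishes with it.

## Numerical choices and degenerate inputs

* Randomness exists only in pixel-noise perturbation, always through an
  explicit seed and a private RNG stream (global RNG state is restored).
* Coincident contact points (< 1 nm apart) are a `degenerate-stance` error;
  coincident segment endpoints a `degenerate-segment` error; a zero
  knee–ankle pixel distance a `degenerate-pose` error. Near-degenerate
  stances (contacts ε apart with the CoM between them) remain well-posed:
  shares stay in [0, 1] and sum to one.
* Boundary CoM positions (exactly above a contact) are accepted
  inclusively; L₁ = 0 yields the full load on that foot.
* Reports serialize numbers at 17 significant digits, which round-trips
  IEEE doubles bit-exactly.
* Zero-weight segments are permitted in hand-built free bodies (for null
  tests) but not in models, whose mass fractions must lie in (0, 1).

## Known limitations

* 2D statics only: no accelerations, no muscle forces, no out-of-plane
  loads; joint moments are net couples, not tissue loads.
* The HAT lump's vertical placement is conventional (0.30 m above the hips
  at default stature); it affects no horizontal equilibrium quantity, but a
  whole-body *moment* about an arbitrary point would feel it. All shipped
  checks are invariant to this choice because the GRF solution enforces the
  moment balance exactly.
* Heel-contact geometry is approximated by a flat-foot template; subjects
  with substantially different foot proportions need overrides.
* The friction relation is an equality (fully mobilized friction), not an
  inequality constraint; it mirrors the source model rather than a slip
  analysis.
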
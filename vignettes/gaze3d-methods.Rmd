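---
title: "Estimating the 3D Point-of-Regard from pupil size and sightline convergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the 3D Point-of-Regard from pupil size and sightline convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gaze3d` estimates the three-dimensional Point-of-Regard (PoR) — the
point in free space a person is looking at — from binocular eye
features captured by a head-mountable four-camera rig. This vignette is
the package's account of the science: the measurement model and its
assumptions, the calibration search and its numerics, what the
synthetic rig does and does not emulate, the genuinely open design
choices we resolved, and the method's limitations — several of which we
quantify precisely because the synthetic ground truth makes them
measurable.

## 1. Measurement model

Two properties of human vision carry the depth information:

* **Vergence.** The two eyes rotate oppositely so that both sightlines
  pass through the fixated point; their intersection encodes fixation
  depth.
* **Pupillary accommodation reflex.** Under fixed illumination the
  pupil contracts for near targets, so pupil size `S` (mm) is a
  monotone correlate of viewing distance.

The model represents each eye by two points: the **pupil center**
(`P_l`, `P_r`; measured by stereo reconstruction) and an intra-ocular
**line-of-sight convergence point** (`P_L`, `P_R`; calibrated). The
sightline is the infinite line through the two; because measured
sightlines are skew, the PoR is defined as the midpoint of their
nearest points, with the nearest-point gap kept as a quality indicator.
`nearest_points()` implements the closed-form common-perpendicular
construction (the common normal `n = a × b` and the two plane normals
`n × a`, `n × b`); it agrees with the textbook two-unknown linear
solve to 1e-9 relative (a standing test).

The convergence point is not anatomically fixed: it moves with the
accommodation state, i.e. with `S`. After calibration the law

$$Z = \gamma_0 + \gamma_1 S + \gamma_2 S^2,\qquad
  X = \alpha_0 + \alpha_1 Z,\qquad Y = \beta_0 + \beta_1 Z$$

is fitted per eye by ordinary least squares — depth first (the
`S`-sensitive coordinate), then the spatial line through the
convergence points, which any direction-vector parameterization of
that line reduces to. Fitting is `stats::lm()`; a hand-rolled
normal-equations solver exists only as a test oracle.

All coordinates are millimetres in the **rig frame** (the leftmost
virtual camera; +Z from the cameras toward the eyes, so the observed
scene lies at negative Z behind the virtual cameras — an artifact of
the semi-transparent-mirror construction that folds the optical path).

## 2. Feature extraction from eye images

Single-camera processing (module `detect_eye_features()`):

1. **Eye localization** by horizontal/vertical intensity projections:
   the dark eye structures produce a trough in both smoothed mean
   projections; the box is the trough span (`depth_frac = 0.35` of the
   range, 3 % padding). A flat frame (range `< 2` intensity levels)
   raises "no eye found".
2. **Adaptive gradient pupil edge map** (`pupil_edge_map()`): gradient
   magnitude by central differences (zero on the 1-px border); the
   amplitude is zeroed near the image center and the four corners
   (margins default to 5 % of each dimension — the source gives no
   size); the map is split into 3×3 blocks and only values above each
   block's mean over its surviving values are kept; the amplitude is
   zeroed inside the dilated specular-spot mask (components above
   intensity 250, dilated 3 px); finally a pixel is retained iff its
   3×3 neighborhood sum exceeds `0.6 · Σ(neighborhood sums)/(6 m n)`.
   We implement the printed denominator `6·m·n` literally (it makes the
   retention threshold roughly a tenth of the mean neighborhood sum);
   retained pixels are additionally forced to zero inside the margin
   and spot regions so the binary map respects the zeroing. A second,
   deliberately naive loop implementation of the same definition is
   kept in the test suite and the two must agree **bit-for-bit** on
   every fixture.
3. **Two-step ellipse fit** (`fit_pupil_ellipse()`): RANSAC over exact
   5-point conics (500 iterations, 1.5 px inlier tolerance, explicit
   seed), consensus refit, then discarding points whose *metric*
   distance to the step-1 ellipse exceeds ⅛ of the major semi-axis,
   and a final direct least-squares ellipse fit (Halir–Flusser
   stabilization, which cannot return a non-ellipse). Point-to-ellipse
   distance is computed by Newton iteration on the parametric angle
   (first-quadrant reduction, tolerance 1e-9) because the ⅛-rule is a
   metric rule, not an algebraic-residual rule. Ellipses are canonical:
   `A ≥ B`, tilt in `(−π/2, π/2]`.
4. **Inner corner** (`detect_inner_corner()`): Harris responses at
   three Gaussian scales (σ = 1, 2, 4; tensor smoothing 1.5σ), each
   normalized by its maximum, combined with weights (0.5, 0.3, 0.2),
   arg-max inside a region found by threshold segmentation of the dark
   eye structures (the canthus is their medial extreme), refined to
   sub-pixel by a 2D quadratic fit. This is a documented simplified
   multi-scale variant, not a full scale-space implementation.

Stereo (module `extract_frame_features()`): each eye is imaged by a
rectified pair (22 mm baseline), so corresponding points share the
image row. The fitted boundary ellipses are sampled along common
epipolar rows — each row crosses the pupil boundary twice, and because
the 3D pupil circle is planar, the two row crossings in the two images
are genuine stereo correspondences when matched left-to-left and
right-to-right. Crossings are triangulated as midpoints of the
back-projected rays and the spatial pupil circle is fitted (total
least-squares plane via SVD, in-plane algebraic circle fit, center
lifted back; normal canonicalized to +Z). **Pupil size is the diameter
of the 3D circle** — a metric quantity invariant to eye–camera
distance, which is what the accommodation law needs; the source never
fixes diameter-vs-area or units. Corners are triangulated as
index-paired single landmarks.

## 3. Calibration of the convergence points

The subject fixates the four crosses (spacing `L = 150` mm) of a board
placed at five distances between 40 and 120 cm — 20 captures. Per
placement, the convergence pair is sought starting from the mean of the
four pupil centers pushed 10 mm along +Z (into the eyeball), inside a
4 mm cube per eye.

Two judgment bases score a candidate pair: the summed nearest-point
**gap** over the four fixations, and the **shape error** — the summed
absolute deviations of the four adjacent estimated cross-to-cross
distances from `L` (the square's diagonal is never used). The merged
objective is

$$\mathrm{score} = \exp\!\Big(-\frac{\sum_i \|P_{1i}-P_{2i}\|}{D_\mathrm{gap}}
  \;-\; \frac{\mathrm{Shape}}{\varepsilon\, D_\mathrm{shape}}\Big),
  \qquad \varepsilon = 10,$$

where each basis is normalized by its dispersion over the candidates of
the current search region — the stated purpose of the merged form is to
*unify the two judgment bases*, and only a per-basis normalization
actually puts them on one dimensionless scale. Numerical choices that
matter:

* **Median dispersions.** Both error surfaces have enormously
  heavy-tailed upper ranges (shape errors reach 1e7 mm where the
  sightlines become near-parallel and the nearest points shoot off),
  so an RMS dispersion is dominated by the tail and flattens all
  useful scores onto an indistinguishable plateau; the median is the
  robust scale. A candidate with both errors zero scores exactly 1; a
  zero dispersion with a positive error scores 0 by convention.
* **Asymmetric alternative.** Normalizing only the gap term (with the
  shape term at raw mm / ε) makes the shape basis ~1000× stiffer than
  the gap basis at every lattice resolution; we implemented that
  variant first and it verifiably cannot recover a noiseless planted
  pair (every coarse round's arg-max lands on shape-consistent
  impostors several millimetres away).

**Search realization** (`search_convergence()`). The printed joint
shrinking lattice (each cube enumerated at step 0.2 mm, step and region
halved per round until the step drops below 0.0005 mm — nine rounds;
a 4 mm cube at 1 mm step is the canonical 125-point example) has
`21³ ≈ 9.3e3` points per cube and therefore ~8.6e7 candidate *pairs*
per round: infeasible. Worse, single-track recentering provably
diverges here regardless of pairing (Section 6). The package therefore
realizes the search as:

1. a **coarse full-product seeding pass** over the two initial cubes at
   1 mm step (125 × 125 pairs — the printed example), which fixes the
   dispersion normalization for the placement and proposes up to four
   diverse seed pairs (greedy selection with a 0.8 mm joint-separation
   rule; the initial guess is always a seed);
2. per seed, **shrinking section scans**: fine 1D scans over a fan of
   directions in the three coordinate planes, applied either to both
   cubes equally (*shared* moves — the objective's sloppy directions)
   or with opposite sign (*differential* moves — the stiff vergence
   directions), plus a Hooke–Jeeves-style pattern move along each
   sweep's net displacement; span and step are halved per scale until
   the step passes the printed 0.0005 mm cutoff;
3. the finalist with the best merged score wins. Ties break to the
   lowest index; there is no randomness — identical inputs give
   identical output.

`pairing = "product"` retains the full product-per-round form for
coarse lattices and is exercised in the tests. `calibrate_gaze()` runs
the search per placement, anchors the reference eye frame on the first
placement, aligns all convergence pairs into it, and fits the law with
one `(S, X, Y, Z)` sample per placement and eye (the four crosses of a
placement share one viewing distance, so their pupil sizes are
averaged — five samples per eye, matching the protocol's five
placements).

## 4. Corner-vector alignment

The eye coordinate frame has its origin at the right inner corner and
the rig's axes (a pure translation); the inner-corner vector `v` runs
from the right to the left canthus. The calibration stores `v₀`, the
reference origin, and per eye the **minimal (geodesic) rotation**
carrying `v₀` onto the convergence-point vector plus that vector's
norm. A rotation between two vectors is one degree of freedom
underdetermined; the geodesic choice (axis `u × w`, angle `∠(u,w)`) is
the only canonical continuous one, with a deterministic half-turn axis
for anti-parallel inputs.

At transfer time the current corner vector `v_i` determines
`R′ = minimal_rotation(v₀, v_i)`, and each calibrated vector is rotated
by `R′` and re-anchored at the current right corner with its norm
preserved. We compose the rotations in the order `R′ ∘ R_eye` — i.e.
`R′` acts on the calibrated offset vector — because only that order is
*equivariant*: under a rig motion that is a translation plus a minimal
rotation of the corner vector, the transferred points then coincide
with the truly moved points to machine precision (a standing 1e-9 mm
test over 1000 random frames). The reverse composition printed in the
source equation is not equivariant and fails that round-trip. Head
roll about the corner vector itself is unobservable from two corner
points; the suite asserts that a rolled rig produces a real,
uncorrected error — a model property, not a bug. The device's physical
pitch restriction is what justifies the one-vector reference in
practice.

## 5. The synthetic rig

`rig_scenario()` plants the full ground truth: inner-corner geometry
(30 mm canthal separation), per-eye convergence laws (γ, α, β in the
reference frame), a pupil-size law `S(d) = 3 + 1.5 (d − 400)/800` mm —
strictly *increasing* with distance, i.e. the pupil contracts for near
targets — board placements at 400…1200 mm, and noise levels. Each
fixation is constructed so the exact sightline passes through its
target: the planted laws give the convergence point, and the pupil
center is placed on the convergence-to-target segment at a 10 mm
anatomical offset (matching the calibration's initial-guess prior).
One accommodation state — hence one convergence pair — is planted per
board placement, driven by the board-center distance. Feature noise is
i.i.d. Gaussian on all 3D coordinates and pupil sizes.

The image level (`render_eye_pair()`) renders dark-pupil views for all
four cameras with exact per-camera ground truth: the pupil is the exact
projection of the planted 3D circle with a sharp (~1 px) boundary, the
iris margin is deliberately faint and soft (near-infrared iris–sclera
contrast is genuinely low — which is why trackers use the pupil, not
the limbus), lid-margin shadow bands meet at the inner canthus, and
optional upper-lid occlusion, saturated specular spots, and pixel noise
exercise the robustness paths. The default eye relief is 85 mm so that
both the pupil and the canthus stay inside both cameras of a pair at
the 22 mm baseline. Problem sizes used throughout the tests (five
placements, 20-fixation Monte-Carlo batches, single rendered frames for
the imaging checks) were chosen as the smallest that exercise every
code path of the study protocol.

What the simulator does *not* emulate: corneal refraction (the model
has no cornea), pupillary light reflex (fixed illumination is a method
precondition), iris texture, blinks, saccade blur, and photorealistic
shading. Passing tests therefore demonstrate correctness of the
geometry, search, alignment and fitting pipeline under the model's own
assumptions — not robustness to real-world imaging nuisances.

## 6. Identifiability: what the synthetic ground truth reveals

The merged objective's landscape can be mapped exactly with noiseless
planted data, and it explains the method's error structure:

* **Vergence lever.** A differential (vergence-direction) error `δ` in
  the convergence points tilts the sightlines by `δ / 10 mm` and moves
  the implied PoR depth by roughly `d²/(offset · interpupil) · δ` —
  about 1000–2000 mm per mm at 1 m. The shape error inherits this
  stiffness (~600–2900 mm per mm of candidate error at 0.4–1.2 m).
* **Impostor basins.** The shape error has exact zeros off the truth
  (any candidate pair whose implied cross estimates form a 150 mm
  square), and the gap has its own zero manifold; only their
  intersection pins the truth. At far placements (≥ 1 m) a broad
  vergence-flipped impostor basin scores within ~7e-4 (in the
  exponent) of the global optimum, while the truth's advantage is
  cancelled by the shape-error slope within ~7 µm of the truth — a
  needle no lattice at the printed 0.2 mm step can resolve, including
  the exact full-product search. The two basins are separated by a
  near-parallel-geometry barrier (shape errors ~2e4), so no local
  refinement crosses between them.
* **Consequences.** Noiseless convergence recovery is 0.003–0.02 mm at
  400–800 mm but 0.5–1.5 mm at 1000–1200 mm (errors lying along the
  objective's sloppy directions). Pooled into the five-sample
  quadratic, the far placements' errors distort γ and α, and through
  the vergence lever the fitted model's depth predictions at far test
  distances degrade to decimetre–metre scale even with noiseless
  features. This measured behavior is consistent with the error
  pattern reported for the physical system, where depth errors grow
  from ~5 cm at 0.8 m to ~24 cm at 6 m while lateral errors stay at
  millimetre–centimetre level; the package reproduces exactly that
  anisotropy (depth error strictly dominating lateral error at every
  distance under isotropic 0.05 mm feature noise, by a factor ≥ 28 in
  the default acceptance run).

We deliberately did not tune the generator, the protocol constants or
the objective's printed parameters to mask this: the identifiability
limit is a property of the method at its own operating point, and
quantifying it is one of the package's main scientific outputs.

## 7. Other design choices and limitations

* **Corner localization bias.** The pinned refinement (Harris arg-max
  plus quadratic interpolation) carries the classic inward
  displacement: ~1.4 px on an ideal right-angle step junction and
  ~4–5 px on the default acute (~40°) canthus wedge. The bias is
  stable across frames and cameras, so it cancels in the corner-vector
  *transfer* (which only needs consistency) and barely affects the
  corner-distance stability (std ≈ 0.02 mm under 0.2 px noise, well
  under the 0.10 mm stability reported for real hardware); it does
  shift the absolute eye-frame origin by ~0.5 mm.
* **Pupil-size range.** Predictions outside the calibrated `S` range
  (±10 % margin) warn and proceed; the quadratic extrapolates smoothly
  but uncertainly.
* **Edge-map reading.** The retention threshold's printed denominator
  (`6·m·n`) is implemented literally; the plausible alternative
  (`m·n`, i.e. 0.6 × the mean neighborhood sum) retains about six
  times fewer pixels. Both readings are self-consistent; the
  bit-equivalence contract fixes ours.
* **Row-order stereo correspondence.** Pupil-boundary matching uses
  rectified-row rank order (the boundary is textureless); near-
  horizontal ellipses give two crossings per row whose left/right
  order is preserved by the epipolar geometry of a planar circle.
* **Per-eye pupil size.** Each eye's law uses that eye's own `S` — the
  least-assuming reading of the per-eye model structure.
* **Scope.** No blink handling, no gaze-event classification, no
  illumination normalization, no head-pose tracking (deferred to
  SLAM/IMU by the device concept), and no luminous targets (screens
  violate the fixed-illumination precondition).
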
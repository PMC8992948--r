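---
title: "An in-silico NART-vs-DART trial for prostate IMPT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An in-silico NART-vs-DART trial for prostate IMPT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package simulates

In intensity-modulated proton therapy (IMPT) for high-risk prostate
cancer the clinical target volume (CTV) is the prostate plus the entire
seminal vesicles (SV). The SV position is coupled to rectal and bladder
filling, so a plan optimized once on a planning CT ("NART": non-adaptive
radiotherapy, the original plan delivered through all 21 fractions) can
miss the SV on treatment days, while daily re-optimization on each day's
anatomy ("DART") can follow it. `adaptrt` rebuilds this comparison as a
fully synthetic experiment: a parametric pelvic phantom, a calibrated
daily-variation generator with a known (ground-truth) deformation, a
simplified spot-scanning dose engine, worst-case robust spot-weight
optimization, per-fraction recalculation under both strategies, and
deformable accumulation of the 21 fraction doses on the planning
anatomy, evaluated with DVH indices, clinical-goal achievement rates,
paired t-tests and McNemar tests.

Everything is deterministic given a single master seed; no external data
are used.

## Synthetic anatomy

The reference phantom (`patient_config()`, `build_reference_phantom()`)
is built from closed-form shapes in world millimetres (LPS axes, the
isocenter at the prostate centre):

* prostate — ellipsoid at the isocenter (nominal semi-axes
  22 x 20 x 20 mm, about 37 ml);
* SV — two ellipsoidal lobes posterior-superior to the prostate,
  anchored at their inferior tips where they join the prostate base;
* rectum — a tube of nominal radius 15 mm directly posterior to the
  prostate/SV, with its posterior wall resting on the sacrum;
* bladder — an ellipsoid anterior-superior, anchored near the bladder
  neck (the inferior-posterior pole);
* pelvic bone — lateral iliac shell sectors with angle-modulated
  (curved) crest profiles plus an ellipsoidal sacrum. The curvature is
  deliberate: flat faces aligned with the voxel lattice quantize
  sub-voxel rigid motion and would spoil registration accuracy;
* body — an elliptical cylinder of soft tissue.

HU are class-constant (no CT physics), and a piecewise-linear monotone
calibration (`hu_to_stopping_power()`) anchored at air (0.001) and water
(1.0) converts them to relative stopping power. Masks are voxelized by
the voxel-centre rule and clipped pairwise (prostate > SV > rectum >
bladder) so the label map is disjoint; `CTV = prostate U SV` exactly.
With a patient seed, organ sizes and positions are jittered within
anatomically plausible bounds to create a heterogeneous cohort.

## Daily variation model

`variation_params()` holds the generator's calibration. Percent volume
differences (daily vs planning) are drawn per organ from a *shifted
lognormal* `X = c + exp(N(mu, sigma^2))`, moment-matched to the target
mean and SD through the shift offset `k` in `c = mean - k*SD`
(`sigma^2 = log(1 + 1/k^2)`). For the rectum and bladder, `k` is solved
so that `P(X > 0)` equals the observed fraction of days with a larger
organ (71 % and 82 %); a Gaussian cannot reproduce both the moments and
these exceedances (it gives about 72 % and 77 %). Prostate and SV use
`k = 2` (mild right skew). Draws are truncated below at -80 %.

Each patient's 21 daily quantiles are sampled *stratified*: a random
permutation of the 21 equal-probability strata with uniform jitter
inside each stratum. Every draw is marginally the calibrated
distribution, every synthetic patient experiences the documented range
of variation, and cohort means converge faster than under iid sampling
(`sampling = "iid"` restores plain draws). A Gaussian-copula latent
correlation `rho` can couple a patient's days; the default is 0 because
the source statistics are pooled marginals and exchangeable days
reproduce exactly those.

Volume changes are realized geometrically, volume-exactly, about
anatomical anchors:

* prostate/SV: linear scaling `s^(1/3)` about the centre/anchor;
* rectum: transverse scaling `s^(1/2)` of the tube cross-section about
  its *posterior wall* — the rectum distends anteriorly, as the sacrum
  fixes its back wall;
* bladder: linear scaling about the *neck*, so filling expands the dome
  anteriorly/superiorly.

The SV anterior-posterior displacement is coupled to filling:
`dy_SV = a * dV_rectum% + b * dV_bladder%`. The magnitudes follow from
the anchored geometry rather than being free: the anteriorly distending
rectal wall advances by about `r * dV%/100 ~ 0.15 mm/%`, and the
abutting SV rides on it (`a = -0.15 mm/%`, anterior); the neck-anchored
bladder's posterior surface moves by only about `+0.02 mm/%`
(`b = +0.02`, posterior). Residual prostate motion relative to bone
(per-axis SD 0.3/1/1 mm, carried by the SV) and a rigid set-up error
(translation SD 2 mm, rotation SD 1 degree, truncated at 3 SD) complete
a daily instance. Set-up magnitudes are stand-ins chosen so the 3 mm
robustness setting is exercised near its design point; the source cohort
does not report them.

### Ground-truth deformation

Each daily instance records the parametric map from planning to daily
coordinates: the organ-state deformation followed by the rigid set-up
transform. The organ-state field applies, inside each organ, exactly
that organ's affine (so the analytic daily masks and the field agree),
with a smoothstep decay to zero at 1.6 organ radii carrying the
surrounding soft tissue; where interiors would overlap, the
higher-priority organ claims the point. Because a single large step can
fold (a 90 % bladder expansion is not a small perturbation), the map is
composed of up to 12 sub-steps whose per-step linear scale stays within
about 4.5 % of identity; each sub-step is comfortably invertible and the
composed interior map is still the exact total affine. The inverse
iterates a per-step fixed point; round-trip errors are at the micrometre
level, far inside the half-voxel contract used by the tests.

## Dose engine

A deliberately simple spot-scanning model (`beam_model()`,
`compute_dose()`), standing in for a clinical pencil-beam algorithm at
toy fidelity:

* two opposed lateral parallel (non-divergent) fields along the x axis;
* water-equivalent path length (WEPL) by exact voxel-boundary ray
  tracing (`trace_wepl()`); the axis-aligned fields use an equivalent
  cumulative-sum fast path (voxel-centre convention: half the voxel's
  own water-equivalent thickness);
* an analytic Bragg curve: an asymmetric Gaussian peak at the nominal
  range (distal sigma 3.55 mm, i.e. an 80-20 falloff of 4 mm; proximal
  sigma 6.5 mm) over an entrance plateau (25 % of peak, rising 60 %
  towards the peak, handed off about 6 mm proximal of it), hard zero
  beyond range + 8 mm;
* lateral Gaussian spread with sigma growing linearly with depth
  (6 mm surface sigma + 0.025 mm per mm WEPL), normalized so the lateral
  integral preserves the depth dose;
* a constant RBE of 1.1 applied exactly once — all doses are Gy(RBE);
* dose is linear in the spot weights by construction.

A robustness `scenario()` is an isocenter shift (the patient moved
rigidly relative to the beams) plus a range scale; the scale divides the
WEPL, so values above 1 push every spot deeper (stopping power was
overestimated), matching the 3.5 % stopping-power-ratio uncertainty.

Spots are placed on a beam's-eye-view lattice (pitch 1.5 sigma) over the
CTV projection plus an 8 mm margin, with energy layers spaced in water
range over each lattice position's CTV depth envelope plus 8 mm.

## Robust spot-weight optimization

`plan_impt()` is the planning "fit". It minimizes, over non-negative
spot weights, a weighted sum of one-sided quadratic penalties evaluated
on the voxel-wise worst case over the nine scenarios (nominal, six 3 mm
cardinal shifts, range +/- 3.5 %; shift and range errors are not
cross-producted):

* CTV under-dose below the planning aim on the scenario minimum: a mean
  term (weight 100) plus a coldest-5 % tail term (weight 60) so that a
  thin seminal-vesicle section — a handful of points among hundreds —
  cannot be diluted away by the averaging. Coverage is enforced on the
  target *continuum*: besides the mask voxel centres, points drawn
  uniformly inside the analytic target shapes enter the objective, since
  a coarse grid can miss a thin SV tip entirely. The aim is 100.8 % of
  prescription (63.5 Gy(RBE)) — the usual planning practice of aiming
  slightly above the goal;
* CTV over-dose above 66.5 Gy(RBE) on the scenario maximum (weight 150);
* smooth DVH surrogates for rectum V50 < 20 %, rectum V30 < 50 % and
  bladder V30 < 30 %: the volume fraction is estimated by a logistic
  step of width 1.5 Gy and the excess over the limit penalized
  quadratically (weight 40). A fixed smooth objective was preferred to
  iteratively re-linearized DVH points: it keeps one well-defined
  objective whose optimization trace is provably non-increasing;
* a rectum "as low as possible" term above 45 Gy(RBE) (weight 2),
  implementing the protocol's instruction beyond the hard V50 limit;
* a normal-tissue hot-spot penalty above prescription (weight 4) on a
  soft-tissue shell around the target.

Target terms dominate OAR terms, encoding target priority. The solver is
bound-constrained L-BFGS-B run in restarted chunks from a uniform start
scaled to the prescription; the objective value recorded after each
chunk is non-increasing and the iteration stops on a relative change
below 1e-5. Finally the weights are renormalized (clamped to
[0.85, 1.15]) so the nominal CTV D99 sits at the planning aim — the
clinical renormalization step every treatment-planning system applies.
DVH-constraint feasibility is re-checked on the final plan and reported
in the plan metadata.

Worst-case composition itself is exposed as `worst_case_dose()`
(voxel-wise minimum for the target, maximum elsewhere), and
`evaluate_plan_robustness()` replays the protocol's error-scenario
analysis: six 3 mm shifts plus voxel-by-voxel stopping-power scaling at
+/- 3.5 % (the density error that a Hounsfield-unit variation represents
— the phantom's HU are class-constant, so the perturbation is applied on
the stopping-power scale directly), reporting CTV D99, rectum V60 and
bladder V60 deltas against the nominal control.

## Alignment and accumulation

The daily alignment protocol is reproduced in two stages
(`rigid_align_bone()`, `align_prostate_center()`): a six-axis rigid bone
match — closed-form initialization from the bone mask's first and second
moments (the bone moves rigidly, so centroid and principal axes
determine the transform), refined by restarted Nelder-Mead on the
mismatch of box-blurred mask indicators — followed by a translation of
the daily prostate centroid onto the planning isocenter. The isocenter
is the planning prostate's geometric centre measured with the same
centroid estimator, so identical anatomies yield exactly zero
correction, and the prostate-centring step absorbs any residual
translation left by the bone match. Registration recovers synthetic
set-up errors to a few hundredths of a millimetre and of a degree at
CT-like resolution; the trial pipeline therefore runs the closed-form
stage only (`align_refine = 0`).

Fraction doses are mapped onto the planning grid by trilinear pull-back
through the generator's known deformation (`map_dose_to_reference()`) —
the deliberate replacement of a proprietary deformable-registration
algorithm by ground truth, which removes an uncontrolled component from
the evaluation; a different registration can be plugged in through the
same interface. Accumulated DVH indices are computed by direct
composition — the fraction dose is evaluated exactly at the mapped
positions of the planning structure voxels — because resampling through
a coarse intermediate grid measurably biases accumulated D99 near
gradients; the gridded pull-back remains the interchange artifact. No
energy/mass correction is applied (the deformations
are near-volume-preserving, and plain dose interpolation is what
commercial accumulation tools do). `accumulate_dose()` sums the 21
mapped fraction doses and records provenance; fractional (worst-case
style) evaluation scales a single fraction by 21
(`scale_fraction_dose()`), which refuses already-scaled input.

## The trial

`run_trial()` builds each patient (seeded geometry), fits the original
robust plan, and simulates the requested strategies fraction by
fraction (`run_strategy()`): sample the daily anatomy, align, compute
the nominal-scenario dose of the fraction's plan (the set-up error is
already realized in the anatomy; robustness scenarios exist only inside
the optimizer and the robustness evaluation), evaluate the x21-scaled
fractional DVH indices on the daily structures, map and accumulate.
NART uses the original plan throughout; DART re-places spots and
re-optimizes weights on every aligned daily anatomy with the same goals
and the same 3 mm / 3.5 % robust setting. DART contours are the
generator's ground truth (a boundary-noise sensitivity mode is a
deliberate non-default). A failed re-optimization would fall back to
the original plan with the fraction flagged goal-failed, never silently
skipped.

Evaluation indices: CTV/prostate/SV D99; rectum Dmax, V30, V50, V60;
bladder V30, V60 and V63 in millilitres (the absolute index that is
robust to a truncated bladder field of view; the synthetic bladder is
never truncated, the index is kept for comparability). Clinical D99
goals sit at 95 % of prescription (59.85 Gy(RBE)); rectum Dmax < 66
Gy(RBE) and bladder V63 < 10 ml complete the clinical set.
`summary()` on a trial recomputes cohort means, achievement rates,
paired t-tests (fractional pairs by patient-fraction, accumulated by
patient) and McNemar tests on the paired pass/fail flags (exact
binomial below 25 discordant pairs, chi-square `(b-c)^2/(b+c)` without
continuity correction above).

DVH curves are cumulative with 0.05 Gy bins; D-indices interpolate the
curve linearly (bin width keeps interpolation error far below the goal
margins); Dmax is the exact voxel maximum. `gamma_analysis()` is global
gamma: dose differences normalized to the reference maximum, a 10 %
low-dose cutoff, and a sub-voxel search lattice at half the
distance-to-agreement out to three times it — all three conventions are
arguments, since gamma implementations differ exactly in these knobs.

## Numerical profiles and problem sizes

Two working scales are used throughout the package's own experiments:

* single-plan work: 3-4 mm grids, 6 mm spot sigma, 10 mm layers —
  a plan in a few seconds;
* the cohort profile (`trial_config()` defaults): 23 patients x 21
  fractions on a 6 mm grid with an 8.5 mm sigma / 13 mm lattice and a
  reduced optimizer budget (4 chunks of 25 L-BFGS-B iterations),
  chosen so a full daily-adaptive cohort simulation runs on a single
  desktop core in roughly ten minutes. The directional property checks
  use a further-coarsened 7 mm profile over ten patients.

Coarse grids trade DVH precision for throughput: with ~200 CTV voxels
the D99 estimate moves in ~0.3 Gy steps, which is why cohort-level
claims are made on means over patients, never on single instances.
At the cohort profile the in-target homogeneity is poorer than clinical
plans achieve (CTV Dmax can exceed the 110 % planning goal on the
pelvic phantom even though coverage and OAR constraints are met); the
water-box validation phantom, with the default finer profile, meets
both D99 and Dmax goals.

## What the synthetic cohort does and does not show

The generator reproduces the *statistical envelope* of daily pelvic
anatomy — per-organ volume-change distributions including their
right-skewed exceedance fractions, the SV-filling coupling mechanism,
rigid set-up error — with exactly known correspondence. It does not
emulate CT physics (noise, beam hardening, HU texture), gas pockets or
locally irregular rectal distension, intra-fraction motion,
contouring variability (unless the noise mode is enabled), bladder
field-of-view truncation, or inter-fraction trends (time drifts);
days are exchangeable by default. Passing the acceptance suite
therefore demonstrates that the *pipeline logic* — robust planning,
alignment, recalculation, accumulation, scoring — reproduces the
direction and scale of the clinical findings under a faithful
statistical model of anatomical change, not that the dose engine or
the phantom is clinically accurate. Quantities that depend on the 23
real patients' anatomies (absolute OAR indices, NART achievement
percentages) are checked as directions and orderings, not values.

## Known limitations

* The Bragg parameterization and beam model are qualitative; no nuclear
  halo, no divergence, no measured depth-dose data.
* DVH surrogates in the optimizer are smooth approximations; a plan can
  satisfy the surrogate while marginally violating the exact index
  (the final plan reports the exact values).
* The bone-match refinement assumes the bone moved rigidly — true here
  by construction; with deforming bone the moment initialization would
  need a robust loss.
* Accumulated-dose evaluation inherits the trilinear smoothing of the
  pull-back; on 6 mm grids this is visible as a fraction of a Gy in
  steep-gradient structures.
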
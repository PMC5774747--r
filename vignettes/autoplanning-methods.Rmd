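---
title: "Automated inverse planning by stepwise DVH reduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated inverse planning by stepwise DVH reduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

autoplanr is a self-contained research engine for automated inverse
treatment planning. Its core is a controller that starts from the best
achievable target plan and then buys organ-at-risk (OAR) sparing with
target-dose homogeneity, one controlled step at a time, until a prescribed
heterogeneity budget is spent. This vignette describes the models, the
controller, the numerical choices, and what the synthetic phantoms do and
do not demonstrate.

## The optimization model

### Dose model

Dose is linear in the fluence: `d = D x`, with `x >= 0` the per-beamlet
fluence weights and `D` a sparse dose-influence matrix. `D` is computed
with a pencil-beam model in homogeneous water: beamlet `b` contributes to
voxel `i`

    D[i, b] = C * exp(-mu * depth) * exp(-r^2 / (2 * sigma_p^2))

where `depth` is the water-equivalent path length from the body entry
along the beamlet axis, `r` the lateral distance from the axis,
`mu = 0.005 / mm` (an effective attenuation typical of a 6 MV beam),
`sigma_p = 0.6 *` beamlet width, and `C` calibrated so a unit-fluence
beamlet deposits 1 Gy on axis at 100 mm depth. Entries below `1e-4` of a
beamlet's maximum are truncated to zero; on the reference phantom this
perturbs any voxel dose by well under 0.5%.

This is a deliberately simple, differentiable stand-in for a clinical
dose engine: the controller above it is dose-model-agnostic, and a
transparent linear model keeps every controller property testable.
Arc delivery is approximated by 36 equispaced static beams (configurable);
beamlets are parallel rays on a 5 mm lattice wide enough to cover the
target plus a 10 mm margin. The 5 mm width is a typical fluence
resolution; the isocenter is the target centroid.

### Objectives

All objectives are weighted, volume-normalized quadratic penalties. For
objective dose `d_obj`, weight `w`, and voxel set `V` of the bound
structure,

    F = w * sum_{i in V'} ((d_i - d_obj) / d_obj)^2 * dv_i

with `dv_i` the voxel volume divided by the structure volume, so small
and large structures contribute on the same scale. The residual set `V'`
depends on the kind: voxels above `d_obj` (overdose penalty, used for
maximum-dose and DVH-point objectives), below it (minimum dose), all
voxels (uniform dose), or the structure mean (one-sided mean-dose
penalty; rings and OARs only ever need a downward pull, so a mean below
`d_obj` is free). Gradients are exact and analytic; the fluence-space
gradient is `t(D) %*% g`.

The overdose penalty deliberately includes *every* voxel above `d_obj`,
not only the hottest fraction; a DVH-point objective's fractional volume
records which DVH point the controller is tracking but does not cap the
penalized set.

### Inner optimizer

`optimize_fluence()` is a monotone projected-gradient method: the trial
step is the Barzilai-Borwein spectral step, projected onto `x >= 0` and
accepted under an Armijo backtracking line search, so accepted objective
values never increase. The inner cycle stops after 100 iterations or when
the composite objective changes by less than `1e-4` between accepted
iterates. The tolerance is interpreted as an absolute change (the
composite objective is dimensionless and of order 0.01-1 in practice);
it is configurable for users who prefer a relative reading. DVH-point
objectives make the problem non-convex in general; like clinical systems
we accept locally optimal fluences. On convex (all-uniform) instances the
solver agrees with a generic bound-constrained quasi-Newton reference to
within 0.1% in objective value, which the test suite checks.

## The planning controller

`run_autoplan()` executes the automated loop:

1. **Rings.** Three concentric shells (default 10 mm thick, starting 5,
   35 and 55 mm from the target surface) are generated to force dose
   fall-off. Distance is measured from voxel centres to the nearest
   target-surface voxel centre; rings exclude targets and each other but
   may overlap OARs, mirroring common planning practice.
2. **Initial plan.** Targets get minimum/maximum/uniform dose objectives
   at `1.00 / 1.07 / 1.02` times the prescription (weight 100); each ring
   gets a maximum and a mean dose objective (weight 80) at fixed
   fractions of the prescription that step down with ring index
   (0.95/0.70/0.45 max, 0.60/0.35/0.15 mean — the rings' purpose is a
   monotone fall-off; these fractions are engine defaults exposed in the
   configuration). The fluence is optimized against these objectives
   only and normalized so that D95 of the target equals the prescription
   (35 Gy to 95% in the default configuration). These objectives are
   never altered afterwards.
3. **DVH sampling.** Each OAR's cumulative DVH is read at five
   equispaced fractional volumes from 1% to 70%, seeding one DVH-point
   objective per point (weight 1).
4. **Scaling.** On the current dose, each OAR objective dose is re-solved
   (bisection; see below) so that its objective value equals 1.05 times
   the largest target objective value. A per-OAR priority multiplier
   (default: none) multiplies that target value: a higher-priority organ
   is pushed to a lower objective dose and hence spared harder. New
   objective doses are clamped never to increase across cycles.
5. **Loop.** Re-optimize from the uniform reset fluence with all
   objectives, renormalize to the prescription, measure the population
   standard deviation of the target dose relative to the prescription,
   and either stop (once it reaches 5%) or rescale the OAR objectives and
   repeat, up to a safety cap of 20 cycles.

The delivered plan is the last one whose heterogeneity stayed *below*
the limit (keep-best-feasible): the loop intentionally overshoots by one
cycle to find the boundary, then returns the final feasible plan, so the
delivered plan always satisfies the criterion. Renormalizing after every
inner optimization keeps the comparison across cycles well-posed; it is
exact because the dose model is linear.

### Root-finding for objective doses

For an overdose objective on a fixed dose distribution, `F(d_obj)` is
continuous and strictly decreasing wherever positive, so
`F(d_obj) = target` has a unique root when one exists. It is found by
bisection on `(0.01 Gy, max structure dose]` to an absolute tolerance of
`1e-6 * target` within at most 200 bisections. If even the 0.01 Gy floor
cannot produce the requested value (the organ already receives almost no
dose) the floor is kept and flagged; an all-zero structure dose
short-circuits without root-finding. A round-trip test confirms that
evaluating at the root reproduces the requested value to `1e-4`
relative.

### Design choices that were genuinely open

* **Heterogeneity denominator.** The termination statistic is the
  population standard deviation over target voxels divided by the
  *prescription* dose (not the mean target dose). The same shared
  implementation feeds the controller and the reported metrics.
* **Priority direction.** The priority multiplier acts on the scaling
  target, not on the objective weight: weights stay at 1 for all OARs
  while a priority of 2 doubles the objective-value target and therefore
  the downward pressure. Acting on the weight instead would change the
  meaning of the 1.05 scaling contract.
* **Stopping sense.** Heterogeneity grows from about 1-2% toward the
  limit; stopping at the last feasible plan (rather than the first
  exceeding one) guarantees the delivered plan meets the criterion.
* **Clamping.** Re-solving on a new dose distribution can suggest a
  higher objective dose than the previous cycle's; the clamp enforces the
  monotone reduction that defines the method.
* **Ring overlap.** Rings are not cropped to avoid OARs; OAR objectives
  and ring objectives coexist on shared voxels.

## The reference phantoms

`build_reference_phantom()` emulates the geometric situation of
pancreatic SBRT: a ~30 mm target in the middle of a water-equivalent
body, an abutting serial organ ("duodenum", surface gap 2 mm), a distant
serial organ ("cord", over 60 mm posterior), and two lateral parallel
organs ("kidney_l/r"). The 2D preset (96 x 96 x 1 voxels at 4 mm) is the
default study object — it keeps a full planning run around two seconds
so every end-to-end property is tested on it; the 3D preset
(64 x 64 x 32) exists for volumetric realism. The seed jitters
non-critical placement (the abutting organ's direction, small lateral
shifts) while the abutment gap and clearances are held fixed, so every
seeded phantom poses the same planning problem.

What the phantom does *not* emulate: CT density heterogeneity, realistic
organ shapes and volumes, inter-patient anatomical variation, arc
deliverability, or a clinical dose engine. Passing tests demonstrate the
controller's contracts (monotone DVH reduction, coverage conservation,
termination, sparing direction), not clinical dose accuracy; absolute
OAR doses from the pencil-beam model should not be compared with
clinical values.

## Behaviour on the reference phantom

On the 2D reference phantom with the default configuration the initial
target-plus-rings plan reaches a relative target-dose standard deviation
of about 1.8%; the reduction loop then raises it stepwise (roughly
1.8 → 2.0 → 2.3 → 2.8 → 3.4 → 4.2% over six cycles before the
termination overshoot), while the abutting organ's near-maximum dose
falls to a fraction of its initial value. The number of cycles to
termination is an emergent property of the scaling factor, the objective
weights and the dose model — engines whose inner optimizer equilibrates
differently will traverse the heterogeneity budget in fewer or more
steps (we verified the count is insensitive to inner-loop convergence
quality by re-running with a 20-fold iteration budget). The monotone
contracts, not the cycle count, are the method's invariants.

## Plan metrics and comparison

`plan_metrics()` tallies D95, D5, D2%, Dmean, Dmax, an absolute-volume
D_2cc (voxel count rounded half-up), and the dose standard deviation per
structure. `D_v` is computed sort-based (dose of the hottest `v%`,
linearly interpolated between ranks), which is exactly homogeneous under
dose rescaling — this is what makes prescription normalization exact.
The binned cumulative DVH (default 0.05 Gy bins, exact voxel counting)
agrees with the sort-based indices to within one bin width.
`compare_plans()` reports normalized dose-index ratios
(comparison/reference; below unity means less dose) and, across a cohort
of paired plans, an exact Wilcoxon signed-rank p-value per structure and
index.

## Problem sizes used in the tests

The packaged suites run the full controller on the 2D preset (9216
voxels, 360 beamlets), oracle comparisons on toys of up to 200 voxels,
exhaustive signed-rank enumeration on 6 pairs, and the geometry-response
property on three 64 x 64 variants; the complete suite finishes in well
under a minute. These sizes were chosen so that every oracle can be
brute-force exact while the phantom still exhibits the full controller
dynamics.

## Known limitations

* The pencil-beam model ignores scatter kernels, heterogeneity and
  beam-hardening; it is calibrated, not commissioned.
* Arcs are approximated by static beams; no deliverability constraints.
* DVH-point objectives make the inner problem non-convex; different
  optimizers may find different local trade-offs, and the cycle count to
  termination is engine-dependent (see above).
* The signed-rank comparison assumes no ties among paired differences
  (exact enumeration otherwise falls back to the usual approximations).
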
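---
title: "Fuzzy-guided inverse planning: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-guided inverse planning: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyplan)
```

This vignette is the package's account of its science: the models it
implements, the tunable parameters and why their defaults are what they are,
what the synthetic generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## 1. The planning model

All doses in the package are relative, in percent of the target (PTV)
prescription; no absolute dosimetry (Gy) is attempted.

**Dose engine.** A 2D pencil-beam model builds a dose-influence matrix
$A$: for each gantry angle, parallel beamlets cover the target's lateral
projection, and a beamlet deposits
$\exp(-\mu\,\mathrm{depth}) \cdot \exp(-\ell^2 / 2\sigma^2)$ per unit fluence
at each body voxel ($\ell$ the lateral distance to the beamlet axis, depth
measured from the body surface along the beam). Dose is linear in fluence,
$d = Af$, $f \ge 0$.

**Objective.** The optimizer minimizes the standard quadratic dose-volume
cost

$$F = \sum_{i \in \Omega_{PTV}} WF^{min}_{PTV}\,[d^{min}_{PTV} - d_i]_+^2
    + \sum_{x} \sum_{i \in \Omega_x} WF^{max}_{x}\,[d_i - d^{max}_x]_+^2 ,$$

with $[z]_+ = z H(z)$ the positive operator: underdose is penalized in the
target only, overdose in target, OARs and normal tissue. Minimization is
projected-gradient descent with backtracking, so the objective is
non-increasing across accepted iterates by construction.

**Controller.** Six Takagi–Sugeno networks — one per plan parameter in
$\{PD, WF\} \times \{PTV, OAR, NT\}$ — map the relative dose deviations
$\Delta D_x = (D_x - PD_x)/PD_x$ (with $D_x$ the structure's mean dose
derived from the recorded DVH) to a relative parameter change. Each network
has five layers: sigmoidal memberships
$\mu = 1/(1 + e^{-a(\Delta D - b)})$ for the labels low/high of each input
(12 premise parameters), product-t-norm firing strengths over eight rules,
normalization, first-order consequents
$f_i = c_{i,0} + c_{i,1}\Delta D_{PTV} + c_{i,2}\Delta D_{NT} +
c_{i,3}\Delta D_{OAR}$, and the weighted sum $f = \sum_i \bar w_i f_i$.

**The loop.** Starting at the most restrictive prescription level with unit
weights, the loop alternates fluence optimization and multiplicative updates
$TPP \leftarrow TPP \cdot (1 + \Delta TPP)$ (clamped to a positive range),
declares a plateau when

$$\frac{\sum_x \big(D_x^{(n+1)} - D_x^{(n)}\big)^2}
       {\sum_x \big(D_x^{(n)}\big)^2} < T, \qquad T = 0.01,$$

then evaluates the level's goals and, on failure, advances to the next
level. The plateau compares doses after consecutive parameter
*modifications*, so the earliest possible stop is after the second
modification (three optimizations). Plans are scored on mean doses: a level
is met when the target mean sits on its prescription (within 0.05 percentage
points of percentage-to-goal, absorbing the normalization round-off) and
every OAR and the normal tissue are at or below their targets.

Two dose views coexist deliberately. The controller always sees the *raw*
optimizer dose — that is what its parameter moves actually change — while
goal evaluation and reporting use the finalized dose, rescaled so the mean
target dose equals the prescription (the benchmark tables show a mean target
dose of exactly 100 at every level, which is a plan-normalization
convention). Mixing the two (normalizing before the controller) would blind
the controller to target underdosage.

## 2. Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `engine_kernel()$mu` | 0.003 | 1/mm | depth falloff; milder than a megavoltage depth-dose slope because the 2D engine has no scatter buildup |
| `engine_kernel()$sigma_mm` | 4 | mm | beamlet penumbra, one voxel width |
| `gip_control()$T` | 0.01 | — | plateau constant of the convergence test |
| `gip_control()$max_inner` | 25 | iterations | per-level cap; plateaus in 3–6 in practice |
| `gip_control()$ptv_margin` | 0.05 | fraction | target upper objective at 105% of its lower one, motivated by the usual 107%-of-prescription maximum-dose goal |
| `gip_control()$tpp_floor/ceiling` | 0.01 / 1000 | — | clamp range of the multiplicative update |
| `anfis_control()` | lr 0.01, L2 β 0.015, batch 16, ≤500 epochs, patience 20, split 0.6 | — | the training protocol of the study this package re-implements |
| `fis_defaults()` | a₀ 10, δ_wf 0.1, δ_pd 0.05 | — | static controller: crisp memberships centered at zero deviation; moderate constant moves of 10% (weights) and 5% (prescriptions) per iteration |

The mapping from the six plan parameters to the engine objective is not
dictated by the planning model and is a package choice: the target's lower
objective is `PD_PTV` and its upper one `PD_PTV × 1.05`; each OAR and the
normal tissue get their `PD` as upper objective; and each structure-level
weight is spread over the structure's voxels (`WF_x / |Ω_x|`), so a unit
weight penalizes the structure's *mean* squared violation. Without the
per-voxel spreading, the normal tissue (thousands of voxels) numerically
swamps the target (a few hundred), the optimizer parks the target far below
prescription, and the controller's deviations no longer describe the plan
being evaluated. The voxel-sum objective itself is implemented exactly as
written above; the spreading lives in the mapping.

## 3. The synthetic phantoms and what they do and do not emulate

`phantom_cshape()` builds a C-shaped target (elliptical annulus with a 100°
posterior opening) around a circular core OAR; `phantom_prostate()` an
elliptical target with posterior rectum and anterior bladder. Geometry
defaults scale with the grid (target outer radius ≈ 0.17 of the grid side).
`phantom_variants()` emulates a cohort of modified phantoms along three
modes — shifting the OAR(s) toward/away from the target, scaling the
target's height and width (0.8–1.3 by default), and stretching it vertically
into a taller, narrower shape — with invariant-violating draws redrawn.
Variant generation is a pure function of (base, n, seed).

The scripted planner (`scripted_policy()`) stands in for the human planner
whose moves would form the training data. It is proportional and
asymmetric: a structure violating its prescription gets a strong weight
push (gain 2) and a prescription push/tighten (gain 0.3); a satisfied
structure's weight is relaxed only gently (gain 0.2) and its prescription is
ratcheted *down* toward the achieved dose (gain 0.5) — the
as-low-as-reasonably-achievable instinct that converts slack into a tighter
constraint on the next pass. Asymmetry matters: the heuristics this system
encodes are stated as increases on violation, not as symmetric relaxation,
and the ratchet is what sustains OAR-sparing pressure once the nominal
prescription is met. First-order consequents can represent a proportional
policy exactly, which is why these trajectories are learnable by the
networks. The static controller, by contrast, is the symmetric untrained
prior — constant ±10%/±5% moves whichever side of the prescription the
structure is on — mirroring a hand-built system before training reshapes it.

What passing tests on these phantoms show: that the controller loop,
training pipeline and evaluation machinery behave as specified, and that
training on better-than-static trajectories yields a better-than-static
controller *within this toy world*. What they do not show: performance on
real anatomy, 3D dose, a commercial optimizer, or human-planner variability
— none of which the package models.

**The 2D dilution effect and the `toy2d` prescription preset.** In a
volumetric body, beam entrance/exit dose is diluted over many slices and
normal-tissue mean doses of ~10% of prescription are routine. In a single
slice, every beam's track lies in the evaluation plane: the normal-tissue
mean is bounded below by roughly
(target width × path length) / normal-tissue area ≈ 20–25% for the default
geometry, regardless of the controller. The five-level evaluation ladders
with normal-tissue targets of 10–15% are therefore kept for reproducing the
published benchmark tables (`gip_levels(..., "evaluation")`), while planning
studies on the packaged engine use the `"toy2d"` preset, which keeps the OAR
ladder and raises the normal-tissue targets to the geometrically attainable
22–30% range. This is a property of slice geometry, not a calibration to any
particular controller: both controllers face the same ladder.

## 4. Training

Samples are built from consecutive trajectory snapshots: inputs are the
three deviations at $t$ (mean doses derived from the stored dose-at-volume
records on the 0–100% by 10% grid, trapezoidal rule), outputs the six
relative parameter changes between $t$ and $t+1$. Splits are at the phantom
level, 60/40, so no phantom leaks across sides. Each level pass is treated
as its own trajectory: the jump between levels is a prescription reset, not
a planner move, and must not become a training sample.

Training is plain mini-batch Adam on
$\mathrm{MSE} + \beta \sum \theta^2$ over premise and consequent parameters
($\beta = 0.015$), with learning-rate halving on training-loss plateau and
early stopping on validation loss (patience 20); the returned network always
carries the best-validation parameters, and the reported history is the pure
MSE. Gradients are analytic (layer-by-layer differentiation) and are checked
against central finite differences to 1e-5 relative in the test suite. A
`shared_consequents` option ties the 32 per-rule coefficients to 4 shared
ones; the default is per-rule, which is what the eight-rule first-order
architecture implies.

**A known limitation: weight decay bounds recoverable accuracy.** With the
L2 term inside the loss over *all* 44 parameters, the minimizer of
$\mathrm{MSE} + \beta\|\theta\|^2$ is displaced from any noise-free teacher
by a bias that grows with the teacher's parameter norm; for teachers in the
realistic range the resulting validation MSE floor sits at a few $10^{-4}$,
and early stopping's best-epoch snapshot does not go materially below it.
Exact teacher recovery therefore requires $\beta = 0$ (the suite
demonstrates recovery to below $10^{-4}$ without decay), while recovery
under the full protocol levels off above that; the acceptance suite measures
and reports both. This is a property of regularized estimation, not of the
optimizer.

## 5. Numerical choices and degenerate inputs

* **Rule table.** The published eight-rule listing assigns the same
  antecedent combination to two rules and omits one of the $2^3$
  combinations; eight distinct rules require the full truth table, so the
  duplicate is replaced by the missing (target high, OAR low, NT low)
  combination. A welcome consequence of the complete table: with constant
  consequents the controller's output for a structure depends only on that
  structure's memberships, which makes the sign properties of the static
  controller provable (a cold target never lowers its own weight).
* **Degenerate rule activation.** If every rule fires with strength zero
  (possible only under saturated memberships), normalized strengths fall
  back to the uniform 1/8 so a planning run never halts; the standalone
  `normalize_strengths()` signals the condition instead.
* **Solver.** Projected gradient with Armijo backtracking, step growth 1.8×
  on acceptance, relative step tolerance 1e-6, cap 500 iterations (300
  inside the loop); warm starts reuse the previous fluence within and across
  levels (disable with `warm_start = FALSE`). Weights all zero is a valid
  objective (F ≡ 0); the initial fluence is uniform, scaled so the mean
  target dose equals the target's lower objective.
* **DVH conventions.** Cumulative DVH with $V(d)$ = fraction of voxels at or
  above $d$; $D_q$ is the minimum dose of the hottest $q\%$ (so D95 is a
  coverage dose); $V_x$ the fraction at or above $x$. Table reproduction
  rounds half away from zero to one decimal, with a $10^{-9}$ boundary guard
  so decimal half-values represented fractionally low in binary still round
  away from zero.
* **Cohort comparison.** Welch's unequal-variance t-test; the fully
  degenerate equal-constant case returns p = 1 by convention.
* **Multi-OAR sites.** The controller's OAR channel aggregates all OAR
  structures (union of voxels) for deviations and weights, while goal
  evaluation remains per-structure.

## 6. Problem sizes

The packaged studies run at desk scale by choice: 64×64 grids (4 mm voxels)
for phantoms and planning runs, 32×32 for unit-test fixtures; nine beams at
40° (C-shape) and seven at 50° (prostate, spanning 300° as specified for
that arrangement); cohorts of 18 variants (8 for trajectory recording, 10
for comparison) in the comparative study and 2,000 samples per network in
recovery studies. On one CPU the full test suite runs in minutes; nothing
in the method is specific to these sizes, and the same types support 3D
grids.

## 7. Known limitations

* Single-slice dosimetry (see the dilution discussion above); no
  heterogeneity, no MLC sequencing, no absolute dose.
* The scripted planner emulates, but cannot reproduce, human planning
  trajectories; distributional fidelity to any real planner is unverifiable
  by construction.
* The plateau test with $T = 0.01$ is dominated by the target term of its
  denominator, so levels conclude after a handful of parameter
  modifications; controllers therefore differ mainly through the quality of
  a few moves and the weight/prescription state they accumulate across
  levels — which is precisely where the trained controller's advantage
  shows.
* Weight decay at β = 0.015 bounds teacher-recovery accuracy (Section 4).
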
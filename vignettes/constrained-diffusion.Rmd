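---
title: "Constrained diffusion sampling with SHAKE projection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained diffusion sampling with SHAKE projection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shakediff)
```

This vignette is the package's account of its model, numerics and design
choices. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Model

The state is a conformation `x ∈ R^(3N)` (Cartesian coordinates, Å).
Generation integrates the reverse SDE
`dx = [f(x,t) − g(t)² ∇ log p_t(x)] dt + g(t) dW̃` with Euler–Maruyama from
the noise prior at `t = T` down to `t = 0`. Holonomic constraints
`σ_a(x) = 0` restrict the state to a manifold of codimension `A` whenever
the stacked gradient Jacobian `D_xΣ` (rows `∇σ_a`) has rank `A`; the
`rank_diagnostic()` report exposes this condition at run time, since rank
loss — not mere proximity of constraints — is what invalidates the
projection step.

Each sampler step interleaves four operations, in this order:

1. **Bound update.** The deterministic bound variables advance to the new
   normalized progress `τ ∈ [0, 1]` (`τ = 1 − t/T`; schedules are
   parameterized by sampling progress, not diffusion time, so the same
   schedule file works for either integration direction). Because the
   sigmoid interpolation gives the bound trajectory in closed form, the
   update evaluates that closed form rather than integrating an ODE — the
   deterministic component of the coupled system carries no integrator
   error and is invariant to step-size partitioning.
2. **Noise projection** (optional; default on for SHAKE). The increment
   `η` is replaced by `(I − Jᵀ(JJᵀ)⁻¹J) η`, removing the component along
   the active constraint gradients.
3. **Trial step.** The unconstrained Euler–Maruyama update.
4. **Constraint handling.** SHAKE projection onto the feasible region at
   the new `τ`, or a harmonic guidance nudge, or nothing.

## The projection

Residuals use the linear form `σ = value − target` (angular residuals
wrapped to `(−180°, 180°]`). The squared alternative `σ²` is available as
`form = "squared"` for comparison, but its gradient vanishes exactly on the
manifold, which degrades the conditioning of the multiplier system near
feasibility — the linear form is the default for that reason.

Each SHAKE iteration solves the coupled Gram system
`G λ = −σ`, `G_ab = ∇σ_a·∇σ_b`, by Cholesky with a Tikhonov fallback
(`ε = 1e-10 · tr(G)/A`) and applies `Δx = Jᵀλ = −Jᵀ(JJᵀ)⁻¹σ`, the
Gauss–Newton step onto the manifold. All constraints are corrected
simultaneously rather than swept Gauss–Seidel-style, so gradient
information couples across constraints. The Jacobian is re-evaluated every
iteration (full Newton-type behavior); `frozen_jacobian = TRUE` reproduces
the classic linearized variant. A backtracking halving of the step guards
against overshoot from strongly curved constraint surfaces. No mass
weighting is applied (unit masses): in the overdamped generative setting
there is no kinetic energy to partition.

Convergence is declared on the maximum absolute residual, with angular
residuals scaled by `angular_weight` (default 0.01, i.e. 1° counts like
0.01 Å) because the criterion mixes units; the tolerance default 0.003
(Å or weighted-degree equivalent) is the constraint-violation acceptance
used throughout the package. Non-convergence raises an error by default;
the sampler uses warn-and-continue, since a hard step during the schedule
ramp-in is recoverable — the trajectory log records what every step
actually achieved, and the feasibility guarantees quoted for the package
are the logged post-projection residuals.

Atom indices are 1-based everywhere — in the R API because R is 1-based,
and in config files matching SDF convention — so no index translation
exists anywhere in the package.

## Bounded constraints and schedules

A bounded constraint `lower ≤ value ≤ upper` is handled through its slack:
while the value lies inside the interval the constraint is *inactive* and
contributes nothing to the Jacobian or Gram matrix; outside, it becomes an
equality against the violated bound (the slack clamped at its limit). When
`lower = upper` the constraint is always active — the holonomic limit.
After projection the active set is re-resolved (up to 3 cycles) in case a
correction pushed a previously inactive constraint out of bounds.

Bounds tighten along the logistic `s(t) = 1/(1 + e^(−β(t − t₀)))` between
initial and final values; defaults `β = 10`, `t₀ = 0.5`. Two numerical
choices deserve note:

* **Unbounded initial bounds.** Linear interpolation from an infinite
  endpoint is ill-defined (it stays infinite until `s = 1` exactly, which
  a logistic never reaches on `[0, 1]`). Such bounds are therefore
  sentinels: inactive until the (endpoint-normalized) mixing exceeds
  `1e-6`, then tightening toward the final bound from a proxy placed
  `unbounded_width` away (default 20 Å/°, far outside the scatter of the
  built-in noise schedules, so the early regime is effectively
  unconstrained).
* **Endpoint normalization.** With `β = 10`, `s(1) ≈ 0.993`: the raw
  logistic would leave the proxy track about 0.7 % of its width short of
  the strict bound at the end of sampling — 0.13 Å for a 20 Å width, far
  above the 0.003 acceptance. The proxy track therefore uses the logistic
  rescaled to hit 0 and 1 exactly at `τ = 0` and `τ = 1`. Finite
  user-specified bounds use the raw logistic, matching its stated
  semantics (`s(t₀) = 0.5` exactly).

## Score models

Two analytic stand-ins replace a trained score network:

* `gaussian_mixture_score()` is exact: the forward process maps an
  isotropic Gaussian mixture to another Gaussian mixture, so the noised
  score is available in closed form (responsibility-weighted component
  scores, computed with log-sum-exp).
* `toy_boltzmann_score()` is an *approximation*: `−∇U(x)/T_eff(t)` with
  `T_eff = temperature + v(t)`, where `v(t)` is the forward-noise
  variance. For a unit-curvature harmonic well this annealing reproduces
  the exact noised score (the basis of the Ornstein–Uhlenbeck variance
  check in the test suite); for general energies it is a controlled
  surrogate, documented as such. Its norm is capped (`max_norm`, default
  100) as a trust region: a noisy trial point landing inside a
  Lennard-Jones core otherwise produces an unbounded score that
  destabilizes the explicit Euler–Maruyama step. Near equilibrium the cap
  never engages.

Noise schedules: variance-exploding (`σ_min = 0.01`, `σ_max = 5`,
geometric) and variance-preserving (linear `β` from 0.1 to 20). The VE
schedule's score is nearly flat early in sampling; the VP schedule keeps
the prior standardized and the score O(1) throughout, which matches
DDPM-type conformer models. The guidance-versus-SHAKE error-ratio
experiment uses VP for exactly that reason: under VE even the weak default
guidance can herd samples into the feasible basin before the score acts,
which misrepresents how guidance behaves alongside a real score model.

The score is treated as exact *on* the manifold: no Fixman/coarea density
correction for the dimensional reduction is applied. This is a known
limitation — constrained sampling reweights the manifold density relative
to the ambient one, and none of the package's quantitative claims depend
on that weight.

## Guidance baseline

Guidance descends the harmonic restraint `U = Σ (k_a/2) σ_a²` with step
`γ`, each constraint independently (no coupling solve). Defaults
`k = 10`, `γ = 1e-3`, one inner iteration per diffusion step: stable but
visibly under-correcting, the regime in which the baseline is normally
operated; all three are configurable. The tug-of-war test (two constraints
pulling a shared atom in opposite directions) shows the qualitative gap:
single-pass guidance cannot reach tolerance where the coupled SHAKE solve
converges.

## Synthetic data

`build_chain()` places atoms from bond lengths/angles/torsions by the
natural extension reference frame; measurements round-trip to 1e-8.
`make_two_mode_ensemble()` draws conformers from internal-coordinate modes
with Gaussian jitter (defaults: 5° on torsions, 0.005 Å on bonds, 0.5° on
angles — the scale of thermal scatter within one torsional basin of an
alkane at room temperature), recording ground-truth mode labels. The
butane fixture uses standard skeleton values C–C 1.53 Å, C–C–C 112.5°
(fixture constants, not fitted), giving an anti end-to-end distance of
3.91 Å; its staggered/eclipsed constraint sets put the end-to-end distance
at 3.9/3.15 Å plus the three covalent bonds at 1.53 Å — a lone end-to-end
constraint can drag bonded geometry out of shape, which the bond
constraints prevent. When a ramp schedule is supplied it applies to *all*
four constraints, so early sampling is genuinely unconstrained. The toy
chain energy (harmonic bonds and angles, Lennard-Jones on 1–4-and-beyond
pairs, LJ minimum at 3.9 Å) supports ordering-level statements only — the
anti skeleton is lower in energy than the eclipsed one — and is not a
force field.

What the generator does *not* emulate: excluded-volume interactions beyond
the toy LJ term, hydrogens' steric detail (the explicit-hydrogen butane
builder is geometric decoration), solvent, and any learned score's bias.
Passing tests therefore certify the constraint machinery — feasibility,
equivariance, convergence, mining recovery — on realistic geometry, not
chemical accuracy of generated ensembles.

## Experiment design choices

* **Problem sizes.** The feasibility run uses a 6-atom chain with 5
  distance constraints, 1000 steps, batch 16; the eclipsed-butane run 2000
  steps, batch 64; the error-ratio comparison a 10-atom chain with 10
  mined constraints, 500-step matched budgets, batch 32, 5 seeds with the
  median reported. These sizes give stable statistics while keeping the
  full suite in the minutes range on one CPU.
* **Perturbation profile.** The window in which SHAKE corrections
  concentrate tracks the schedule midpoint: bounds contract through the
  inter-mode distance gap around `t₀`, and corrections decay once the
  strict regime is reached. The profile experiment (corrections in the
  middle 40 % of steps versus the final 20 %, and SHAKE's mean versus
  guidance's) therefore uses a mid-transition schedule `t₀ = 0.25`; with
  `t₀ = 0.5` the contraction falls mostly after the middle window and the
  comparison would measure the window placement, not the method. The
  eclipsed-butane acceptance run keeps `t₀ = 0.5`.
* **Mining.** k-means with 10 restarts on the flattened upper-triangle
  distance vectors; Δ ties broken lexicographically by pair index; the
  cluster count is user-supplied (a silhouette helper is provided as a
  convenience, not part of the procedure). Mined bounded constraints use
  the within-cluster standard deviation as the interval half-width.
* **Degenerate geometry.** Interatomic distances below 1e-8 Å, and
  collinear angle/torsion frames, raise errors rather than returning an
  arbitrary gradient direction. Inside the toy energy *gradient* a
  collinear angle frame contributes zero force instead (the configuration
  set has measure zero in the dynamics and an error there would abort a
  long sampling run on a transient).

## Known limitations

* Angle/torsion constraints use standard analytic internal-coordinate
  gradients; mixing them with distances in one solve relies on the
  `angular_weight` unit bridge, which is a convention, not physics.
* The guidance comparison depends on the guidance defaults; stronger
  guidance narrows the error gap at the cost of larger perturbations to
  the dynamics.
* No Fixman correction (above); generated ensembles on a manifold carry
  the ambient score's bias.
* The reverse integrator is plain Euler–Maruyama; no predictor–corrector
  or probability-flow variant is provided.
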
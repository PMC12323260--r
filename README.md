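# shakediff

Exact enforcement of geometric constraints — interatomic distances, bond
angles, torsions — inside score-based diffusion sampling of molecular
conformations.

## The problem

Score-based diffusion samplers generate molecular conformations by
integrating the reverse stochastic differential equation

    dx = [f(x,t) − g(t)² ∇ log p_t(x)] dt + g(t) dW̃

from a noise prior back to the data distribution. Often one wants the
generated structures to satisfy *holonomic constraints* σ_a(x) = 0,
a = 1,…,A — fix an end-to-end distance to select a conformer, hold covalent
bonds at equilibrium lengths, pin a torsion. Adding a harmonic penalty
gradient ("guidance") only biases the dynamics: constraints are frequently
left violated, and the violations grow with the number of constraints.

`shakediff` instead projects every stochastic trial step exactly onto the
constraint manifold with a SHAKE-type Lagrange-multiplier solve. At each
iteration the multipliers come from the coupled A×A Gram system

    Σ_b λ_b (∇σ_a · ∇σ_b) = −σ_a ,   a = 1,…,A

and the correction `Δx = Σ_a λ_a ∇σ_a` (a Gauss–Newton step onto the
manifold) is repeated until `max_a |σ_a| ≤ tol` (default 0.003). Noise
increments can additionally be projected onto the constraint tangent space
via `P = I − Jᵀ(JJᵀ)⁻¹J`. Constraints may carry time-dependent bounds that
tighten along a sigmoid schedule, so early sampling explores freely and the
final steps enforce strict equality. The package also mines *consistent*
constraint sets from conformer ensembles: k-means clustering of flattened
pairwise-distance vectors, ranking pairs by the deviation of cluster means
from the global mean, Δ_k(i,j) = |x̄_k(i,j) − x̄(i,j)|.

Written for computational chemists and method developers who want exact
geometric control in generative sampling without retraining a score model:
any callable score plugs in, and analytic toy scores (Gaussian mixtures, an
annealed Boltzmann score over a toy chain energy) cover testing and method
comparison.

## Worked example: selecting a butane conformer

The end-to-end carbon distance of the butane skeleton distinguishes its
conformers: about 3.9 Å for the staggered (anti) form, about 3.15 Å for the
eclipsed form. `butane_fixture()` provides both constraint sets (the
end-to-end distance plus the three C–C bonds at 1.53 Å).

Projection alone — pull a distorted skeleton onto the staggered manifold:

```r
library(shakediff)
fx <- butane_fixture()
set.seed(1)
start <- conformation(fx$template$coordinates +
                        matrix(rnorm(12, 0, 0.3), 4, 3))
measure_distance(start, 1, 4)
#> [1] 4.578
pr <- shake_project(start, fx$staggered)
pr
#> <projection_result: converged in 2 iter, max residual 0.000365, |dx| 0.691>
measure_distance(pr$conformation, 1, 4)
#> [1] 3.9
```

Full constrained sampling — generate eclipsed butane with an annealed toy
Boltzmann score and a sigmoid bound schedule:

```r
fx <- butane_fixture(schedule = bound_schedule(beta = 10, t0 = 0.5,
                                               lower_final = 0,
                                               upper_final = 0))
score <- toy_boltzmann_score(
  function(x) toy_energy(vector_to_conf(x), fx$energy_params),
  function(x) toy_energy_gradient(vector_to_conf(x), fx$energy_params),
  temperature = 0.1, dim = 12L)
out <- sample_diffusion(score, fx$eclipsed,
  sampler_config(n_steps = 1000, method = "shake", batch_size = 8,
                 seed = 42),
  template = fx$template)
d14 <- vapply(out$samples, measure_distance, numeric(1), 1, 4)
mean(d14)
#> [1] 3.152
tail(out$trajectory$max_residual, 1)
#> [1] 0.00294
```

Every sample ends within the 0.003 Å acceptance of the 3.15 Å target, with
bonds held at 1.53 Å. Switching `method = "guidance"` runs the harmonic
baseline instead; `method = "none"` disables constraint handling. The
per-step trajectory log (`max_residual`, `shake_norm`, `guidance_norm`,
`iterations`) is the surface for method comparisons.

Constraint mining from an ensemble:

```r
specs <- list(  # anti vs gauche torsional modes of the skeleton
  list(bond_lengths = rep(1.53, 3), bond_angles = rep(112.5, 2),
       torsions = 180),
  list(bond_lengths = rep(1.53, 3), bond_angles = rep(112.5, 2),
       torsions = 65))
ens <- make_two_mode_ensemble(specs, M = 500, torsion_sd = 5, seed = 1)
f <- featurize_distances(ens)
labels <- cluster_conformers(f, 2, seed = 1)
report <- constraint_significance(f, labels)
set <- top_constraints(report, top_t = 5, cluster = 1)
```

A thin command-line wrapper with `sample`, `mine`, `demo` and `analyze`
subcommands lives at `inst/cli/shakediff.R`.

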
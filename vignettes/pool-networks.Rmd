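---
title: "Excluded particle flow on lane networks with finite pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excluded particle flow on lane networks with finite pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolflow)
```

## The model and its assumptions

`poolflow` treats a transport system as `N` one-dimensional lanes wired
through `M` reservoirs ("pools") of free particles. Each lane is a
ribosome flow model (RFM): a chain of `n` sites with normalised
densities `x_j(t) ∈ [0, 1]` and positive transition rates
`λ_0, …, λ_n`, where the flow from site `j` to `j + 1` is
`λ_j x_j (1 − x_{j+1})` — the mean-field form of simple exclusion, in
which flow stalls as the downstream site fills. The network structure is
a directed multigraph: pools are nodes, lanes are edges. A lane sourced
at pool `j` enters particles at rate `λ_0 G(z_j) (1 − x_1)`, where
`z_j ≥ 0` is the pool occupancy and `G` is the pool outflow function;
its exit flux `λ_n x_n` feeds its sink pool. Pool levels evolve by flux
balance. Three assumptions on `G` are enforced at registration:
`G(0) = 0` (an empty pool injects nothing), continuity, and strict
monotonicity (a fuller pool injects faster). The registry ships
`identity`, `tanh` (saturating competition) and `scaled_identity`
(`c·z`); custom closures are accepted after a grid check of the same
properties.

Every flux enters the equations once with each sign, so the total
occupancy `Q = Σ_j z_j + Σ_i Σ_j x_j^i` is a first integral: the network
is closed and trajectories live on level sets of `Q`. The model's core
structure — verified numerically by the test suite rather than proved
here — is that the flow is cooperative (the Jacobian is Metzler on the
state space, with irreducibility after arbitrarily short time), which
yields a unique, globally attracting steady state `e_r` on each level
set `{Q = r}`, a strictly increasing continuum `e_{r1} ≪ e_{r2}` for
`r1 < r2`, persistence (trajectories become uniformly separated from the
boundary: no site pins at 0 or 1, no pool empties), and entrainment:
if some or all rates vary continuously and `T`-periodically while
staying positive and bounded, every trajectory converges to a
`T`-periodic orbit.

Connectivity is validated at construction: every pool must feed at
least one lane and receive at least one lane's output, otherwise
particles would accumulate or drain irreversibly and the network is
rejected. A lane returning to its own source pool is accepted as a
multigraph self-loop but flagged with a warning, since it changes the
competition structure (entry and exit pressure on the same reservoir).

## Computing steady states

Two independent routes are implemented, and their agreement (to 1e-6
componentwise on random ensembles) is itself a standing test of both.

**Relaxation + Newton** (`find_steady_state()`). The dynamics are
integrated (lsoda, `rtol = 1e-10`, `atol = 1e-12`) in doubling time
chunks until the max-norm of the vector field drops below `1e-6`, then a
damped Newton iteration refines the algebraic system in which one pool
balance equation — redundant because the field components sum to zero —
is replaced by the conservation constraint `Q(e) = r`. Newton uses the
analytic Jacobian with the replaced row set to ones and step-halving
line search, and targets a residual of `1e-12`. Pure integration alone
cannot cheaply certify agreement to the fourth decimal; the Newton tail
costs a handful of iterations and certifies it.

**Spectral** (`solve_pool_balance()`). For a lane with effective entry
rate `c = λ_0 G(e_z)`, the steady-state profile has a closed form
through the `(n+2) × (n+2)` symmetric tridiagonal Jacobi matrix with
zero diagonal and off-diagonals `λ_k^{−1/2}`: with Perron eigenvalue `σ`
and positive eigenvector `ζ`, the densities are
`e_j = ζ_{j+2} / (λ_j^{1/2} σ ζ_{j+1})` and the lane flux is
`R = 1/σ²`. The only unknowns are then the `M` pool levels, fixed by
`M − 1` independent per-pool flux balances plus conservation. For the
bipartite two-pool network the solve is a nested bisection: the inner
loop finds the second pool level whose lane output balances the first
side's output (chain flux is strictly increasing in the effective entry
rate, so the root is bracketed and unique; if the second side's outflow
saturates below the target — possible with bounded `G` such as tanh —
the residual is treated as `+∞` and the outer interval shrinks), and the
outer loop bisects the first pool level on `(0, r)` against the
conservation residual, which is strictly increasing. No Newton
fragility, tolerance `1e-12` on both residuals. For `M ≥ 3` pools (and
for self-loop topologies) a damped finite-difference Newton on the `M`
pool levels is used, started from an even split of `r` and falling back
to a coarse ODE relaxation for its initial guess if needed; the general
solve is cross-validated against the ODE route in the tests. A zero
effective entry rate returns the all-zero lane profile directly rather
than building a singular matrix.

Eigen-decomposition uses the symmetric path of base `eigen()`; the
Perron vector's sign is fixed by forcing the first component positive,
and an any-nonpositive eigenvector aborts loudly since it can only
reflect numerical failure.

## Conservation, tolerances and degenerate inputs

Integration monitors `max_t |Q(t) − Q(0)|` and errors above
`1e-8 · max(1, Q(0))` instead of projecting back onto the level set:
silent projection could mask an incorrectly assembled field. Because
conservation is structural, the realised drift is typically at machine
precision even at loose integrator tolerances. The `r = 0` level set is
handled explicitly (the origin is the steady state). Time-varying rates
are supplied as closures of `t`; their common period, continuity proxy
and positive bounds are checked numerically on a 64-point grid at
construction, not assumed.

Period estimation (`estimate_period()`) discards the first half of the
simulated window by default, then for each component locates the first
local minimum of the mean-squared self-distance
`mean((x(t+L) − x(t))²)` below 5% of the squared amplitude and refines
it by parabolic interpolation; components with peak-to-trough amplitude
below `1e-8` are flagged constant. The self-distance criterion finds the
fundamental period directly (all multiples also vanish, but the first
qualifying minimum is returned), and on clean ODE output it resolves the
period well below the sampling interval.

## Classifying rate perturbations

For a two-pool network, increasing one rate `λ_k` of a lane always
lowers the density at site `k` and raises every downstream density of
that lane; the rest of the network responds in exactly one of five
patterns, identified by the directions of the two pool levels (both up;
source down / other up; both down; source exactly unchanged / other up;
source down / other exactly unchanged), with all non-perturbed lanes fed
by a pool moving together with it. `classify_effect()` measures these
directions with a relative tolerance of `1e-6` for the equality cases —
exact equality is measure-zero numerically, so those labels are rare and
strict cases win when a difference exceeds the tolerance — and verifies
the internal consistency of the pattern, returning `"other"` with
diagnostics only when the (exhaustive) case list is violated, which
signals numerical trouble. `sweep_rate()` tabulates pool levels and lane
outputs over an ascending grid and classifies each consecutive increase.
The reference sweeps use 10 points on `[0.2, 2]`, and the test surface
for these scenarios is the direction of each response, not particular
curve values. The both-pools-fall outcome requires a slow downstream
site on the perturbed lane: the competing-lanes scenario places rate
0.1 at site 7, without which the same sweep provably lands in the
both-pools-rise case (both versions are checked numerically).

## The stochastic validator

`simulate_exclusion()` runs the network as a continuous-time exclusion
process: sites hold 0 or 1 particle, hops `j → j+1` fire at rate `λ_j`
when site `j + 1` is empty, exits feed the sink pool, and entries
consume a particle from the source pool at rate `λ_0 G(z)` with `z` the
current integer pool count. The implementation uses a direct
(Gillespie) event scheme over the exponential hopping clocks, which is
statistically identical to a next-reaction scheme whose pending clocks
are redrawn whenever an enabling condition or pool level changes —
exponential clocks are memoryless, so redrawing is exact. Runs start with the particles in the
pools (even split by default) and an empty lattice, "steps" are events,
the first `1e4` events are discarded by default, and occupancies are
time-weighted averages (occupied duration over retained duration).
Integer particle conservation is asserted at the end of every run, and
identical seeds give identical results. The event loop is compiled
(Rcpp) and uses R's RNG, so `set.seed()` governs reproducibility.

The validation ensemble generated by `random_pool_network()` fixes
the reference validation conditions once: three
pools in a directed ring, lanes of 20/30/40 sites, entry rates 1, and
lane rates `b_i + U(0, 1)` with bases 0.5/2/1, at `Q = 6` particles.
The full-scale ensemble (250 networks × 1e7 events) is not desk
scale; the acceptance suite runs 10 networks × 1e6 events, which takes
under half a minute and yields a pooled Pearson correlation between
stochastic and mean-field site densities well above the 0.85 bound it
asserts. A separate property test checks the mean-field limit directly:
a lane fed nearly constant entry (a 200-particle pool through
`G(z) = z/650`, effective entry ≈ 0.3) matches the isolated-lane
spectral profile to 0.02 at 1e6 events. That check is run in the
low-density regime deliberately: near the maximal-current regime
(effective entry ≈ 1 with unit rates) the mean-field approximation
itself carries a bias of a few percent on short lanes, which no run
length removes — a known limitation of the deterministic model, not a
bug in either simulator.

## What the synthetic generator does and does not emulate

The generator produces the wiring, rate ranges and particle counts of
the benchmark topologies; it does not emulate heterogeneous site
lengths within a lane, correlated rate disorder, time-varying
stochastic rates, or direct lane–lane coupling (lanes interact only
through pools, by design). Passing tests therefore demonstrate the
solvers' correctness and the mean-field/stochastic agreement under
these conditions; they do not certify the biological realism of any
particular rate calibration.

## Problem sizes and defaults

Defaults were chosen once for desk-scale reproducibility: integrator
tolerances `1e-10/1e-12`; relaxation switch at `1e-6` and Newton target
`1e-12`; entrainment runs of 30 forcing periods at 100 samples per
period; sweep grids of 10 points; MC runs of 1e6–1e7 events with 1e4
burn-in. The full test suite completes in under two minutes on one CPU.

## Known limitations

* The spectral route for `M ≥ 3` pools relies on a Newton iteration
  without a global bracketing guarantee; it is cross-checked against
  the ODE route, and falls back to relaxation for its starting point,
  but pathological topologies could in principle defeat it.
* `classify_effect()` is defined for two-pool networks; for more pools
  the directional theory constrains only the pools adjacent to the
  perturbed lane, and the package reports pool levels without a case
  label.
* The Monte Carlo simulator supports the three registered outflow
  function families, not arbitrary custom closures (the compiled core
  evaluates `G` itself).
* Equality cases of the perturbation classification are declared at
  tolerance and are thus heuristic labels, as any numerical
  implementation of measure-zero conditions must be.
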
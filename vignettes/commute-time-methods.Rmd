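---
title: "Commute time and the structure-function coupling of brain networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Commute time and structure-function coupling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(commutebrain)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic data emulate,
and the choices made where the design was genuinely open. It states no
empirical result that the test-suite and `scripts/acceptance.R` do not
themselves compute.

## 1. Signalling as a Markov process on the connectome

The core assumption is that a signal travelling the brain has no global
map: at each region it chooses the next tract in proportion to streamline
counts, `M = D^-1 A`. Everything else follows from this single premise.
The hitting time solves the one-step recursion `H_ij = 1 + Σ_{k≠j} M_ik
H_kj`; eliminating the self-consistency through the Laplacian `Γ = D − A`
gives the closed forms implemented in `hitting_time()` and
`commute_time()` (see the README for the formulas). Three independent
routes to the same quantity — the pseudoinverse closed form, the
fundamental-matrix mean-first-passage route (`mfpt_commute_time()`), and
brute-force random walkers (`simulate_commute()`) — are kept deliberately
separate so each can validate the others; the identities
`C = H + t(H)` and `C = Ω · ΣD` are asserted in the tests at `1e-8`
relative tolerance on random graphs.

Numerical choices:

* **Pseudoinverse.** Full symmetric eigendecomposition, dropping
  eigenvalues below `1e-10 ×` the largest. For a connected graph exactly
  one eigenvalue is dropped; this makes the treatment of the null space
  explicit instead of delegating it to generic SVD tolerances, and the
  operator builder cross-checks connectedness against an explicit
  component search (disconnected input is a hard error — commute time is
  undefined across components).
* **Symmetry tolerance.** Input matrices are symmetrized by averaging
  when the maximal asymmetry is below `1e-8`; anything larger is an
  error, because tractography matrices are symmetric by construction and
  silently repairing gross asymmetry would mask data corruption.
* **Scale invariance.** `M`, `H` and `C` are invariant under uniform
  rescaling of all weights (asserted in tests), so raw streamline counts
  need no normalization for the metric stage.

## 2. The comparison set

* **Communicability** is the factorially damped walk sum on the
  degree-normalized adjacency `A'_ij = A_ij / √(D_ii D_jj)`. The
  normalized-exponential formula admits two readings — a matrix
  exponential (walk series) or an elementwise scalar exponential. The
  communicability literature the formula descends from, and the phrase
  "scaling by the factorial of the path length", imply the matrix
  exponential, which is the default; the elementwise reading is retained
  behind `method = "elementwise"` so the two can be compared. The matrix
  exponential is evaluated spectrally (the normalized adjacency is
  symmetric), and a test checks it against the truncated series at
  `n = 30` terms to `1e-10`.
* **Search information** is `−log2` of the probability that a random
  walker follows the shortest path, with shortest paths computed on the
  tract-length graph (lengths are the physical distances; when absent,
  `1/A` is the documented fallback). The sign convention is
  positive-bits, so larger values mean a harder-to-find path; downstream
  comparisons then treat search information and commute time uniformly as
  distance-like (their additive inverse is taken before correlating, and
  the flip is recorded per report). Dijkstra ties are broken by
  lexicographic predecessor index so results are identical across
  platforms. The raw matrix is asymmetric; pair-level comparison uses the
  mean of the two directions.
* **Connectivity** (the raw matrix) is the edge-centric control.

## 3. The mean-field Ising simulator

`run_ising()` implements spins on regions with energy
`E = −λ Σ_ij A_ij s_i s_j` (both orderings counted, so the two-spin
system has `⟨s₁s₂⟩ = tanh(2λ)` — the exact enumeration used in the
tests). Parameters, with defaults and reasons:

| parameter | default | meaning |
|---|---|---|
| `lambda` | supplied | global coupling strength (dimensionless); never fitted here |
| `n_steps` | 5000 | recorded frames; enough to sample the equilibrium regime at desk scale |
| `flip_fraction` | 0.15 | fraction of regions proposed per timestep |
| `burn_in_fraction` | 0.2 | initial frames discarded before FC |
| `adjacency_normalization` | `max_one` | divide A by its largest off-diagonal entry |
| `seed` | supplied | full trajectory is bit-reproducible |

Open design points and how they were resolved:

* **Sequential vs joint acceptance.** Proposing 15% of spins as one
  joint Metropolis move would have vanishing acceptance at the coupling
  strengths of interest; flip proposals are therefore accepted
  one-by-one (sequential single-flip Metropolis within each timestep),
  which matches the per-node acceptance arithmetic
  (`exp(−ΔE)` for a single destabilizing flip). The joint variant cannot
  reproduce single-flip acceptance probabilities and is not implemented.
* **Adjacency normalization.** Raw streamline counts (10²–10⁵) with
  λ of order one would freeze the dynamics instantly; the λ scale only
  makes sense on a normalized matrix. Division by the maximum weight is
  the default and alternatives (`mean_one`, `none`) are exposed.
* **Burn-in.** FC may be computed on the whole series or after
  discarding the initial fraction; discarding is the default
  (`discard_burn_in = TRUE`) since the initial quench from random spins
  is not equilibrium, and the literal whole-series option is a flag.
* **HRF.** The hemodynamic kernel is the canonical double-gamma with
  positive lobe peaking at 6 time-units, undershoot at 16, ratio 1/6,
  length 32, unit sum, sampled at one Ising timestep per frame (no TR
  mapping is imposed); all parameters are serialized with every output.
  Convolution is causal and linear — superposition is asserted to
  `1e-10`.

### Stationarity checks on correlated frames

The two-spin system is checked against its Boltzmann distribution two
ways: the time-average `⟨s₁s₂⟩` within ±0.02 of `tanh(2λ)` for
λ ∈ {0.5, 1, 2}, and a χ² goodness-of-fit of the empirical 4-state
distribution. Metropolis frames are strongly autocorrelated, which
invalidates an iid χ² on raw frames at any λ > 0; the test therefore
thins the chain (1 frame in 200, comfortably beyond the measured mixing
time at λ = 0.5) before the χ², which is the standard Markov-chain-aware
form of the check. At λ = 2 the chain essentially never leaves one
aligned basin at desk scale — the time-average check still applies
(`tanh(4) ≈ 0.9993`), but a state-distribution test would need
astronomically long runs and is run at λ = 0.5 only.

## 4. What the synthetic connectome emulates

`generate_connectome()` draws 84 regions (Desikan–Killiany scale) as two
hemispheric slabs in 3-D space and emulates the features of
tractography-derived matrices that this analysis actually depends on:

* **Geometry.** Tract length is the (curved, ×1.3) Euclidean distance
  between region centroids; inter-hemisphere tracts are therefore
  systematically longer.
* **Length bias.** Streamline counts decay exponentially with tract
  length (e-folding `length_decay = 15` mm) with log-normal scatter
  (`weight_log_sd = 1`), the well-documented bias of deterministic
  tractography; counts are integers ≥ 1 on the support.
* **Blocks.** The closest 35% of within-hemisphere pairs and 15% of
  between-hemisphere pairs are connected, making intra-hemisphere
  connectivity denser *and* stronger — the hemispheric block structure
  of real matrices. Homotopic pairs `(i, i + N/2)` carry no extra tracts
  by default: under-detection of homotopic connections is precisely the
  gap the tract-addition experiment probes.
* **Dominant bundle.** The strongest edge is calibrated so that the
  median region degree is `bundle_degree_ratio = 0.5` times the maximum
  weight. This pins the scale of the max-normalized adjacency — the
  matrix the Ising coupling actually sees — so that λ ≈ 6 sits near the
  ordering transition, the operating regime the simulation is meant to
  occupy. Without the calibration, a random draw lands at an arbitrary
  point of the phase diagram and the simulated function no longer
  resembles resting-state-like activity at the stated coupling.
* **Connectedness** is guaranteed by deterministic bridging, so every
  output satisfies the container invariants without repair.

What it does **not** emulate: empirical degree and weight distributions
in quantitative detail, spatially smooth parcel shapes, distance-
dependent noise in FC, subject-to-subject variability, or measurement
artefacts of either modality. Tests passing on these synthetic matrices
show that the *pipeline* behaves as designed under the stated
assumptions — not that real dMRI/fMRI data would yield the same
correlation values.

### A known dynamical limitation

At λ = 6 a quench from random spins is bimodal: most runs reach the
globally aligned state, whose structured fluctuations commute time
explains well, but a fraction settle into metastable
hemisphere-anti-aligned or partially ordered states with weaker
commute–FC correlations, and 5000 steps cannot escape them. The
replicate spread reported by `analysis/04_ising_structure_function.R`
and the acceptance script reflects this honestly; no re-initialization
or run-length tricks are used to hide it.

## 5. Monte-Carlo walkers

The walkers are kept free of linear-algebra shortcuts — they are the
independent oracle for the closed forms. Order 2 forbids immediate
backtracking (renormalized transition row); order 3 additionally
excludes the node visited two steps ago. When the constraint leaves no
admissible neighbour (a leaf), backtracking is allowed — the chain must
remain well-defined on every connected graph, and leaf behaviour is
otherwise unspecified. Each walk is capped at `1e7` steps; capped walks
are excluded and counted, never silently truncated. Each (pair, order)
gets its own RNG stream derived from the master seed, so per-pair
results are independent of evaluation order. Convergence is checked as
a property: the RMS error of the commute estimate decays as
`n_walks^-0.5` (slope asserted within ±0.2 over three decades).

## 6. Pair-level comparison machinery

Pair vectors are the off-diagonal upper-triangle in fixed row-major
order, optionally masked to intra-hemisphere pairs. Spearman ρ uses
average ranks for ties and the large-n t approximation for its two-sided
p-value (at `n = 3486` pairs the difference from an exact permutation
p-value is negligible, but it is an approximation and is documented as
such). Principal-mode truncation takes eigenvectors of the symmetric
matrix itself — no row centering, since FC matrices are treated
algebraically — with a deterministic sign convention
(largest-magnitude component positive); a centered variant exists but is
non-default. Rank defaults follow the use case: `k = 2` for
simulated-FC comparisons, `k = 1` for empirical-style data where the top
eigenvalue dominates. Hitting time and search information enter
pair-level comparison through their symmetrized means only; quartiles of
replicate distributions use linear interpolation (type 7).

## 7. Problem sizes

The test-suite and acceptance script run at sizes chosen to exercise
every claim at desk scale: exact identities on graphs up to N = 30;
Monte-Carlo agreement on 10 connectomes of N = 10–20 at 10⁴ walks per
pair; Ising exactness on the two-spin system at 1.25 × 10⁵ frames;
structure–function recovery on the default 84-region connectome with
10–20 replicate simulations of 5000 frames each. These sizes are the
package's own reproducibility choices; all of them are parameters the
user can raise.

## 8. Known limitations

* First-order Markov dynamics only; the second/third-order walkers exist
  to *measure* the effect of memory, not to replace the closed forms.
* λ is always supplied, never fitted to data.
* The Ising simulator records one frame per timestep with no TR mapping;
  absolute time-scales are arbitrary.
* The generator's realism is qualitative (see §4).
* Wilson–Cowan-style rate models are out of scope; the simulator
  interface (`connectome → trajectory → BOLD → FC`) is the plug-in point
  a richer model would use.
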
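---
title: "Markov state modeling of ion release: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state modeling of ion release: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionrelease)
```

## The model

`ionrelease` estimates the kinetics of an ion leaving a transporter
binding site from an ensemble of independent, unbiased trajectories.
The analysis assumes that on a suitable lag time the system's coarse
dynamics are Markovian in a discretized reduced space, so that a
transition probability matrix (TPM) estimated from many short
trajectories predicts relaxation on timescales far beyond any single
trajectory.

The chain of estimators is:

1. **Featurization.** Each frame is reduced to a small vector of
   physically chosen order parameters: four distances tracking the
   tagged ion (to the second bound ion and to three coordinating acidic
   residues), seven distances among the intracellular-gate residues, and
   the ion's water coordination number. Water-accessible cavities
   (extracellular vestibule/cavity, intracellular vestibule split into
   channel and cavity) are defined by distance and membrane-normal
   (z-axis) clauses around fixed reference atoms and counted per frame.
2. **tICA.** With `X(t)` the mean-centered feature vector, the
   instantaneous covariance `C = ⟨X Xᵀ⟩` and time-lagged covariance
   `C_TL(τ) = ⟨X(t) Xᵀ(t+τ)⟩` define the generalized eigenproblem
   `C_TL V = C V Λ` whose leading eigenvectors are the slowest linear
   reaction coordinates. Lagged pairs never span a trajectory boundary.
3. **MSM.** Projected frames are clustered (k-means++ seeding, Lloyd
   iterations); transitions are counted with a sliding window at lag τ′;
   the count matrix is symmetrized with its transpose and
   row-normalized, giving a reversible TPM whose stationary distribution
   is the normalized row-sum vector. Implied timescales
   `τ_i = −τ′ / ln λ_i` must be flat in τ′ for the model to be
   Markovian; the package scans a lag ladder with a
   trajectory-level bootstrap.
4. **GMRQ.** Hyperparameters (number of tICs, number of microstates) are
   scored by how well eigenvectors learned on a training half
   diagonalize the TPM of a held-out half:
   `score = Tr[(VᵀSV)⁻¹(VᵀCV)]` with `S = diag(π_test)` and
   `C = S T_test`. When train equals test the score is the sum of the
   top eigenvalues, and it is bounded above by the number of scored
   modes — both properties are enforced in the test suite.
5. **TPT.** The forward committor `q` solves a linear boundary-value
   problem (0 on the bound set, 1 on the released set); the reactive
   flux `f_ij = π_i (1−q_i) T_ij q_j` is antisymmetrized to a net flux,
   decomposed into ranked pathways by iterated widest-path extraction,
   and aggregated over macrostates obtained by sign-based spectral
   lumping of the TPM eigenvectors.
6. **Thermodynamics.** Free energies are `−ln` of bin populations along
   tIC 1, in kT, min-shifted to zero, with block-bootstrap errors and a
   barrier-depth-based basin search.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| tICA lag | 16 ns (release data); 5 frames (three-well) | time | slow-mode separation; tICA coordinates are insensitive to this choice over a broad range |
| MSM lag τ′ | 48 ns (release data); 25 frames (three-well) | time | smallest lag on the flat part of the implied-timescale curves |
| microstates k | ~100 (release data); 50 (three-well) | — | GMRQ-selected scale; enough resolution without starving counts |
| tICs kept | 2 | — | non-Gaussianity screen plus GMRQ comparison |
| macrostates | 15 (release data); 3 (three-well) | — | readability of the pathway graph; three-well truth has 3 basins |
| paths extracted | 7 | — | captures the bulk (>60%) of reactive flux |
| coordination cutoff | 3.5 | Å | first hydration shell of Na+; configurable, recorded in configs |
| release threshold | 10 | Å | ion-pair distance separating post-release configurations |
| release persistence | 10 | frames | suppresses threshold flicker |
| free-energy bins | 50 | — | resolves basins at the available sample sizes |
| basin depth | 1 | kT | barriers below thermal noise are not basins |
| block length | 180 ± 70 ns (release data) | time | longer than the feature autocorrelation time; jitter drawn uniformly over the range (the distribution is otherwise unconstrained) |

## The synthetic generators

The package is exercised end to end on generators whose answers are
known exactly:

* **Ground-truth chains** (`ground_truth_chain()`, `simulate_chain()`)
  provide discrete ensembles whose TPM, stationary vector and implied
  timescales are known in closed form. The estimator-recovery tests
  simulate 50 trajectories × 2·10⁴ steps and require the slowest
  implied timescale within 15% of `−τ′/ln λ₂(T_true)`, flat across a
  1–10 step lag ladder.
* **Three-well Langevin diffusion** (`three_well_params()`,
  `simulate_three_well()`) integrates an overdamped Euler–Maruyama path
  on a 2-D potential with two deep end basins (bound, released), a
  shallower intermediate basin, Gaussian barrier ridges between them,
  and a soft confining wall. Ridges depend only on the release
  coordinate so they cannot be bypassed laterally — without this the
  1-D free-energy marginal washes out the intermediate basin. Defaults
  (depths 3/1.5/3 kT, ridges 2.5 kT, widths 0.35/0.3, D = 1,
  dt = 0.002) were chosen so that end-basin escapes occur every few
  thousand recorded frames: frequent enough to estimate fluxes from
  10 × 2·10⁴-frame trajectories, rare enough that the three basins are
  genuinely metastable. `boltzmann_basin_weights()` integrates
  `exp(−U/kT)` on a grid for the exact basin populations that sampled
  occupancies and free-energy gaps are tested against.
* **Coordinate frames** (`synthesize_frames()`) carry labeled
  pseudo-atoms (ions, residue markers, water oxygens, lipids, a ligand
  proxy) arranged so the geometric operators reproduce the qualitative
  signatures of release: the ion's distance to its partner ion crosses
  10 Å through an intermediate pose near the coordinating glutamate,
  intracellular water counts rise, the hydration shell grows, and a K+
  ion reaches the emptied site only after release. The ensemble
  generator engineers release in 12 of 50 trajectories by default,
  mirroring the study design the pipeline targets; release-time
  dispersion is a free parameter (drawn uniformly in the middle of the
  trajectory) because no event-time distribution is prescribed by the
  underlying biology at this level of abstraction.

What passing tests do and do not show: the generators emulate the
*statistical and kinetic structure* of transporter trajectories — not
their physics. Success on synthetic data demonstrates that the
estimators are correct and internally consistent at realistic sample
sizes; it does not validate force fields, sampling convergence, or the
featurization's adequacy for any particular real protein.

## Numerical choices

* **Covariances.** Features are mean-centered before covariance
  estimation (required for covariance semantics; whether to center is
  otherwise a free choice). `C_TL` is symmetrized before solving — the
  finite-sample estimate is slightly asymmetric and would otherwise
  yield complex pairs. `C` receives a ridge `ε = 10⁻¹⁰ · tr(C)/d`; a
  still-singular `C` raises an error advising feature pruning. The
  solve whitens with the Cholesky factor of `C`, so eigenvectors come
  out `C`-orthonormal (`vᵀCv = 1`); each eigenvector's
  largest-magnitude entry is made positive for reproducible plots.
* **Counting and connectivity.** Sliding-window counting is the
  default (strided counting is available); counts are restricted to the
  largest connected component of the symmetrized count graph before
  normalization — without this the stationary vector is not unique.
* **Eigensystems.** Reversibility makes the TPM self-adjoint in the
  π-weighted inner product, so the spectrum is computed from the
  symmetric matrix `D^{1/2} T D^{-1/2}` — real by construction. A
  detailed-balance violation above 10⁻⁸ is an error, not a warning,
  because the symmetric solve would silently be wrong.
* **Degenerate eigenvalues in timescales.** λ ≥ 1 (numerical) maps to
  `Inf`; λ ≤ 0 has no timescale interpretation and is reported missing.
* **GMRQ state-space mismatch.** States visited in only one half are
  dropped: both TPMs are restricted to the intersection of their
  connected state sets and renormalized, keeping both row-stochastic.
* **Path-decomposition ties.** After subtracting a path's bottleneck
  flux, ties between equal-bottleneck paths are common. The
  decomposition resolves them canonically — shortest path first, then
  lexicographically smallest — which makes the output deterministic and
  lets an exhaustive enumeration reproduce it edge for edge.
* **Sign-based lumping.** Macrostates group microstates with identical
  sign patterns across the dominant eigenvectors (the smallest number of
  eigenvectors giving enough patterns). Surplus patterns are merged
  smallest-population-first into their Hamming-nearest neighbor; Hamming
  ties are broken by the distance between population-weighted mean
  eigenvector coordinates. The tie-break matters: states straddling a
  basin have near-zero slow-mode entries whose signs are noise, and
  coordinate distance reunites them with their kinetic kin. This
  deterministic sign rule deliberately replaces simplex-optimization
  PCCA+; it is simpler, reproducible, and sufficient for well-separated
  metastable systems, but it will fragment basins when the spectral gap
  is weak.
* **Empty bins** in free-energy profiles are reported missing (`NA`),
  not zero or `+∞`, so bootstrap error propagation stays finite.
  Samples beyond explicit histogram limits accumulate in the edge bins.
* **Release criterion.** A trajectory is "released" at the first frame
  opening a run of ≥ 10 consecutive frames with the ion-pair distance
  above 10 Å. The persistence guard is needed because thermal jitter
  produces transient crossings; by construction the detected time then
  matches the generator's engineered release frame.
* **Reducible chains.** A stationary vector with zero entries (e.g. the
  identity TPM) falls back to the uniform vector when that is
  stationary; otherwise the user is told to restrict the chain first.

## Design decisions that were genuinely open

* **Transpose symmetrization** of the count matrix was chosen over
  maximum-likelihood reversible estimation: it is the simplest estimator
  satisfying detailed balance exactly and suffices at the sample sizes
  the pipeline targets. ML reversible estimation (and Bayesian MSMs,
  hidden Markov models) are out of scope.
* **Multiple random splits** (default 5) for GMRQ rather than a single
  split, reporting mean ± sd — one split's selection noise can flip the
  winning hyperparameters; a single-split mode remains available for
  replication. Stratified splitting preserves release/no-release
  proportions (a 50-trajectory, 12-release ensemble splits 6/19 in each
  half).
* **Lipid exclusion** for cavity membership uses *all* particles labeled
  lipid, not only headgroups; the residue-distance features use the
  marker particle as given (on real data: the closest side-chain heavy
  atom, configurable).
* **No periodic-boundary imaging** is applied to synthetic frames; a
  minimum-image correction would be needed for raw MD input and can be
  applied upstream of the featurizer.
* **Endpoint macrostates** for the pathway report are the macrostates
  carrying the largest stationary weight of the source/target
  microstates (a lump that straddles a region boundary would otherwise
  blur the endpoints).
* **Command-line surface.** The pipeline is exposed as R functions
  (`run_pipeline()`, `make_fixtures()`, YAML configs) rather than a
  shell executable: the package's users work in R, and the functions
  compose with the rest of the ecosystem.

## Problem sizes

The shipped configurations are sized for a laptop: the three-well
pipeline integrates 10 trajectories × 2·10⁵ steps (recorded every 10th
step), clusters 2·10⁵ projected frames into 50 microstates, and
completes in well under a minute; chain-estimator checks use 50 × 2·10⁴
steps; the synthetic coordinate ensemble is 50 trajectories × 120–150
frames × ~90 particles. All sizes are configuration entries and scale
up directly for real data.

## Known limitations

* Linear tICA cannot separate slow modes that are nonlinear functions of
  the features; kinetic-map or commute-map scalings and nonlinear
  embeddings are not provided.
* The sign-based lumping degrades when metastability is weak (no clear
  spectral gap); use more microstates or fewer macrostates in that
  regime.
* Flux error bars are provided only via trajectory bootstrap; there is
  no analytic error model for TPT quantities.
* The free-energy module is 1-D by design; 2-D surfaces over (tIC 1,
  tIC 2) are left to plotting layers.
* The synthetic coordinate generator reproduces geometry and event
  structure, not energetics: its water counts and distances are staged,
  so it validates bookkeeping, not physics.
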
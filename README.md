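# ionrelease

Markov state model (MSM) analysis of ion-release kinetics from molecular
dynamics trajectory ensembles, in tidyverse-native R.

## The scientific problem

Secondary transporters of the neurotransmitter:sodium symporter family
(dopamine, serotonin, norepinephrine transporters) couple substrate
transport to a transmembrane Na+ gradient. The release of the sodium ion
bound at the second crystallographic site ("Na2") into the cytoplasm is
an early, rate-relevant step of the transport cycle: it is triggered by
hydration of the binding site, passes through a metastable intermediate
in which the ion is held by an acidic side chain in the intracellular
vestibule, and completes when the ion reaches bulk solvent. Quantifying
this process from an ensemble of unbiased MD trajectories — each long
enough to sample single events but far too short to converge kinetics on
its own — is the canonical use case for Markov state modeling.

`ionrelease` implements the full analysis chain as a reusable, tested
pipeline:

1. **Geometric featurization** — inter-residue gate distances, ion–site
   distances, water-cavity occupancies (EC/IC vestibules, IC channel and
   cavity), ion hydration (coordination number), mediated contacts, and
   K+ site-occupancy statistics with trajectory-level bootstrap and
   t-tests.
2. **tICA** — time-structure-based independent component analysis: the
   generalized eigenproblem `C_TL(τ) V = C V Λ` between the time-lagged
   and instantaneous feature covariances, yielding the slowest linear
   reaction coordinates; includes a non-Gaussianity screen for choosing
   the number of components.
3. **MSM** — k-means microstates in tICA space, sliding-window
   transition counts, a reversible (transpose-symmetrized) transition
   probability matrix, its full eigensystem, and implied timescales
   `τ_i = −τ′ / ln λ_i` scanned over a lag ladder with
   trajectory-bootstrap error bars.
4. **GMRQ model selection** — cross-validated generalized matrix
   Rayleigh quotient `Tr[(VᵀSV)⁻¹(VᵀCV)]` with `S = diag(π_test)`,
   `C = S·T_test`, scoring how well training eigenvectors diagonalize a
   held-out TPM, over a grid of (number of tICs, number of microstates).
5. **Transition path theory** — forward committor, gross/net reactive
   flux `f_ij = π_i (1−q_i) T_ij q_j`, iterative maximum-bottleneck
   (widest-path) decomposition into ranked release pathways, sign-based
   spectral lumping of microstates into macrostates, and macro-level
   flux reports.
6. **Thermodynamic statistics** — free-energy profiles `F = −ln p` along
   tIC 1 with block-bootstrap errors, basin detection, and
   release-event bookkeeping (sustained-threshold criterion).

Because public MD ensembles for this system are not available at desk
scale, the package ships first-class synthetic generators with known
ground truth: discrete Markov chains, overdamped Langevin diffusion on a
three-well free-energy landscape (bound / intermediate / released), and
labeled pseudo-atom coordinate frames in which a tagged ion escapes its
site in a configurable minority of trajectories (default 12 of 50).
Every stage of the pipeline is validated against these generators.

## Worked example

```r
library(ionrelease)
library(dplyr)

# a 10-trajectory ensemble, release engineered in 3
ens   <- synthesize_release_ensemble(n_traj = 10, n_release = 3,
                                     n_frames = 120, seed = 11)
feats <- table_features(ens)          # 12 canonical features per frame

release_summary(feats)
#> <release_summary> released 3 / 10 trajectories (fastest 280 ns, slowest 405 ns)

model <- tica(feats %>% select(-na2_water_coord), lag = 3)
model
#> <tica_model> 11 features, lag 3 frames (15 ns), top eigenvalues: 0.9867, 0.6383, 0.5903, 0.1034

proj <- tica_project(feats %>% select(-na2_water_coord), model,
                     n_components = 2)
cl   <- cluster_microstates(proj, k = 12, seed = 2)
msm  <- markov_model(cl$assignments, lag = 3, stride = 5,
                     centers = cl$centers)
head(tidy(msm), 4)
#> # A tibble: 4 × 3
#>    mode eigenvalue implied_timescale_ns
#>   <int>      <dbl>                <dbl>
#> 1     1      1.000                Inf
#> 2     2      0.984                955.
#> 3     3      0.774                 58.6
#> 4     4      0.685                 39.7
```

The slowest finite implied timescale (mode 2, ~955 ns here) is the
relaxation time of the release process itself: the time for population
to flow from bound to released states once intracellular gating is
disrupted. Mode 1 is the stationary (Perron) mode. `release_summary()`
reports the per-trajectory sustained-threshold release calls and their
times; `autoplot()` methods are available for tICA models, timescale
scans, GMRQ scans, flux decompositions, and free-energy profiles.

The complete chain — including TPT pathways over lumped macrostates and
a free-energy profile with block-bootstrap errors — runs from one
config:

```r
res <- run_pipeline(default_config("three_well"))
res$basins          # three basins: bound / intermediate / released
res$macro$paths     # ranked release pathways with flux percentages
```

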
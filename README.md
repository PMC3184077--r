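# fluxmodules

Does an organism's need to survive in many chemical environments, by
itself, make its metabolic network modular?  `fluxmodules` is an R package
for asking that question *in silico*.  It samples large ensembles of random
**viable metabolic networks** — networks that can synthesize biomass from the
nutrients of prescribed minimal environments — and measures how their
modular organization changes as the number of required environments (the
**environmental versatility index**, V_env) grows.  It is aimed at systems
biologists studying constraint-based models of metabolism and the origins
of network modularity.

## The model in brief

* A **reaction universe** fixes N reactions with stoichiometric matrix S,
  reversibility, exchange reactions (positive flux = secretion, negative =
  uptake) and one biomass reaction.  A **genotype** is a bit vector selecting
  which reactions a network contains; its size n is held fixed.
* **Viability** in an environment is decided by flux balance analysis:
  `max Z = c'v  s.t.  S v = 0,  a ≤ v ≤ b`, with uptake open only for the
  environment's importable metabolites.  Viable means optimal Z > 0 in
  every required environment.
* A **module** is a *fully coupled set* (FCS): a maximal set of reactions
  whose pairwise flux ratios are fixed and nonzero across all steady
  states, found by the LP pair `R_max = max v1 | v2 = 1` and
  `R_min = min v1 | v2 = 1` (coupled iff R_max = R_min ≠ 0).  Modularity is
  summarized by **M** (reactions inside FCSs) and **s** (number of FCSs).
* Ensembles at fixed n and phenotype are drawn by **MCMC**: propose a
  reaction swap, accept iff the result stays viable — a symmetric proposal
  with indicator acceptance, hence a uniform stationary distribution over
  the reachable viable set.
* A reaction's **scope distance** is the iteration of the network-expansion
  algorithm at which it first fires, minimized over environments — how far
  downstream of the nutrients it sits.
* **Pathway coherence** of an FCS is Q, the fraction of members sharing its
  dominant annotation; a merged FCS list is summarized by the **h-index**
  (largest h with a fraction h of FCSs at Q ≥ h) and tested by an
  annotation-swap randomization that preserves annotation frequencies.

All linear programs run on a bounded-variable two-phase simplex built into
the package (no external solver needed); it is cross-checked in the test
suite against a brute-force vertex-enumeration oracle.

## Worked example

The analysis scripts run the whole study on a bundled synthetic universe
with known ground truth (8 nutrient-specific catabolic chains feeding a
shared core through redundant routes, plus blocked distractors):

```sh
Rscript analysis/01_build_universe.R
Rscript analysis/02_sample_ensembles.R     # ~6 min: 12 chains, 1200 partitions
Rscript analysis/03_consensus_scope.R
Rscript analysis/04_pathway_coherence.R
```

Output of `01` (the model, written to `results/model/`):

```
universe: 73 reactions / 84 metabolites; 63 swappable
blocked reactions: 20 (the designed distractors: 20 )
full-universe FCS partition: s = 12 , M = 43 (designed: 12 / 43 )
```

`02` samples 100 genotypes (n = 53 reactions, burn-in 10³, 10⁴ attempted
swaps, every 100th saved) for each of three replicate nested environment
families at V_env ∈ {1, 2, 4, 8} and prints the modularity curve:

```
 V_env   mean_M   mean_s
     1 22.54667 3.796667
     2 24.33000 4.573333
     4 28.37667 5.710000
     8 39.00667 9.006667
```

Both indices rise with versatility in every replicate: each additional
required nutrient forces its catabolic chain — itself a fully coupled
set — into every viable genotype.  `03` locates the gained modules:

```
consensus set sizes: |R_hi| = 37  |R_lo| = 16  |R_hi \ R_lo| = 21
mean scope distance: difference set 2  vs universe 5.14
K-S p = 0.000699 ; Welch p = 7.9e-05
```

The 21 reactions that enter the consensus only at high versatility sit at
scope distances 1–3 — immediately downstream of the nutrients — while the
universe background averages 5.1.  `04` confirms that modules are
pathway-coherent:

```
merged list: 14 distinct FCSs, 2702 entries
fraction of entries with Q = 1: 0.889
h-index: 0.889   randomization p: 0.00498
```

## Package layout

* `R/`, `src/` — the implementation: model I/O (`read_universe`,
  `write_universe`, `read_annotations`, `read_environments`), the FBA layer
  (`max_biomass`, `is_viable`, `flux_variability`, `blocked_reactions`),
  flux coupling (`coupling_bounds`, `fcs_partition`, `modularity_indices`),
  sampling (`mcmc_chain`, `build_start_genotype`,
  `build_nested_environment_sets`), scope (`scope_expand`,
  `scope_distances`), coherence (`q_statistic`, `h_index`,
  `annotation_swap_randomization`) and orchestration
  (`run_versatility_experiment`, `versatility_curve`,
  `consensus_reactions`, `compare_scope_distributions`).
* `analysis/` — the numbered driver scripts shown above.
* `vignettes/metabolic-modularity.Rmd` — the methods notes: model
  assumptions, tolerances, design decisions, and what the synthetic
  universe does and does not emulate.
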
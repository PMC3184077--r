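---
title: "Environmental versatility and the modular organization of metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environmental versatility and the modular organization of metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmodules)
```

## The question

Metabolic networks are conspicuously modular: reactions cluster into
pathway-like units.  One explanation is direct selection for modularity;
another is that modularity falls out of ordinary functional demands.
`fluxmodules` implements an *in silico* test of the second idea.  It samples
random viable metabolic networks — networks required to synthesize biomass
in a prescribed set of minimal environments — and measures how their
modularity changes as that set grows.  If requiring growth on more carbon
sources mechanically forces more pathway modules into a network, modularity
is (at least partly) a by-product of environmental versatility.

## Genotypes, viability, and flux balance analysis

A *reaction universe* fixes a global set of N metabolic reactions, their
stoichiometry (an m-by-N matrix S), reversibility, exchange reactions that
move external metabolites across the system boundary, and one biomass
reaction whose substrates are the biomass precursors.  A *genotype* is a
bit vector over the universe: which reactions the network contains.  Only
metabolic reactions are swappable; exchanges and biomass are infrastructure
present in every genotype, so the genotype size n counts a network's
enzymatic repertoire.

Viability in an environment is decided by flux balance analysis: maximize
the biomass flux Z = c'v subject to steady state S v = 0 and bounds
a ≤ v ≤ b.  Bounds encode presence (absent reactions are pinned to zero),
thermodynamics (irreversible reactions get [0, U], reversible [−U, U]) and
the environment: an exchange may always secrete ([0, U]) and may import
(lower bound −U) only the metabolites on the environment's importable list.
A genotype is viable when optimal Z exceeds 10⁻⁶ in *every* required
environment; the number of required environments is the environmental
versatility index V_env.

Numerical conventions: the generic flux bound is U = 1000 (so "unlimited"
nutrient supply is an uptake bound of −U and every program is bounded);
v = 0 is always feasible, so the maximization never reports infeasibility
on valid input.  The LPs are solved by a bounded-variable two-phase primal
simplex written for this package (dense tableau, Dantzig pricing with a
Bland's-rule fallback against cycling, feasibility tolerance 10⁻⁷, pivot
tolerance 10⁻¹⁰).  The test suite cross-checks it against a brute-force
vertex-enumeration solver on random programs.

## Modules: fully coupled sets

Two reactions are fully coupled when the ratio of their fluxes is the same
nonzero constant in every steady state.  The decision is made by two LPs:
fix v₂ = 1 and maximize / minimize v₁; the pair is coupled iff
R_max = R_min (relative tolerance 10⁻⁹) and the common ratio is nonzero.
A ratio locked at zero means r₁ is off whenever r₂ runs — directional
dependence, not mutual coupling — and is rejected.  If v₂ = 1 is
infeasible and r₂ is reversible, the pair is re-solved at v₂ = −1 with the
ratios negated, making the test total.

Full coupling is an equivalence relation on the unblocked reactions, and a
*fully coupled set* (FCS) is an equivalence class of size at least two.
`fcs_partition()` exploits transitivity: each reaction is tested against
one representative per existing class, so the LP count grows with the
number of classes rather than quadratically (`exhaustive = TRUE` forces
all O(n²) pairs and verifies that the coupling graph is a disjoint union
of cliques).  As a further economy, the flux-variability vertices computed
for blocked-reaction detection are reused as witnesses: a stored steady
state in which one reaction runs and the other does not — or two states
with different ratios — disproves coupling without an LP.  Witnesses only
ever *prune*; membership is always confirmed by the LP criterion.

Couplings are computed under fixed analysis conditions, independent of any
environment: every exchange is open in both directions, and the biomass
reaction is replaced by one independent sink per precursor so that no
fixed biomass composition artificially couples the producers of different
precursors.  Sinks and exchanges never appear in reported FCSs.  Blocked
reactions — flux-variability interval {0} under these conditions, with a
10⁻⁶ tolerance on both ends — are excluded first.

Two indices summarize a partition: M, the number of reactions contained in
FCSs, and s, the number of FCSs.  Both are zero for a network with no
modules.

## Sampling viable genotypes

The space of viable genotypes at fixed n is far too large to enumerate and
far too sparse to hit by rejection from random bit vectors, so ensembles
are drawn by a Markov chain: propose a *reaction swap* (remove one
uniformly chosen present swappable reaction, add one uniformly chosen
absent one — n is preserved), accept iff the result is viable in all
required environments, otherwise keep the current genotype.  The proposal
is symmetric and acceptance is an indicator, so the stationary
distribution is uniform on the reachable viable set; the test suite
verifies this against exhaustive enumeration on a fixture small enough to
list every viable genotype.

Chains use R's own RNG under an explicit integer seed (recorded in the
sample's provenance), memoize viability by genotype hash (rejected
proposals repeat, and the LP dominates runtime), and save every
`thinning`-th state after a burn-in.  At genome scale a sensible design is a
burn-in of 10⁵ attempted swaps, 10⁶ further attempts and every 1000th
state saved; the desk-scale experiments in this package use 10³ / 10⁴ /
10², which the uniformity fixture shows is ample for universes of this
size.  Starting genotypes are built from
the union over environments of the reactions carrying nonzero flux
in one biomass-maximizing solution of the full universe, padded with
random swappable reactions to exactly n.

Nested environment sets isolate the effect of versatility: above a pivot
size a single nested chain of subsets is shared by all replicates; at the
pivot, independent replicate subsets are drawn; below it each replicate
continues as its own nested chain.  Every smaller set is contained in its
parent, so moving along a family changes only V_env.

## Scope distances

How far downstream of the nutrients does a reaction sit?  Network
expansion answers structurally: start from a seed set A of metabolites
(the environment's importables), and at each iteration fire every reaction
whose substrates are all in A, adding its products.  A reaction's firing
iteration is the first iteration at which it fires; its *scope distance*
is the minimum firing iteration over all environments, with an explicit
`NA` ("unreached") sentinel — never a stand-in large number — and
unreached reactions are dropped (with a reported count) from
distributional statistics.  Reversible reactions are evaluated as two
directed half-reactions, following the network-expansion literature.
Because expansion cannot bootstrap autocatalytic cofactor cycles (a
cofactor is consumed before it can be regenerated), cofactors are supplied
in the seed explicitly; the synthetic universes declare their own cofactor
seed list.

## Pathway coherence

If FCSs are biologically meaningful modules, their members should share
pathway annotations.  For one FCS, Q is the fraction of member reactions
annotated with the FCS's dominant pathway (ties broken lexicographically;
unannotated members count in the denominator but match nothing).  For a
*merged list* — the FCSs of all genotypes in an ensemble, where a repeated
set records its multiplicity — the h-index summarizes the Q distribution:
the largest h such that a fraction h of the list (weighted by
multiplicity) has Q ≥ h, computed exactly as the maximum over distinct Q
values of min(q, fraction(Q ≥ q)).

Significance comes from an annotation-swap randomization: repeatedly pick
two distinct FCSs with the same multiplicity, one member in each, and
exchange their entire annotation sets.  Swapping within a multiplicity
class is what preserves each pathway's total (multiplicity-weighted)
frequency in the merged list — the package applies the swap at the level
of distinct FCSs, whose assignment is shared by all copies, because that
is the only reading under which the same-multiplicity restriction has any
conserving effect.  Whole-set exchange (rather than single labels)
preserves the multi-annotation structure of each reaction slot.
Frequencies, FCS sizes and multiplicities are asserted unchanged after
every randomized list.  The p-value uses the add-one correction
(1 + #{random h ≥ observed h}) / (1 + number of lists) and is never zero.

## The synthetic universe and what it does (not) show

At genome scale this analysis would run on a curated reaction database of
thousands of reactions with pathway annotations.  No such resource is
bundled; the package instead ships a generator whose
output has the same *statistical structure* at desk scale with exact
ground truth: per nutrient, an exchange and a linear catabolic chain
(annotated as its own pathway) feeding a shared hub; several redundant
two-reaction routes from the hub into a linear core that synthesizes the
biomass precursor, so that many genotypes realize each phenotype; blocked
distractor reactions consuming unproducible metabolites; optionally a 2:1
stoichiometric step (exercising non-unit coupling ratios) and a cofactor
cycle (exercising scope seed sensitivity).  Construction is deterministic,
and the generator returns the expected FCS partition of the full universe,
designed scope distances and the blocked set — the coupling, scope and
blocked-detection code is tested against this ground truth, and against
LP-free oracles (null-space proportionality, Monte-Carlo flux-ratio
sampling) on random networks.

Default dimensions (8 nutrients, chains of 3, 3 redundant routes, core of
12 with a cofactor cycle, 20 distractors; sampled genotypes carry 43 of
the 63 swappable reactions) were chosen so that the three regimes of real
metabolism are represented: reactions forced by the phenotype, reactions
free to drift, and reactions that can never run.  The core is deliberately
long so that the universe contains genuinely deep reactions — the
background against which nutrient-proximal modules stand out — and the
distractor count keeps the bit density of sampled genotypes moderate, so
that at low versatility a complete foreign catabolic chain arises only
occasionally by chance.

What the synthetic universe does *not* emulate: branched and interwoven
real pathways sharing intermediates and cofactors across the network,
heavy-tailed metabolite connectivity, multi-functional enzymes with
several annotations, or realistic scale (dozens of reactions rather than
thousands).  Passing tests therefore certify the *algorithms* — coupling
detection, uniform sampling, expansion, the statistics — and the
qualitative mechanism linking versatility to modularity under controlled
conditions; they are not a quantitative reproduction of genome-scale
results.

## The experiment

`run_versatility_experiment()` ties the pieces together: for each
replicate family and each V_env it runs one chain, partitions every saved
genotype, and `versatility_curve()` aggregates ⟨M⟩ and ⟨s⟩ with their
dispersions (re-aggregation of a stored experiment is bit-identical).
Ensembles of 100 genotypes at V_env ∈ {1, 2, 4, 8} with 3 replicate
nestings complete in minutes on one CPU.  Downstream,
`consensus_reactions()` extracts reactions appearing in FCSs of at least
half an ensemble's genotypes (a strict ≥ threshold), the
difference set R_hi \ R_lo isolates versatility-driven module reactions,
and `compare_scope_distributions()` contrasts their scope distances with
the whole-universe background (two-sided two-sample K-S plus Welch t; raw
p-values, no multiple-testing correction, matching the single-test
design).  `empirical_percentile_test()` supports comparing one observed
network against an ensemble by rank.

## Known limitations

* The simplex is dense; it is comfortable at hundreds of reactions but
  not designed for genome-scale models with tens of thousands.
* Full coupling is decided at fixed numerical tolerances; ratios that
  differ only beyond 10⁻⁹ relative are treated as equal, and coupling at
  ratios below 10⁻⁹ is treated as zero.
* The sampler guarantees uniformity only on the *reachable* component of
  the viable set; for the universes here reachability is verified by
  enumeration, for arbitrary universes it is an assumption, as in the
  original sampling framework.
* SBML import is minimal (species, stoichiometry, reversibility,
  boundaryCondition); models relying on fbc extensions or compartment
  semantics need preprocessing.
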
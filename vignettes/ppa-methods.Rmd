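---
title: "Methods: simulation, progressive analysis, dating and discordance in ppaphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, progressive analysis, dating and discordance in ppaphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppaphylo)
```

`ppaphylo` chains six stages — scenario specification, sequence
simulation, distance estimation, tree inference, calibrated dating, and
discordance analysis — into one reproducible pipeline. This vignette
explains the model behind each stage, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate about real data.

## The scenario model

A `scenario_spec` is the generative truth: a dated species tree (node
ages in years before present), a group label per leaf (`african`,
`non_african`, `archaic`, `outgroup`), a set of lineage-capture
introgression events, and strict-clock substitution parameters. The
invariants are enforced at construction: ages strictly decrease from
root to leaves, and every event must be younger than the divergence of
its donor and recipient lineages (an event exactly coinciding with a
divergence is rejected rather than resolved arbitrarily).

An introgression event is a *full lineage capture*: for the named locus,
the whole subtree hanging below the recipient's ancestral branch at the
event age is detached and re-attached to the donor's ancestral branch at
exactly that age (`derive_locus_tree()`). The locus tree therefore stays
dated and ultrametric, and with no events it is the species tree
exactly. Partial or recurrent gene flow is deliberately out of scope:
the event grammar models whole-locus replacement, which is the right
abstraction for a non-recombining mitochondrial genome.

The shipped `fig1_fig3` preset is a ten-taxon hominin scenario: Pan
outgroup with a Pan/Homo divergence at 8 MYBP; a basal split within Homo
at 800,000 YBP; within the archaic side a Denisovan/Neanderthal split
and a Sima-de-los-Huesos/main-Neanderthal split; within modern humans a
basal split at 250,000 YBP (Mbuti/San vs all others), Yoruba divergences
at 225,000 and 180,000 YBP, and a basal non-African split at
125,000 YBP; plus one mtDNA capture from the modern-human stem into the
main Neanderthal lineage (`Hsnn_star`) at 500,000 YBP. Three internal
ages are not pinned down by the scenario the preset encodes and were
fixed once as round, literature-plausible values: the
Denisovan/Neanderthal split at 700,000 YBP, the Neanderthal-internal
split at 600,000 YBP (it must predate the 500,000 YBP capture), and
Mbuti/San at 200,000 YBP. None of the five headline nodes checked by the
acceptance script depends on these three choices.

## Sequence simulation

`simulate_alignment()` evolves each site independently down the dated
tree. A branch of duration $t$ years receives expected
$d = t \times \mathrm{clock\_rate}$ substitutions per site, applied
through the closed-form K2P transition-probability matrix

$$P(\text{transition}) = \tfrac14 + \tfrac14 e^{-4\beta t}
  - \tfrac12 e^{-2(\alpha+\beta)t}, \qquad
  P(\text{each transversion}) = \tfrac14 - \tfrac14 e^{-4\beta t},$$

with $\alpha/\beta = \kappa$ and total rate normalised so that branch
length equals expected substitutions. JC69 is the $\kappa = 1$ special
case. Defaults: `clock_rate` $= 1.5\times10^{-8}$ substitutions per site
per year, `seq_length` = 16,500 bp (a complete-mtDNA-sized locus) and
$\kappa = 4$, a typical mitochondrial transition excess. The rate was
chosen so that the deepest path in the preset (Pan to any human,
16 million years) accumulates 0.24 substitutions/site — strong signal,
clearly short of saturation; the youngest internal branch (25,000 years)
still expects ~6 substitutions over 16,500 sites, so shallow nodes are
resolvable but not trivially so.

The random-number stream is consumed branch by branch in a fixed
preorder traversal, so one integer seed determines the alignment
bit-for-bit; tests assert byte-identical FASTA across repeated runs. The
simulator emulates a strict clock with homogeneous rates across sites
and branches, no rate heterogeneity, no indels, no ambiguity codes, and
one haploid exemplar per lineage (no within-population coalescent).
Passing tests therefore demonstrate correctness of the inference chain
*under its own assumptions* — they do not show robustness to rate
variation, model misspecification or population-level sampling, all of
which real mtDNA data exhibit.

## Distances and tree inference

Distances use pairwise deletion: any site with `N` or `-` in either
sequence of a pair is excluded for that pair only, which preserves taxa
in gappy alignments (complete deletion would discard whole columns).
`p` (uncorrected), JC69 and K2P corrections are available; K2P is the
default throughout because mtDNA is transition-rich, and the model used
is recorded in the matrix and echoed in reports. Saturated pairs
($p \ge 3/4$ for JC69, or a non-positive log argument for K2P) raise an
error naming the pair instead of returning a truncated value — on
simulated data a saturated pair indicates a broken scenario, and hiding
it behind a capped distance would corrupt everything downstream.

Neighbor joining delegates to `ape::nj` after validating symmetry,
non-negativity and a zero diagonal. NJ can emit negative branch-length
estimates on noisy input; these are clamped to zero with the deficit
moved to a sibling edge so that path lengths through the node are
approximately preserved, and the count of clamped branches is kept as an
attribute. Tie-breaking among equal agglomeration criteria is `ape`'s
deterministic internal order. UPGMA delegates to `phangorn::upgma`;
Fitch parsimony to `phangorn::fitch` with `N`/`-` treated as fully
ambiguous (missing data, not a fifth state); both are cross-checked in
the test suite against independent oracles (trees with known additive
distances; brute-force enumeration of all internal state assignments).
Exhaustive topology search enumerates all $(2n-5)!!$ unrooted binary
topologies via stepwise leaf insertion and is capped at nine taxa.

Outgroup rooting places the root at the midpoint of the outgroup's
pendant edge. The true root generally does not sit at that midpoint
(here: 8.0 of the 15.2 million years of the Pan pendant path lie on the
Pan side), which inflates the calibration node's mean depth slightly and
biases all calibrated ages a few percent downward — a known, documented
property of this rooting choice, visible in the replicate medians, and
small relative to the 10% recovery tolerance the tests use. Ingroup
node depths themselves are unaffected by where the root lands on the
outgroup edge.

## Calibrated dating

`node_depths()` assigns each node the mean path length to its descendant
leaves, then repairs monotonicity bottom-up (a parent is raised to at
least the deepest child). On an ultrametric tree the repair is a no-op
and depths equal true heights. `calibrate_ages()` scales depths linearly
through a single calibrated node — here the Pan/Homo MRCA at 8 MYBP —
so the calibration age is recovered exactly (an identity asserted in the
tests), ages are invariant under uniform branch rescaling, and no rate
smoothing of any kind is applied. Mean-path depths rather than UPGMA
heights are used so that dating runs on the same NJ topology the PPA
reports; UPGMA is available as an independent ultrametric cross-check.
Stored ages are exact floats; rounding to 25,000-year granularity
happens only in human-readable output.

## Progressive phylogenetic analysis

`ppa_run()` re-infers the tree from scratch at every addition step
(full rebuild, not grafting), so the final tree provably equals the
one-shot inference on the complete taxon set — an invariant the tests
assert. The newcomer's attachment edge is then *derived*: removing its
pendant edge from the new tree merges two edges into one, whose
bipartition is looked up among the previous tree's edges (pendant edges
included). If re-inference also rearranged something else, the nearest
edge by bipartition similarity is reported and the record is flagged
`shifted`, so placement reporting stays robust to minor rearrangements.

Monophyly classification uses the standard operational definitions:
monophyletic if the group equals the leaf set of its MRCA; otherwise
paraphyletic if the group's complement is monophyletic (the group is a
clade minus one nested clade); otherwise polyphyletic. The complement is
taken within a *classification universe*. In `ppa_run()` that universe
is the union of the labelled population groups, so archaic lineages and
the outgroup — which are present in the tree but are not population
groups under classification — do not count toward any group's
complement. This matters: with the mtDNA capture in place, the African
populations are a clade minus the nested non-African clade
(paraphyletic), but if archaic leaves were admitted to the complement
the verdict would flip to polyphyletic on a technicality of universe
choice, misrepresenting the population-level question being asked.

## Discordance and direction

Topology comparison is unrooted and bipartition-based; the displaced-taxon
search is exact over all leaf subsets up to `max_k` (default 3), smallest
first and lexicographic within a size, returning an explicit
"irreconcilable" result rather than an error when nothing within the cap
reconciles the trees. The direction rule is purely topological: for a
displaced taxon, the donor is the smallest reference-tree clade
containing the taxon's sister group in the test tree. The two competing
configurations are distinguishable because they predict different sister
groups — a forward transfer leaves the recipient sister to the donor
clade while its former sister keeps its old position, whereas a reverse
transfer would drag the pair to a different flank. The rule trace in
every call records both sister groups so the matched configuration is
auditable. No branch-length or likelihood test of introgression is
performed, and the reports say so.

## Problem sizes and what the tests show

The test suite validates exact oracles at small scale (50 random 6–8
leaf additive matrices for NJ recovery; brute-force Fitch on 5–6 leaf
trees; topology counts for 4–9 taxa; 100 random single-leaf-move pairs
for displaced-taxon pruning) and the stochastic properties at the
scenario's own scale: 20 replicates of the 16,500-bp simulation for
date-chain recovery (medians within 10% of the generating ages), and 50
replicates each for the African-paraphyly verdict and the
donor/recipient direction call (both required in at least 95% of
replicates). Simulator calibration is checked against the closed-form
JC69 expected p-distance at $10^5$ sites within three Monte-Carlo
standard errors. These sizes make the full suite run in about a minute
on a single core while keeping every stochastic criterion's Monte-Carlo
error well below the tolerances being tested.

## Known limitations

- Strict clock everywhere: no relaxed-clock or rate-smoothing dating.
- One exemplar per lineage; no coalescent variance, so simulated node
  ages are exact lineage divergences, not population split times.
- The direction rule is topological only and assumes the displaced
  taxon's placement is correctly inferred; it inherits any tree-inference
  error.
- Exhaustive machinery (topology enumeration, parsimony PPA,
  displaced-set search) is exact but capped at toy scale by design.
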
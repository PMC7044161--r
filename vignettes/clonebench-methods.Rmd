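---
title: "clonebench: simulation models and evaluation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clonebench: simulation models and evaluation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonebench)
```

# Scope

`clonebench` generates multi-sample tumor bulk-sequencing read counts from
known clone phylogenies and scores inferred clone genotypes and phylogenies
against that truth. It deliberately does **not** implement any clonal
deconvolution method, the multi-labeled tree edit distance itself (only its
input tables are exported), or consensus-tree construction.

# The domain model

A clone phylogeny is a rooted tree whose root is the germline and whose
branches carry sets of SNVs. Under the infinite-sites assumption each SNV
arises exactly once, so a clone's genotype is the union of branch-mutation
sets on its root path and an ancestor's genotype is always a subset of its
descendants'. This makes three representations interconvertible, and the
package leans on that:

* `genotypes_from_tree()` — tree to binary clone-by-SNV matrix;
* `tree_from_genotypes()` — perfect-phylogeny reconstruction from binary
  characters, rooted at the all-zero germline. Because mutations are unique,
  maximum parsimony reduces to the classic construction: sort sites by
  decreasing carrier count; each clone's mutation list then spells a root
  path in a mutation trie. Conflicting site pairs (all of the patterns
  (1,1), (1,0), (0,1) present) raise an error naming the pair. Clones with
  identical genotypes merge onto one node (labels retained for the
  multi-label metrics); pattern-required nodes matching no input row become
  anonymous internal nodes.
* `genotype_phylo()` — the same tree as an `ape::phylo` in which *every*
  clone is a tip: ancestral clones become pendant tips at their node and
  the germline is the tip `Normal`. This mirrors how clone phylogenies are
  rebuilt from genotype matrices by parsimony with germline outgroup
  rooting before tree-distance scoring.

# Simulators

## Random phylogenies with localized sampling

`generate_random_dataset()` grows a topology by a Yule-type process:
a uniformly chosen tip splits into two daughters until the clone budget is
met, with an optional post-split tip-death probability (default 0) that
leaves unifurcating persisted ancestors. Where the scenario fixes no
distribution we chose once and document here:

* **Mutations per branch**: uniform on 1..10 (configurable). Only "a random
  positive number" is specified; a uniform handful per branch reproduces the
  observed tens-of-SNVs-per-dataset scale.
* **Clone frequencies**: each sample holds one tip clone plus all its
  ancestors (localized sampling); their frequencies are symmetric
  Dirichlet(1) — the maximum-entropy choice on the simplex — and sum to 1,
  i.e. 100% tumor purity.

## CNA and LOH overlay

`assign_snvs_to_haplotypes()` packs SNVs into abstract chromosomes of at
most 30 sites and flips a fair coin for paternal/maternal placement.
`place_cna_events()` draws per-chromosome event counts (default Poisson(1),
a choice calibrated to its *outcome*: on the order of seven affected SNVs
per clone at typical sizes), assigns each event a
uniform type (gain / loss / LOH), haplotype, and branch, and interleaves
events with the branch's mutations at uniform positions.
`evolve_copy_states()` replays each clone's root path: a gain duplicates
one surviving copy of the affected haplotype (total +1 copy, not a
doubling); a loss deletes one; LOH deletes one copy of the affected
haplotype and duplicates one of the other. Degenerate collisions are
defined, not crashes: events on exhausted haplotypes are logged no-ops, and
a mutation scheduled after its haplotype was lost lands on a surviving copy
if any exists, otherwise the mutant count stays 0 (logged). When several
copies of a haplotype survive, the deterministic "first instance" is used;
at the chosen simulation scale multiple same-branch events on one
chromosome are rare, so this tie-break is immaterial but reproducible.

## Expected VAFs, depths, and read counts

Copy-neutral: `V = ½ f M`. With CNAs each clone contributes
`f · mutant_copies/total_copies` (a clone with total 0 at a site contributes
0), and expected depth is `Σ_c base · f(c) · total_copies(c)/2` plus the
diploid normal-cell term. Note the VAF summation is deliberately *not*
re-weighted by depth; the two adjustments are applied independently. Observed counts are Poisson totals with Binomial mutant reads; a
total of 0 is kept. Defaults: depth 100 for growth/CNA-style datasets, 50
for the low-depth regeneration (`regenerate_at_depth()`), all configurable.
Purity defaults to 100%; the `normal_fraction` path is implemented and
tested but inactive at defaults.

## Lattice tumor growth

`grow_tumor()` is a simplified, self-contained re-implementation of an
agent-based 3D growth simulator, pinned by these choices:

* **Lattice**: face-centered-cubic packing (12 neighbors) as the 3D
  hexagonal lattice.
* **Scheduling**: per-cell clocks with Gamma(shape k = 10, mean 1/rate)
  waiting times; eligibility is re-evaluated when a clock fires. Under
  `step`, a cell with no empty neighbor is permanently retired (without
  pushing, sites never vacate); under `linear`, firings are thinned with
  acceptance probability (empty neighbors)/12 — equivalent to a birth rate
  proportional to local emptiness.
* **Push rule** (`constant` only): the daughter is placed along a uniformly
  random lattice direction and the occupied chain beyond it shifts outward
  one site. This single documented rule stands in for the original
  simulator's configurable push models.
* Each division gives the *new* cell Poisson(1) brand-new mutations; no
  death, no migration, no drivers; growth stops at exactly N cells
  (default 10,000).

`sample_sectors()` picks 8 anchors by greedy farthest-point selection among
200 random candidate cells ("uniformly located" is otherwise unspecified)
and takes the 100 nearest unassigned cells per anchor, so sectors are
disjoint. `call_clones()` keeps SNVs carried by strictly more than 5% of
the pooled sampled cells, merges identical restricted genotypes into
clones, and counts per-sector frequencies. These seeded rules are a
self-contained emulation of sector-sequencing designs, not a replication of
any particular simulator's spatial semantics.

# Evaluation metrics

* **Pair ordering** (`classify_mutation_pairs()`, `ordering_error_rate()`):
  pairs on one branch are concurrent; on ancestor/descendant branches,
  sequential; otherwise parallel. The per-category error rate averages the
  missed-true-pair proportion and the false-inferred-pair proportion,
  with denominators *within* the category. True pairs over SNVs absent
  from the inference count as missed ("unassigned"); inferred pairs over
  SNVs absent from the truth count as incorrect. If the inference has zero
  pairs in a category that the truth populates, the rate is flagged
  `undefined` (infinite error — the star/line failure semantics); if the
  truth itself lacks the category the missing term contributes 0, so
  self-comparison is 0 on any tree.
* **Clone mapping** (`map_clones()`): genotype distance is Hamming on the
  union SNV universe (absent SNVs are 0). Greedy ascending-distance
  pairing, then surplus inferred clones attach to their nearest true clone;
  all ties break lexicographically (true id, then inferred id), making the
  mapping deterministic.
* **TreeVec** (`treevec_distance()`): for every unordered label pair, the
  edge count from the root to the MRCA of the two label groups; Euclidean
  distance between the two trees' vectors over the union label ordering.
  Collapsing monophyletic same-label clades is implicit in the group-MRCA
  rule (a collapsed clade's tip sits exactly at the group MRCA); labels
  missing from one tree contribute depth-0 entries there. Verified exactly
  against a naive per-pair oracle built on independent `ape` primitives.
* **Rooted RF** (`rf_distance()`): nontrivial clades (internal-node tip
  sets, sizes 2..n−1, deduplicated) of both trees; distance =
  |symmetric difference| / (total clades), in [0, 1]. Requires equal,
  duplicate-free tip sets; `prune_inferred_tips()` first keeps, per true
  clone, the mapped tip of minimal Hamming distance. When the inference has
  fewer clones than the truth no pruning exists and the report carries
  `NA` — an honest "not comparable", consistent with treating degenerate
  output as failure.
* **Ancestral-clone detection**: a true ancestral clone (internal node
  present in some sample) counts as identified when an inferred clone maps
  to it at distance 0; since "identified" is an interpretation, the
  tolerance is configurable.

# Post-processing of frequency-less methods

`estimate_clone_frequencies()` solves, per sample,
`min ‖½ f M − V_obs‖²` subject to `f ≥ 0`, `Σf ≤ 1`, after excluding SNVs
with total reads < 50 or mutant reads < 2. The solver is Lawson–Hanson
active-set NNLS on an augmented system with an explicit normal-fraction
slack variable and a heavily weighted equality row — exact on noiseless
identifiable inputs, and a warning is raised when the filtered design is
rank deficient. `filter_spurious_ancestors()` applies a one-sided Welch
t-test (shared > descendant-unique VAFs; the direction follows the
biological expectation, the Welch variant is our choice) per coexisting
ancestor/descendant pair and removes the ancestor from a sample when no
test is significant at α = 0.05, reassigning its frequency to the nearest
retained descendant. Tests with fewer than two SNVs in a group are skipped
(ancestor retained). `discard_rare_clones()` drops frequencies strictly
below 2% and re-normalizes to the original row sum; all three filters are
idempotent.

# What a green test does and does not establish

The synthetic generators encode an idealized world: 100% purity, exact
Poisson/Binomial counting noise, whole-haplotype CNAs without coordinates,
infinite sites with no back mutation, no sequencing-error model, no normal
cells in the lattice tumor. Real data violate most of these (impure
samples, focal CNAs, error-prone low-VAF calls, recurrent mutations at
hotspots), so passing this suite certifies the pipeline's internal
correctness and calibration, not performance claims about any inference
method on real tumors.

# Numerical and determinism notes

All generators take explicit seeds; pipeline stages derive sub-seeds from
the master seed by a fixed hash (`derive_seed()`), so one integer pins an
entire bundle byte-for-byte. Matrix comparisons in the reduction property
are exact (integer copy states divide exactly in double precision at the
relevant magnitudes). The NNLS penalty weight (1e4) keeps the augmented
system well conditioned while enforcing the simplex row to ~1e−8. The
greedy mapping, sector assignment, clone ordering, and tie-breaks are all
deterministic by sorted-identifier rules documented above.

# Known limitations

* The growth model's push and sector-placement rules are plausible
  stand-ins, so spatial statistics (e.g. exact intermixture levels) are
  comparable across its three models, not against external growth
  simulators.
* TreeVec here implements the label-pair depth vector only (no per-label
  tip-depth block and no branch-length component).
* The frequency regression assumes copy-neutral SNVs; applying it to
  CNA-affected sites biases `f`, exactly as it would in the emulated
  workflow.
* `rf_distance()` is undefined (reported `NA`) when the inference yields
  fewer clones than the truth.
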
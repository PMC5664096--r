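---
title: "Network-based pathway enrichment: model, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based pathway enrichment: model, nulls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpea)
```

## The problem

Over-representation analysis (ORA) asks whether an input gene set — say,
genes differentially expressed in a tumor — shares more members with an
annotated pathway than chance would allow, via the cumulative
hypergeometric test. Because ORA treats genes as independent units it is
blind to associations mediated by gene–gene interactions: an input set and
a pathway can share almost no genes yet sit immediately next to each other
in the protein–protein interaction (PPI) network, for instance when the
observed genes are downstream targets of the causal pathway. This package
scores pathway association through network proximity instead, and attaches
permutation-based significance to the scores.

## Similarity by random walk with restart

Input genes and pathway members are first mapped onto a PPI network by
exact identifier match. The mapped input genes seed a random walk with
restart (RWR): every seed node starts with value 1 (vector $V$), all other
nodes with 0, and values are propagated by

$$S_n = (1 - p)\, M\, S_{n-1} + p\, V, \qquad S_0 = V,$$

where $M$ is the column-stochastic transition matrix of the network
(column $j$ uniform over the neighbors of $j$) and $p$ is the restart
probability — the chance at each step that the walker jumps back to its
origin rather than moving to a random neighbor. The iteration is a
contraction with factor $1 - p$, so $S_n$ converges geometrically to the
unique fixed point $S = p\,(I - (1-p)M)^{-1} V$; `rwr_closed_form()`
computes this fixed point directly by a dense linear solve and serves as
an independent oracle for the iterative `rwr()` in the test suite. A
pathway's **similarity score** is the mean converged value over its
network-mapped members.

Two useful conservation facts, both exercised by the tests: on a network
without isolated nodes the converged values sum to the number of mapped
seeds, and an isolated seed node retains exactly $p$.

## Two randomization schemes

**NetPEA.** The input gene set is replaced by `n_perm` random gene sets of
the same size, drawn uniformly without replacement from network nodes.
With $D$ the observed score of a pathway and $R$ its null scores,

$$z = \frac{D - \operatorname{mean}(R)}{\operatorname{sd}(R)},$$

using the sample (n−1) standard deviation. Pathways are ranked by
decreasing $z$; $z > 1.65$ (one-sided normal upper tail, $p = 0.05$) is
called significant. This scheme rewards both shared genes and interacting
genes, so it reports a superset of what overlap alone supports.

**NetPEA′.** A pathway can reach a large $z$ purely because it overlaps
the input: its own members are seeds. To de-emphasize such pathways the
network itself is also randomized by degree-preserving rewiring
(`n_nets` rewired networks), which destroys the wiring while keeping every
node's degree — overlap-driven signal survives rewiring, proximity-driven
signal does not. With $DN$ the observed score on the real network, $DR$
its scores on the rewired networks, $RN$ the random-set scores on the
real network and $RR$ the same random sets on the rewired networks,

$$z = \frac{(DN - \operatorname{mean}(DR)) -
             \operatorname{mean}(RN - \operatorname{mean}(RR))}
           {\operatorname{sd}(RN - \operatorname{mean}(RR))}.$$

The same random gene sets are reused across the original and all rewired
networks, so $RN_i - \operatorname{mean}_j(RR_{j,i})$ is a paired,
per-replicate difference; this "paired" reading of the inner mean is the
default. The alternative reading — subtracting the grand mean of the
whole $RR$ block, which leaves the numerator unchanged but widens the
denominator — is available as `rr_mode = "grand"`. When the input set
lies next to a pathway without overlapping it, $\operatorname{mean}(DR)$
collapses (the neighbors scatter under rewiring) while $DN$ stays high,
so exactly the hidden causal pathways are promoted.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `restart` | 0.5 | restart probability $p$ of the walk |
| `n_perm` | 1000 | random gene sets per background |
| `n_nets` | 10 | rewired networks (NetPEA′) |
| `swap_factor` | 10 | successful double-edge swaps per edge when rewiring |
| `cutoff` | 1.65 | one-sided z cutoff, $p = 0.05$ |
| `tol` | 1e-10 | L1 convergence tolerance of the walk |
| `max_iter` | 1000 | iteration cap (the contraction needs ~33 at $p=0.5$) |

The restart probability of 0.5 weights retention near the seeds equally
against diffusion; `n_perm` and `n_nets` are the standard background
sizes for this method family and are fully tunable for desk-scale runs.
`swap_factor = 10` is the usual mixing heuristic for double-edge-swap
randomization: ten accepted swaps per edge leave no memory of the original
wiring while exactly preserving the degree sequence. The convergence
tolerance is deliberately strict — at $p = 0.5$ the residual shrinks by
half per iteration, so `1e-10` costs only ~33 sparse products and removes
iteration error as a practical concern.

## Numerical and procedural choices

* **Seed values.** $V$ carries raw indicator 1 per mapped seed, not
  $1/|\text{seeds}|$. Similarity scores therefore scale with seed-set
  size, but z-scores do not, because null gene sets are size-matched.
* **Averaging universe.** Pathway scores average over network-mapped
  members only; members absent from the network have no node value.
  Pathways with zero mapped members are unscorable and excluded from
  ranking (reported via the mapping step's message).
* **Isolated nodes** are retained with an all-zero transition column;
  their converged value is the restart term alone. Removing them would
  silently change seed-set sizes.
* **Zero-variance nulls.** If a pathway's null scores are constant the
  z-score is undefined; the pathway is flagged, assigned $z = 0$,
  $p = 1$, and placed after all unflagged pathways. This arises in
  practice only in degenerate settings (e.g. `swap_factor = 0`, where
  every "rewired" network is the original and the paired differences
  vanish — a useful check that the correction mechanism is real).
* **Ties** in z (or ORA p) are broken lexicographically by pathway
  identifier, making ranks a deterministic permutation.
* **ORA universe.** All network nodes by default, so the three methods
  see the same gene universe; the union of annotated genes is available
  via `ora_universe = "genesets"`.
* **Multiple testing.** The raw 1.65 / 0.05 cutoffs are the default;
  Benjamini–Hochberg adjustment is available behind `bh = TRUE`.
* **Random gene sets** are drawn uniformly from network nodes. A
  degree-matched variant (decile binning on degree) exists behind
  `degree_matched = TRUE` for users worried about hub bias, but it is off
  by default: the plain uniform null is the reference behavior.
* **Determinism.** One integer `seed` governs sampling and rewiring; the
  sub-streams are consumed in a fixed order, so equal seeds give
  byte-identical results end to end.
* **Rewiring edge cases.** Graphs admitting no valid swap (a single
  edge, a star) are returned unchanged with a warning rather than
  erroring, so permutation loops never die mid-run.

## What the synthetic scenarios emulate — and what they do not

`generate_scenario()` builds a planted-partition graph: disjoint modules
of `module_size` nodes wired with intra-module edge probability `p_in`
over a background of density `p_out`, each module registered as a
pathway, plus decoy pathways drawn as uniform random node sets. The
default desk-scale scenario is 300 nodes, five modules of 20, `p_in` 0.8,
`p_out` 0.02, and 20 decoys, with backgrounds of 200 permutations and 3
rewired networks in the heavier tests — sizes chosen so that the full
property suite replays in about a minute while keeping the planted signal
comfortably above sampling noise.

`make_input_set()` controls the direct overlap between the input and a
chosen causal module: `overlap_fraction = 1` reproduces the module
(self-recovery), while `overlap_fraction = 0` in hidden mode samples only
network neighbors of the module — an input adjacent to, but disjoint
from, the causal pathway. That regime is where ORA's p-value is 1 by
construction and only the network methods can recover the pathway, and it
is asserted as a property in the acceptance tests.

These scenarios validate the machinery, not the biology: planted
partitions have no scale-free degree structure, no hub proteins shared
between pathways, uniform module density, and exact ground truth. Passing
them shows the propagation, nulls and rankings behave as designed; it
does not certify performance on a real interactome, where identifier
coverage, annotation bias and network noise dominate.

## Evaluation utilities

For comparing methods on the same candidate collection the package
implements the three comparison procedures used in this method family:
Jaccard-style overlap of significant sets with an upper-tail
hypergeometric p-value against a fixed background count
(`overlap_significance()`); Spearman rank correlation between full
rankings (`rank_correlation()`); and positive/negative cross
verification (`cross_verification()`) — how many of a method's top-20
pathways are corroborated in others' top-20, and how many fall below
rank 100 everywhere else. The positive count endorses a pathway if *any*
other method agrees by default; the stricter all-others reading is
`mode = "all"`. The hypergeometric background defaults to the number of
candidate pathways actually loaded and should be set explicitly when
comparing against published counts.

## Known limitations

* Unweighted, undirected networks only; edge confidence scores are
  ignored on input.
* Exact string matching of identifiers; no alias resolution.
* The closed-form oracle is limited to 2000 nodes (dense solve); the
  iterative walk itself has no such limit.
* NetPEA′ costs roughly `(n_nets + 1) * (n_perm + 1)` propagations;
  batched column propagation keeps desk-scale runs in seconds, but
  genome-scale networks with the full 1000×10 background are a
  compute-cluster job, as for the original method family.
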
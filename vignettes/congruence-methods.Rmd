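---
title: "Measuring congruence between phylogenetic tree samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring congruence between phylogenetic tree samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecord)
```

## The problem

Molecular and morphological character partitions of the same taxa often
support different trees. Quantifying *how* different — across datasets with
different taxon counts, inference methods with different conventions for
summarising tree sets, and consensus trees of very different resolution —
requires statistics that are comparable across all of those axes. treecord
provides that toolkit: normalized symmetric distances, an asymmetric
proportional-congruence statistic, consensus and support machinery,
treespace ordination, and a Bayes-factor combinability verdict. Everything
operates on unrooted topologies: rooted inputs are mechanically unrooted on
entry and "clade" support is interpreted throughout as unrooted split
support.

## Distances and their normalization

For two trees on the same taxon set, the Robinson-Foulds (RF) distance is
the number of bipartitions (nontrivial splits) found in exactly one of the
two; the quartet distance counts 4-taxon subsets whose induced resolution
differs. Both are normalised here by the *maximum attainable* distance for
the pair: the total number of resolved bipartitions (respectively resolved
quartet statements) across both trees,

$$d_{RF}^{norm} = \frac{|B_1 \setminus B_2| + |B_2 \setminus B_1|}{|B_1| + |B_2|},
\qquad
d_Q^{norm} = \frac{r_1 + r_2 - 2s}{r_1 + r_2},$$

where $r_i$ counts quartets resolved by tree $i$ and $s$ those resolved
identically in both. A quartet resolved by one tree but not the other
counts as disagreement in the numerator; this is the only numerator
consistent with the maximum-distance denominator, and on two binary trees
both formulas reduce to the familiar normalized RF and classic quartet
distance. When *both* trees are stars the ratio is 0/0; the functions
return 0 with a `degenerate` attribute rather than an error, on the view
that two trees asserting nothing disagree about nothing.

The quartet engine enumerates all $\binom{n}{4}$ subsets once per tree and
assigns each a resolution status from the split matrix; this
correctness-first path is exact and entirely adequate for the taxon counts
(tens of taxa) typical of combined molecular + morphological datasets.
Pooled quartet matrices over more than 500 trees are refused without an
explicit override, since cost grows with the square of the pool.

## Proportional congruence

Symmetric distances penalise a consensus tree for being unresolved.
Proportional congruence instead asks: *of the relationships the query tree
asserts, how many does a fully resolved reference agree with?*

$$P = \frac{\#\{\text{query splits (or quartets) also in the reference}\}}
           {\#\{\text{query splits (or quartets)}\}}.$$

A query with five bipartitions, four of which occur in the reference,
scores $P = 0.8$ however resolved the reference is. The reference must be
binary (every query assertion is then comparable); a star query asserts
nothing and is an *error*, not a zero — silently coercing such trees to 0
or 1 would bias sample means, so `mean_proportional_congruence()` excludes
them and reports the exclusion tally instead.

## Consensus, support, and the collapse scan

All consensus methods are built on one substrate, the split-frequency
table of the sample. Strict consensus keeps frequency-1 splits;
majority-rule keeps frequency ≥ 0.5; the all-compatible (greedy) consensus
admits splits of any frequency in descending order whenever compatible
with everything already admitted. Admission order is always descending
frequency with ties broken lexicographically on the canonical split key
(the side not containing the first taxon in radix order), and
majority-rule shares the greedy compatibility guard: in an even-sized
sample, exactly-0.5 splits can be mutually incompatible, and the guard
plus the deterministic tie-break always yields a valid, reproducible tree.
The maximum clade credibility (MCC) tree is the *sampled* tree maximizing
the **sum** of its splits' sample frequencies (not a log-product of clade
credibilities), with ties broken by earliest sample position.

`collapse_below(tree, x)` contracts internal edges with support strictly
less than `x` — support exactly equal to the threshold survives, an
off-by-one that matters at grid points, so it is fixed and documented.
Collapsing composes as a maximum: collapsing at $x_1$ then $x_2$ equals
collapsing once at $\max(x_1, x_2)$. `collapse_scan()` sweeps the
threshold over a grid — 0, 0.01, …, 0.99 on the posterior-probability
scale, 0, 1, …, 99 on the bootstrap percentage scale — recording
resolution, mean retained support, and both congruence flavours against a
reference, which is how congruence–resolution–support relationships are
compared across inference methods on an equal footing.

NEXUS posterior samples are read with a *floor* burnin rule (the first
`floor(b * N)` trees are discarded); floor is a convention choice,
documented because rounding changes the sample by one tree.

## Treespace ordination

`pooled_distance_matrix()` computes normalized pairwise distances over
trees pooled from several labelled samples, and `classical_mds()` embeds
the matrix by principal coordinates: double-centre the squared distances,
eigendecompose, scale eigenvectors by $\sqrt{\lambda}$. Tree distances
are generally non-Euclidean, so negative eigenvalues occur; they are
clamped to zero for coordinates, the clamp count is reported, and
variance explained is computed over the positive spectrum only (so it
always sums to 1 across all positive axes). Duplicate topologies are kept
as coincident points — a posterior sample's multiplicities are signal,
not noise. Subsampling to a fixed size (customarily 1000 trees, or the
whole set when smaller) is uniform without replacement and deterministic
given a seed.

## Bayes-factor combinability

Two models of a combined dataset are compared by marginal likelihood: M1
gives each partition its own topology and branch lengths, M2 links the
topology. Run estimates are combined by arithmetic mean of the log
marginal likelihoods, and the Bayes factor is `mean(M1) - mean(M2)` in
log units. The default reading treats a decisive advantage for the
*unlinked* model as evidence of incongruence — `bf >= 5` very strong,
`3 <= bf < 5` strong, `bf < 3` combinable (favouring the linked model
with fewest free parameters) — which is the standard form of this test;
because the opposite sign convention also circulates, a
`direction = "linked_wins"` override applies the same thresholds to the
flipped statistic for sensitivity analysis. A linked-model win of any
magnitude is simply `combinable`; no extra category is invented.
Convergence of repeated runs uses a sample-standard-deviation rule
(≤ 5 log units); a verdict from non-converged runs is flagged
unreliable, and a single run is not assessable.

## What the synthetic generator emulates

`simulate_tree_cloud()` stands in for the output of tree inference: `n`
trees, each the focal topology perturbed by $K \sim
\mathrm{Poisson}(\text{dispersion})$ nearest-neighbour interchanges. NNI
is the perturbation kernel because it is the smallest topological move —
one NNI replaces exactly one split — giving the finest control over
expected distance from the centre. `simulate_partition_scenario()`
composes a synthetic twin of one combined-data study: a uniformly random
molecular truth (sequential random edge attachment, uniform over the
$(2n-5)!!$ topologies), a morphological truth `conflict` NNI moves away,
and a combined cloud centred on the recorded NNI path at a position
proportional to the morphological share of informative characters. That
interpolation is an explicit toy model of signal mixing, not a claim
about how Bayesian combined analyses actually behave. Character counts
are drawn per scenario as 1.5–5 informative morphological characters per
taxon and 10–50 molecular, echoing the relative partition sizes typical
of published combined datasets.

Consequently, passing tests show that the *statistics* behave correctly
on clouds with known geometry — distances rise with the conflict
parameter, conflicting clouds separate on MDS axis 1, consensus recovery
degrades with dispersion. They do not show that real MCMC posteriors or
MPT sets have Poisson-NNI geometry: real samples exhibit autocorrelation,
multimodality, and branch-length effects that the generator deliberately
omits.

## Numerical and scale choices

* Distances, congruence and consensus are topology-only; zero-length and
  absent branch lengths are equivalent, and branch-length-aware metrics
  are out of scope.
* Support harvesting precedence is fixed: a square-bracket comment
  annotation after a closing parenthesis beats a numeric node label, with
  a warning on conflict (MrBayes emits comments; TNT emits labels). The
  support scale is inferred: values in [0, 1] are posterior
  probabilities, values in (1, 100] bootstrap percentages.
* Trees with mismatched taxon sets are a hard error everywhere;
  `restrict_tree()` exists for explicit, deliberate pruning.
* The test suite exercises trees of 4–50 taxa, clouds of up to 500
  trees, 200 random pairs against the brute-force quartet oracle, and a
  20-replicate conflict-recovery grid at 20 taxa and 60 trees per cloud —
  sizes at which the exact engines are comfortably fast while still
  covering the regimes the statistics are designed for.

## Limitations

* The proportional-congruence statistic is defined only against a fully
  resolved reference; no behaviour is offered when the reference itself
  is partial, since any convention would silently change the denominator.
* Quartet computations are exact but $O(n^4)$; hundreds of taxa call for
  specialised quartet algorithms outside this package's scope.
* The combinability module consumes marginal-likelihood estimates; it
  does not estimate them.
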
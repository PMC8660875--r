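---
title: "Estimating and comparing group semantic networks from verbal fluency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing group semantic networks from verbal fluency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flunet)
```

## The model

`flunet` treats a group's verbal-fluency output as noisy observations of a
latent semantic network. The observable is a binary response matrix `M`
(participants × exemplars, `M[p, e] = 1` if participant `p` produced
exemplar `e`). Exemplars that tend to be produced by the same participants
are assumed to be close in semantic memory, which motivates the cosine
association

$$A_{ij} = \frac{c_{ij}}{\sqrt{f_i f_j}},$$

with $c_{ij}$ the number of participants producing both exemplars and
$f_i$ the production frequency of exemplar $i$. $A_{ij}$ ranges from 0
(never co-occur) to 1 (always co-occur). The diagonal is stored as 0 and
never used: self-similarity carries no edge information.

A raw cosine matrix is dense and dominated by weak, spurious
co-occurrences, so it is sparsified with the **triangulated maximally
filtered graph (TMFG)**: start from the 4-clique of nodes with the
greatest total association, then repeatedly insert the remaining node
whose three connections into an existing triangular face have the largest
summed weight, splitting that face into three. The result is connected,
planar, and has exactly $3n - 6$ edges for $n$ nodes — so two groups
equated to the same node set automatically get the same edge count, which
removes network size as a confound in every downstream comparison.

Three standard measures summarize the filtered network:

* **CC** — the Watts–Strogatz mean local clustering coefficient: the
  average, over nodes, of the fraction of a node's neighbor pairs that are
  themselves connected (degree < 2 contributes 0; this cannot occur on a
  TMFG, whose minimum degree is 3).
* **ASPL** — the mean hop-count shortest-path length over all unordered
  node pairs.
* **Q** — Newman–Girvan modularity
  $Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]$ of the best partition
  found by Louvain community detection across seeded restarts.

## Pipeline order and contracts

The estimation order is: per-group minimum-occurrence filter (an exemplar
must be produced by **at least 2 participants** of a group) → cross-group
node equating (intersection of the two surviving column sets) → cosine →
TMFG. Filtering precedes equating. Every stage is deterministic; the only
stochastic components are community detection restarts, the random-graph
ensembles and the bootstrap, all driven by derived substreams of one
master seed, so a full analysis reproduces bit-for-bit under a fixed
configuration.

Inference runs on two complementary tracks:

* **Random-graph nulls.** Each empirical measure is located within the
  distribution of the same measure over `iters_null` Erdős–Rényi draws of
  matched size. The phrase "same number of nodes and edges with a fixed
  edge probability" admits two readings, G(n, m) and G(n, p); the default
  is $G(n, p)$ with $p = m / \binom{n}{2}$, which matches the edge count
  in expectation, and a `null_model = "gnm"` switch provides the
  exact-edge-count variant. ASPL of a disconnected draw is computed on the
  largest component, the standard convention that keeps the statistic
  finite. The two-sided percentile p uses add-one counting,
  $p = 2\min(1 + \#\{x \le \hat\theta\}, 1 + \#\{x \ge \hat\theta\}) /
  (\text{iters} + 1)$, capped at 1 — p is never exactly zero and the floor
  attainable with 1000 draws is $2/1001 \approx 0.002$; reporting
  thresholds below that requires more iterations, and the report prints
  the floor alongside each p.
* **Case-wise bootstrap.** Each iteration resamples every group's
  participants with replacement to the original group size and re-runs
  the *entire* estimation. Node equating is re-applied inside each
  iteration by default — the fully case-wise reading; a
  `equate_per_iteration = FALSE` flag instead fixes the full-sample node
  set, for sensitivity analysis. Iterations whose estimation fails (an
  empty node intersection is possible in principle with tiny groups) are
  redrawn and counted, keeping the distribution length at `iters`. The
  group distributions are then compared with a pooled-variance Student t
  (df = `iters_a` + `iters_b` − 2; with 1000 iterations per group,
  df = 1998) and Cohen's d from the pooled SD, labeled against the
  0.20 / 0.50 / 0.80 benchmarks. d carries the sign of t throughout.

A known caveat, reproduced deliberately: t tests on bootstrap replicate
distributions treat simulation replicates as observations, so the df (and
hence the p values) overstate certainty relative to the two original
samples. The procedure is standard in this literature and is implemented
as such; effect sizes (d) are the more interpretable output, and the
random-graph track provides an independent check.

## Measures: unweighted by default

All three measures are computed on the **unweighted** (binarized) TMFG
graph by default. ASPL is defined in steps (edges), and using one
convention for all three measures keeps CC, ASPL and Q commensurate.
Whether a weighted or unweighted convention was used in any given
published analysis is often unstated and cannot be recovered from
reported values alone; both are therefore available, and
`weighted_metrics = TRUE` switches to the Barrat local clustering
coefficient, inverse-weight shortest paths, and weighted Louvain/Q for
sensitivity analysis.

Louvain is order-dependent, so `modularity_q()` runs `restarts` seeded
restarts under random node permutations and keeps the best-Q partition
(resolution fixed at 1). The empirical networks use 100 restarts; inside
bootstrap and null iterations the default drops to 10, since those
estimates are averaged over hundreds of draws and the occasional slightly
suboptimal partition adds noise well below the resampling variance. Q is
reported for the best-found partition, not an ensemble average, matching
standard practice for a single summary value. The Q *formula* is the
package's own implementation (`partition_modularity()`); only the
partition search is delegated to igraph's Louvain, which keeps
`igraph::modularity()` available as an independent cross-check in the test
suite.

## Preprocessing choices

* Case-folding plus accent-stripping before any lookup: the motivating
  datasets are French, where "léopard"/"leopard" must merge. A fixed
  transliteration table covers Latin accents, with iconv transliteration
  as a fallback.
* Variant merging is **table-driven** (a `variant → canonical` CSV), not
  algorithmic stemming: no stemmer is assumed by the method, and a table
  is auditable by the analyst.
* Off-lexicon responses are dropped with a logged message, never an
  error: excluding non-category members is part of the method, and a typo
  in one transcript should not abort a cohort analysis.
* Column order of every response matrix is lexicographic in the canonical
  labels, making matrices (and therefore every downstream object)
  deterministic across runs and platforms.
* "Exclusive" responses of a group are operationalized as the set
  difference of the groups' produced-exemplar sets (computed before any
  frequency filtering). Published unique/exclusive counts do not always
  pin down a unique operationalization; the set-difference reading is the
  one implemented and reported.

## TMFG numerical details

The TMFG literature fixes the greedy scheme but not every tie rule. The
implementation uses: seed clique = the 4 nodes with the largest total
association to all others; insertion = the (node, face) pair with maximal
3-edge gain; ties broken by lowest lexicographic node label, then
earliest-created face. These choices make the filter fully deterministic;
on matrices with continuous weights ties are measure-zero and the rules
are inert. n < 4 nodes or an all-zero matrix are errors — with fewer than
4 nodes the $3n-6$ target is meaningless, and an all-zero matrix carries
no association signal to filter. The test suite checks the greedy
construction step-for-step against exhaustive (node × face) maximization
on small matrices, and planarity via an independent implementation.

## The synthetic cohort generator

Real child fluency data are typically not shareable, so the package
generates cohorts with controlled ground truth:

* **Ground truth** — a planted-partition (stochastic block model) graph:
  `n_concepts = 120` concepts in `n_modules = 6` equal modules,
  within-module edge probability `p_in = 0.35`, between-module probability
  `p_out` set per group (defaults 0.08 vs 0.02 for the two-group study
  generator, making group A's semantic graph the less modular one).
  Disconnected draws are rejected and redrawn.
* **Production model** — a censored random walk, the standard generative
  account of fluency: start at a salience-weighted random concept, step to
  a salience-weighted random neighbor, restart at a random concept with
  probability `jump_prob = 0.05`, and emit a concept only on first visit,
  so lists contain no repeats by construction. The target list length is
  truncated-normal (min 1, max the concept count) with per-group means and
  SDs of 16.4 (5.0) and 14.8 (5.8) — the scale of one-minute animal
  fluency in school-age children — over 36 and 31 participants.
* **Salience** — both groups share one lognormal concept-salience profile
  (`sdlog = 1.3`). This produces the Zipf-like production frequencies of
  real fluency data: a core of prototypical exemplars produced by nearly
  everyone, a long tail produced by one participant or none. With these
  defaults each group produces roughly 90–105 distinct exemplars of the
  120-concept universe and the equated, filtered networks have ~55–70
  nodes — the scale at which the pipeline is meant to operate. With
  uniform salience the same cohorts would cover nearly the whole universe
  and the ≥2-participant filter would bind almost never, which is not
  what empirical response matrices look like.

What the generator does **not** emulate: retrieval dynamics in time
(inter-response intervals), age or ability covariates, cross-category
intrusions, perseverations (the censoring removes them by construction),
and any direct link between network structure and behavioral scores.
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers group differences *of the kind generated* — notably
ground-truth modularity differences, which the recovery tests show are
signed correctly by the bootstrap comparison in ≥ 90% of seeds at study
scale — not that any particular empirical dataset will show them.

## Problem sizes used in the shipped tests

The test suite favors many small, oracle-checked cases over few large
ones: exhaustive TMFG and partition oracles run at n ≤ 6 and n ≤ 8,
where enumeration is exact; pipeline-level tests run at the study scale
(36 vs 31 participants, 120 concepts) with bootstrap and null ensembles
of 20–200 iterations, and the recovery test uses 20 generator seeds at
200 bootstrap iterations. These sizes are where the statistical
properties under test are already visible; production analyses should use
the 1000-iteration defaults.

## Limitations

* The networks are group-level: individual-level network metrics are not
  estimable from one fluency list per participant with this method, so
  network structure cannot be correlated with individual outcomes.
* The bootstrap-t df caveat above.
* TMFG always returns exactly $3n - 6$ edges, including when the
  underlying association structure is weaker than planar-maximal; the
  filter's constraint is a feature for group comparison and a bias for
  absolute interpretation of single-network measures (hence the
  random-graph track).
* The minimum-occurrence threshold (default 2) and the lexicon are the
  analyst's responsibility; both materially change the node set, and the
  descriptives report makes the consequences visible.
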
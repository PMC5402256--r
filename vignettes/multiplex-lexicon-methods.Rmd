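---
title: "Multiplex lexical networks and the prediction of early word acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplex lexical networks and the prediction of early word acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A toddler's mental lexicon stores words together with several kinds of
relations between them at once. `lexiplex` represents this as an
*edge-coloured multiplex lexical network*: one shared vocabulary of $N$
words and $L$ undirected simple-graph layers, each encoding one relation —
free association (a cue elicits a target), semantic feature sharing,
co-occurrence in child-directed speech, and phonological similarity
(phoneme edit distance one). There are no inter-layer links; a layer acts
as a colour on its edges. Association direction and all edge weights are
discarded at build time, and the working vocabulary is the intersection of
the inventory word list with the words holding at least one connection on
any layer, iterated to a fixed point.

Three ideas drive the analysis:

1. **Topology.** Each layer is summarised (mean degree, mean local
   clustering, degree assortativity, largest-component share, mean shortest
   path within it) and contrasted with degree-preserving configuration-model
   nulls obtained by double-edge swaps. Cross-layer structure is measured by
   Kendall tau-b correlations between per-layer degree vectors, by pairwise
   edge overlap $|E_i \cap E_j| / \min(|E_i|,|E_j|)$ against the same nulls,
   and by *structural reducibility*: each layer maps to the density matrix
   $\rho = L_{\mathrm{lap}}/\mathrm{tr}(L_{\mathrm{lap}})$, layers are
   compared by the Jensen–Shannon divergence between density matrices, a
   Ward dendrogram is built on $\sqrt{\mathrm{JSD}}$, and every cut is
   scored by the relative entropy
   $q = 1 - \langle h \rangle_{\mathrm{groups}} / h_{\mathrm{aggregate}}$,
   where $h$ is Von Neumann entropy. The multiplex is *irreducible* when
   $q$ is strictly maximal with no merges (ties favour merging, so duplicate
   layers report as reducible).

2. **Ordering prediction.** Any word score $s_i$ — a layer centrality
   (degree, harmonic closeness, betweenness, PageRank), a multiplex
   centrality on the layer union, or a word attribute (frequency, negative
   length) — induces a predicted acquisition trajectory by sorting scores in
   decreasing order. Normative trajectories are sampled from production
   norms: a word counts as known once 50% of children produce it in a
   month; months are scanned in order and the currently eligible words are
   drawn sequentially without replacement with probability proportional to
   that month's production fraction. Predictions are compared with the
   normative ensemble through the overlap $O(\tau, t)$ (shared words among
   the first $t$ of both orderings, averaged over the ensemble), the word
   gain $g(\tau,t) = O(\tau,t) - t^2/N$ (the subtrahend is the exact
   hypergeometric mean for a random ordering), the normalized gain
   $G = g/t$, and the Z-score $Z = g/\sigma(O(\tau_{\mathrm{ran}},t))$.

3. **Layer influences.** Weighted-multiplex word scores are convex
   combinations $s_w = \sum_\ell w_\ell \, \tilde s^{(\ell)}_w$ of per-layer
   scores, each layer min–max normalized to $[0,1]$ first (raw degree and
   closeness scales differ by orders of magnitude, so unnormalized
   combinations would make the weights meaningless; rank and z-score
   normalizations are available). The weights maximizing the mean normalized
   gain over a learning-stage window are found by differential evolution
   and averaged over repeated random removals of 20% of the words, with a
   degree-preserving randomized-multiplex control run for contrast.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| co-occurrence threshold | 45 counts | edge requires *strictly more* than this many co-occurrences |
| production threshold | 0.50 | fraction of children producing a word for it to count as known |
| months | 16–30 | inventory reporting range |
| Gaussian minimum $t$ | 60 words | first inventory size where the random-overlap law is treated as Gaussian; below it, direct sampling |
| significance level | 0.025 one-sided | critical $Z = 1.96$ |
| null ensemble | 100 samples, 10 swaps/edge | configuration-model comparisons |
| normative ensemble | 30 orderings | samples from the production norms |
| hold-out scheme | 50 configs × 20% | Monte Carlo robustness of the optimization |
| DE | pop $15L$, dithered $F\in[0.5,1]$, CR 0.7, ≤200 generations, tol $10^{-6}$ | optimizer settings |
| PageRank damping | 0.85 | teleport probability 0.15, uniform |

Learning stages follow the months of the norms: a very early stage (VELS,
months 19–20, operationally the first 40 learned words), an early stage
(ELS, months 20–23) and a late stage (LLS, months 23–28); month windows are
converted to inventory-size windows through the number of words whose
production has crossed the threshold by each month.

## Design choices in ambiguous territory

* **Closeness variant.** Three of the four layers are heavily fragmented,
  so classic closeness is undefined across components. The package uses
  harmonic centrality normalized by $N-1$ (unreachable pairs contribute 0)
  by default and offers the classic within-component variant for
  sensitivity analysis.
* **Multiplex path metrics.** The edge-coloured multiplex has no inter-layer
  links or jump costs, so closeness and betweenness are computed on the
  unweighted union of the layers (a hop costs 1 whichever layer supplies the
  edge). Multiplex PageRank runs on the union weighted by the number of
  layers carrying each edge — with identical node sets and no inter-layer
  coupling, the supra-adjacency construction of versatile PageRank reduces
  to this.
* **Tie handling.** "Averaging over all resolutions" of tied scores is
  combinatorially infeasible verbatim, so the default policy computes the
  *exact expected* overlap contribution of each tied block (a block-wise
  hypergeometric expectation); a Monte Carlo resolutions policy exists and
  agrees in expectation (property-tested).
* **Hold-out semantics.** The robustness analysis optimises over *subsets
  of word trajectories* holding 80% of the words: held-out words are removed
  from the predicted and reference trajectories (scores stay those of the
  full network) and the evaluation window is rescaled proportionally; final
  performance is reported on all words. The alternative of recomputing
  scores on the induced 80% subnetwork is available
  (`holdout_mode = "induced"`) but answers a different question — how robust
  the mechanism is to deleting vocabulary from the *network* — and we found
  it biases planted-weight recovery, so it is not the default.
* **Sub-threshold words.** Words never reaching 50% production by the last
  month are appended to sampled trajectories by final-month-production-
  proportional draws (zero fractions floored at $10^{-6}$), so every sample
  is a full permutation.
* **Direct sampling.** When no reference ensemble is passed, the direct-
  sampling p-value uses the exact single-reference law of the random
  overlap (hypergeometric draws), which is what a permutation sample
  converges to; with an ensemble, random orderings are drawn and evaluated
  against it.
* **Baseline sd against ensembles.** The gain curve averages overlaps over
  the reference ensemble, so the matching null sd is that of the
  *ensemble-averaged* random overlap. `random_baseline()` accepts the
  reference ensemble in Monte Carlo mode for exactly this purpose; with a
  single reference (or a perfectly correlated ensemble) it coincides with
  the analytic hypergeometric sd. Using the single-reference sd against a
  weakly correlated ensemble would overstate $\sigma$ and shrink $Z$.
* **Degenerate inputs.** Empty layers give zero-degree statistics and
  undefined (NA) assortativity rather than NaN propagation; constant score
  vectors min–max normalize to all zeros; constant degree vectors yield NA
  Kendall correlations; zero-weight-sum candidates are rejected inside the
  DE objective.

## What the synthetic generator emulates

The generator plants the statistical structure the analysis expects to
see, so every stage can be exercised end to end without external data:

* per-layer degree sequences from exponential (feature, phonological) or
  Pareto-tailed (association, co-occurrence) marginals with mean degrees
  9.3 / 9.0 / 8.1 / 1.31 matching the empirical scales, coupled across
  layers by a latent Gaussian copula with target Kendall correlations
  (+0.20 association–feature and association–co-occurrence, −0.16
  feature–co-occurrence, +0.27 co-occurrence–phonological);
* extra triangles by random wedge closure (the empirical layers are more
  clustered than their configuration models) and edge copying between the
  semantic layer pairs (their empirical edge overlap exceeds null
  expectations);
* Zipfian word frequencies with lengths negatively rank-correlated with
  frequency;
* production norms from a planted mechanism: a convex combination of layer
  degree scores (default 0.6/0.2/0.2/0.0, association-dominant with
  negligible phonology, mirroring the optimization findings) maps
  monotonically to acquisition-onset months spread over the reporting
  range, perturbed by Gaussian noise (default sd 0.5 months), with
  logistic production curves (slope 2 per month) confined so every word
  crosses 50% production and reaches 95% by the final month.

What it does **not** emulate: real lexical content (no actual words,
features, or phonology), part-of-speech structure, non-monotone or censored
production curves, reporting noise in the norms, and any dependence between
a word's attributes and its network position beyond the planted mechanism.
Passing tests therefore demonstrate that the machinery measures what it
claims on data with known ground truth — not that the cognitive
conclusions transfer to any particular empirical dataset.

Degree realization uses Havel–Hakimi construction followed by randomizing
double-edge swaps; non-graphical sampled sequences are repaired by shaving
the largest degrees. Clustering and overlap boosts add edges, so realized
mean degrees exceed the marginal targets when boosts are active; achieved
correlations and overlaps are always measured on the generated instance
rather than trusted from the targets.

## Numerical choices

Von Neumann entropies drop eigenvalues below $10^{-12}$; JSD values are
clipped at 0. PageRank uses damping 0.85 with igraph's stationary solver
(power-iteration cross-checked in the tests to $10^{-6}$). The DE objective
evaluates the gain on a grid of at most 25 window points (the full window in
the exported `objective()`), and ranks tied combined scores by exact
expected overlap, making the objective deterministic given the ensemble.
Weight simplex handling: DE searches $L$ box-bounded coordinates in
$[0,1]$, normalized by their sum inside the objective; zero-sum candidates
are penalized. Reported mean weights renormalize the per-run means.
Problem sizes in the packaged analyses — $N = 529$ for the descriptive
stages, $N = 200$ with 30 normative orderings and 10 hold-out
configurations for recovery experiments, 100-sample null ensembles — were
chosen so the full pipeline reruns in minutes while keeping Monte Carlo
standard errors well inside the tolerances asserted by the tests.

## Known limitations

* The mean-based reducibility quality can prefer merging two dense,
  high-entropy layers when a very sparse layer drags the group-mean
  entropy down; verdicts on strongly density-heterogeneous multiplexes
  should be read together with the quality profile, not as a binary.
* Multiplex closeness/betweenness on the unweighted union is one reading of
  "free jumps through layers"; formulations with explicit inter-layer
  couplings would differ.
* The sampled normative orderings inherit the month resolution of the
  norms: within-month order is informed only by production fractions.
* DE convergence is declared on the population fitness spread; on flat
  ridges (e.g. duplicated informative layers) the split of weight between
  interchangeable layers is not identifiable — only their sum is.
* The randomized-multiplex control rewires layers while preserving degree
  sequences, so it is an identity for degree-based scores: per-layer degrees
  — and hence degree-optimized gains — cannot change under it. The control
  is informative only for topology-sensitive metrics (closeness,
  betweenness, clustering), which is how the package's recovery experiments
  use it.
* `objective()` rescales stage windows proportionally under hold-out, which
  keeps windows comparable across configurations but is one of several
  defensible conventions.

## Reproducibility

Every stochastic routine takes an integer seed; ensembles derive per-member
seeds from a master seed via `split_seed()`, so `run_pipeline()` runs are
byte-identical given the same configuration. The numbered scripts under
`analysis/` rerun the whole study from scratch, and
`scripts/acceptance.R --seed S --out results/acceptance.json` recomputes
the headline quantities in one shot.
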
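# lexiplex

Multiplex lexical networks and the prediction of early word acquisition.

Toddlers do not learn words in a vacuum: a new word is phonologically close
to known words, shares features with them, co-occurs with them in
child-directed speech, and is cued by them in free association. `lexiplex`
models an English-speaking toddler's mental lexicon as an **edge-coloured
multiplex network** — one shared vocabulary of words, with four undirected
layers (free association, semantic feature sharing, co-occurrence,
phonological similarity) and no inter-layer links — and asks how well
network structure predicts the *normative order* in which words are
acquired between 16 and 30 months.

The package is aimed at cognitive/linguistic network scientists and
developmental psycholinguists who want to run this kind of analysis on
their own relational norms and inventory data, or to study the method
itself on synthetic data with planted ground truth.

## The statistics at the core

A word score $s_i$ (layer degree, harmonic closeness, betweenness,
PageRank, a multiplex variant on the layer union, word frequency, or
negative word length) induces a predicted acquisition trajectory
$\tau = (w_1, \dots, w_N)$ by sorting scores in decreasing order.
Normative trajectories $\tau_{aoa}$ are sampled from month-by-month
production norms (a word is "known" once 50% of children produce it;
within a month, eligible words are drawn without replacement with
probability proportional to production). Predictions are evaluated by

* overlap $O(\tau, t)$ — words shared by the first $t$ positions of the
  prediction and a normative ordering, averaged over the ensemble;
* word gain $g(\tau, t) = O(\tau, t) - t^2/N$, the excess over the exact
  hypergeometric mean for random guessing;
* normalized gain $G = g/t$ and Z-score
  $Z = g/\sigma(O(\tau_{ran}, t))$, with $Z \ge 1.96$ marking significance
  at the one-sided 2.5% level (direct sampling replaces the Gaussian
  approximation below 60 acquired words).

Layer *influences* are estimated by maximizing the mean normalized gain of
a convex combination of per-layer scores,
$s_w = \sum_\ell w_\ell\, \tilde s^{(\ell)}_w$, with differential
evolution, averaged over repeated random 20% word removals, and contrasted
with a degree-preserving randomized-multiplex control. Topology is
characterised against configuration-model nulls, including Von Neumann
entropy / Jensen–Shannon structural reducibility of the layer set.

## Worked example

Everything below runs on synthetic data with a planted acquisition
mechanism — no downloads.

```r
library(lexiplex)

spec <- synthetic_spec(N = 100, seed = 7)   # 4 layers, CDI-like norms
ds   <- generate_dataset(spec)
aoa  <- sample_aoa_ensemble(ds$norms, n = 30, seed = 11)
base <- random_baseline(100)

pred  <- rank_by_score(multiplex_centrality(ds$mln, "closeness"))
curve <- significance(gain_curve(pred, aoa, base), base,
                      gaussian_min_t = 60, n_direct = 10000, seed = 3)
curve[c(10, 25, 50, 75), ]
#>                label  t overlap   gain norm_gain zscore pvalue significant significance_method
#>  multiplex_closeness 10   8.267  7.267     0.727  8.034      0        TRUE     direct_sampling
#>  multiplex_closeness 25  23.400 17.150     0.686  9.101      0        TRUE     direct_sampling
#>  multiplex_closeness 50  46.211 21.211     0.424  8.442      0        TRUE     direct_sampling
#>  multiplex_closeness 75  71.917 15.667     0.209  8.314      0        TRUE            gaussian
```

Read: by the time 25 words are acquired, ranking words by multiplex
closeness correctly anticipates 23.4 of them on average — 17.2 words
(69% of the inventory) more than random guessing would, nine standard
deviations above the random-overlap fluctuation, significant under direct
sampling. Gains shrink as the inventory approaches the full vocabulary
(every ordering ends at $O(N) = N$).

Stage-wise comparison uses the month-to-inventory map implied by the norms:

```r
stage_report(list(curve), stage_windows(), inventory_size_by_month(ds$norms))
#>  stage               label t_lo t_hi mean_norm_gain rank
#>   VELS multiplex_closeness    1   40          0.596    1
#>    ELS multiplex_closeness   33   57          0.485    1
#>    LLS multiplex_closeness   58   98          0.173    1
```

The full study — simulate, topology vs nulls, reducibility, scoring,
ordering evaluation, layer-influence optimization — is scripted as numbered
drivers:

```sh
Rscript analysis/01_simulate.R --seed 20
Rscript analysis/02_topology.R
Rscript analysis/03_reducibility.R
Rscript analysis/04_scores_orderings.R
Rscript analysis/05_evaluate.R
Rscript analysis/06_optimize.R
```

Each writes its tables under `results/`. Real data enter through plain
TSV/CSV readers (`read_association_tsv()`, `read_feature_tsv()`,
`read_cooccurrence_tsv()`, `read_phon_lexicon_tsv()`, `read_cdi_norms()`)
and the same pipeline (`run_pipeline()`, `pipeline_config(inputs = ...)`).

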
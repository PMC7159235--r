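---
title: "Scoring the loss-of-function tolerance of enhancers"
author: "enhtol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the loss-of-function tolerance of enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhtol)
```

## The problem

Protein-coding genes that can be lost homozygously in healthy individuals
are called LoF (loss-of-function) tolerant, and catalogs of such genes have
become standard references for variant prioritization. `enhtol` asks the
same question of enhancers: which regulatory elements can an individual
genome lose entirely, on both haplotypes, without apparent fitness cost?
The package builds the training labels, the network features, and the
classifier needed to answer it, and emits a per-enhancer probability of LoF
tolerance, `P(LoF-tol)`, in `[0, 1]`.

## Training labels from deletions and ultraconserved elements

**Tolerant class.** A deletion observed in a homozygous state in at least
one individual, and not touching any coding exon, is evidence that the
sequence it removes is dispensable. An enhancer is labeled LoF-tolerant only
when it is *fully contained* in such a deletion — partial deletion is not
treated as loss, which makes the label conservative. Containment is closed
under boundary equality (an enhancer exactly coinciding with a deletion is
deleted). Exon overlap disqualifies a deletion at a single shared base pair;
no minimum-overlap threshold is applied, again the conservative choice.

**Low-tolerance class.** Ultraconserved elements with validated in-vivo
enhancer activity are expected to cause fitness defects when lost, even
where single-knockout animals look superficially normal. An enhancer joins
the low-tolerance class when it has strict `> 50%` *reciprocal* overlap with
such an element: the shared span must exceed half the enhancer's length and
half the element's length. The reciprocal requirement prevents a long
element from capturing every small enhancer it happens to cover, and vice
versa. The reporter-validation requirement is an input property of the
conserved-element set, not something this package can compute.

The two label sets are disjoint by construction of a `label_set`; an
enhancer qualifying for both (possible only on adversarial input) is
excluded from both and reported. Enhancer length is deliberately *not* a
model feature: fully deleted enhancers skew short, and a length feature
would let the classifier learn the ascertainment artifact instead of the
biology.

## The integrated network and its feature vocabulary

Regulation is contextual, so features are computed on a single
heterogeneous graph (`build_meganet()`): enhancer nodes, gene nodes,
directed enhancer→gene regulation edges annotated with the set of tissue
groups in which the link is active (edge weight = tissue count), and
undirected gene–gene interactions restricted to four physically direct
layers (protein–protein, metabolic, phosphorylation, signaling). Indirect
layers — genetic interactions, co-expression, regulatory inference — are
excluded by a type whitelist. Each undirected interaction is stored as two
opposite directed edges; unique-neighbor degree counts are unaffected while
path-based centralities treat the interaction symmetrically.

Per enhancer, `compute_enhancer_features()` derives:

| Feature | Meaning |
|---|---|
| `EOD` | number of genes the enhancer regulates (out-degree) |
| `ETU` | number of distinct tissues the enhancer is active in |
| `EGTUa`, `EGTUv` | mean and population variance of per-edge tissue counts |
| `GIDa/v` | target-gene in-degree (enhancers regulating the gene) |
| `GCCa/v` | target-gene closeness centrality |
| `GDCa/v` | target-gene degree fraction (share of nodes adjacent) |
| `GPRCa/v` | target-gene PageRank (damping 0.85) |
| `GECa/v` | target-gene eigenvector centrality |
| `GISa/v` | target-gene indispensability score (input, in `[0,1]`) |
| `<tissue>__EOD` | out-degree within each tissue subnetwork |
| `<tissue>__GIDa` | mean target in-degree within each tissue subnetwork |
| `conservation` | per-enhancer sequence conservation (input, in `[0,1]`) |

Every gene-level quantity X is aggregated over an enhancer's `n` target
genes as a mean `Xa = Σ X(g_i)/n` and a *population* variance
`Xv = Σ (X(g_i) − Xa)²/n`. The denominator-`n` convention follows the
printed edge-ubiquity formulas and is applied uniformly; an enhancer with a
single target has variance 0, not missing. The canonical worked example: an
enhancer with two regulation edges active in tissue sets `{red, green}` and
`{blue}` has `ETU = 3`, edge-ubiquity list `(2, 1)`, `EGTUa = 1.5`,
`EGTUv = 0.25`.

### Numerical choices for the centralities

These solver details are design choices of this package, with igraph doing
the heavy lifting and independent brute-force implementations checking it
in the test suite:

* **Closeness** uses the reachability-scaled form
  `(R/(n−1)) · (R/S)` with `R` nodes reaching the target at total
  shortest-path distance `S`, on the directed graph (so a gene's closeness
  reflects paths *into* it, through enhancers and interactions alike);
  unreached nodes score 0 rather than dropping out.
* **Degree fraction** counts unique neighbors in either direction over
  `n − 1`, so it lies in `[0, 1]` and doubled interaction edges do not
  inflate it.
* **PageRank** runs on the directed graph, unweighted, damping 0.85.
  Tissue-count edge weights are deliberately not used: the weighting
  convention of the upstream networks is a count, not a transition
  probability, and unweighted PageRank keeps the oracle comparison exact.
* **Eigenvector centrality** is computed on the undirected view of the
  graph (regulation symmetrized for this metric only), which guarantees a
  real principal eigenpair. It is evaluated by a shifted power iteration
  `(A + I)x` with a fixed start vector, scaled to maximum 1. A fixed
  iteration makes the feature matrix bit-identical across runs —
  Krylov/ARPACK solvers with random restarts are not bit-reproducible, and
  reproducibility is part of this module's contract. The shift removes
  oscillation on bipartite components.

### Feature pruning and imputation

Correlated columns are pruned greedily (`prune_correlated_features()`):
columns are visited in alphabetical order and, for any live pair with
Spearman `|ρ|` at or above the threshold, the later-named column is
dropped; an explicit drop list (e.g. tissue blocks known to be redundant)
is honored first, and every drop is recorded in a provenance attribute. The
default threshold of 0.9 is intentionally high — pruning exists to remove
near-duplicates (like mirrored tissue blocks), not to do feature selection;
the forest handles the rest. Missing values (genes without an
indispensability score, enhancers without conservation) are imputed by
column median by default; zero-fill and row-dropping are available, and
imputed cells are flagged in provenance.

## The balanced-resampling forest

The label design is extremely asymmetric: hundreds-to-thousands of tolerant
enhancers versus a few dozen low-tolerance ones. Training a single model on
that imbalance would mostly teach the prior. Instead,
`balanced_repeat_train()`:

1. draws a fixed number of positives (default 50) per repeat, cycling
   through a shuffled positive pool without replacement so that every
   positive enters training at least once when
   `repeats × pos_per_repeat ≥ |positives|`;
2. pairs them with *all* negatives;
3. searches random-forest hyperparameters (a random draw over tree count,
   `mtry`, and leaf size, then a local grid refinement around the best
   `mtry`), scoring each candidate by stratified 10-fold cross-validated
   mean AUROC;
4. repeats the whole process (default 50×) and refits the forest of the
   repeat with the highest mean AUROC on its full balanced sample; ties
   break by mean AUPRC, then by lower repeat index.

All randomness flows from one master seed through recorded per-repeat
seeds, so the sampled ids, fold assignments and selected repeat are exactly
reproducible. Predicted probabilities are the mean of per-tree class
probabilities; calls are `tolerant` at `p ≥ 0.5`, with confident calls at
`p > 0.95` and `p < 0.05`. Scoring excludes the training ids.

Two negative controls guard against self-deception. Permuting the labels
among the labeled enhancers must collapse the across-repeat average of mean
AUROCs to chance. And `null_model_check()` replaces the negatives with
random unlabeled enhancers: a result near 0.5 certifies that the small
negative class does not by itself let the forest overfit. For chance-level
checks the package reports the *across-repeat average* — the maximum over
repeats is upward-biased by selection and is only meaningful for the
positive, signal-present question.

Feature importances (mean decrease in impurity, normalized to sum 1) are
reported per feature and summed over four groups — gene-side aggregates,
conservation, enhancer topology (`ETU`, `EOD`, per-tissue `EOD`), and edge
ubiquity — via the feature-name schema.

## Downstream statistics

The validation module keeps each analysis a tidy, testable table:

* `tissue_enrichment()` — per tissue, a 2×2 Fisher's exact test of class
  membership against all other tissues. The default counting unit is the
  enhancer–tissue *membership* (an enhancer active in k tissues contributes
  k memberships), matching percentage-by-tissue summaries; distinct-enhancer
  counting is available by flag. Zero cells get a Haldane–Anscombe +0.5
  correction for the odds ratio only, flagged.
* `ks_compare()` — two-sample Kolmogorov–Smirnov D with the asymptotic
  p-value, plus the pooled ECDF pair for plotting.
* `group_comparison()` — Wilcoxon rank-sum p and Cohen's d (pooled SD;
  positive means the first group is higher) for tolerant-vs-GW,
  tolerant-vs-low and low-vs-GW; exact Wilcoxon enumeration for groups of
  ≤ 20, normal approximation with tie correction otherwise. A zero pooled
  SD flags d as undefined rather than inventing a value.
* `discovery_curve()` — LoF-tolerant enhancers discovered as genomes are
  added in nested random prefixes; monotone by construction.
* `match_disease_enhancers()` — overlap match (largest overlap, ties to the
  smaller start) else nearest edge-to-edge on the chromosome; retained only
  when the reported target gene is among the matched enhancer's regulated
  genes; cancer-type rows are excluded as somatic.
* `motif_enrichment()` — a motif is present when any window on either
  strand reaches 80% (configurable) of the motif's maximum achievable
  log-odds score, with a 0.5 pseudocount against a uniform background;
  windows containing N never match. Per-class presence fractions, Fisher
  enrichment against GW, and Benjamini–Hochberg adjustment within class.

On p-value calibration: Fisher's exact test is conservative on discrete
tables — `P(p ≤ α) ≤ α` holds with room to spare — so under random labels
its p-values are *valid* but sit detectably above the uniform
distribution. The test suite asserts validity (super-uniformity) at several
α levels; a strict distributional-uniformity assertion is also present and
is expected to fail for exactly this reason, which is a property of the
exact test, not of the implementation.

## What the synthetic generator emulates — and what it does not

`generate_universe()` builds, from one seed, every input the pipeline
consumes: enhancer/exon/conserved-element BEDs, a tissue-annotated
enhancer→gene network, gene–gene interaction lists, a genotyped deletion
VCF, gene indispensability and enhancer conservation tables, enhancer
FASTA, motif PWMs, a disease-enhancer table and a ground-truth manifest.
The default spec — 2,000 enhancers, 600 genes, 15 tissue groups, 60
samples, two 10-Mb chromosomes, signal strength 3 — runs the full pipeline
in about two minutes on one CPU and is the condition under which the
package's own acceptance checks operate. The 49 low-tolerance enhancers of
the default spec mirror the size of the real curated negative set; 160
tolerant-like enhancers (8%) keep the positive pool comfortably above one
balanced draw.

Geometry is slot-based: each enhancer owns a private genomic slot, so
deletions and conserved elements planted for one enhancer cannot
accidentally label a neighbor, and the manifest is exactly recoverable by
curation. "Trap" configurations sit deliberately just outside each rule:
full-coverage deletions that are never homozygous, homozygous deletions
covering only part of an enhancer, homozygous full deletions that also clip
a planted exon, conserved elements below the reciprocal threshold or too
long to pass it.

Class-conditional signal follows the biology the features are meant to
detect, scaled by `signal_strength` s (at s = 0 all classes share one
distribution): tolerant-like enhancers are active in few tissues, regulate
one or two highly redundant (high in-degree), dispensable (low GIS) genes,
and carry low conservation; low-like enhancers are broadly active, regulate
several indispensable genes, and are highly conserved. Tissue preferences
steer tolerant-like enhancers toward immune-like groups and low-like toward
brain/kidney-like groups so that enrichment analyses have structure to
find.

What it does *not* emulate: linkage and haplotype structure (genotypes are
independent), realistic sequence composition (uniform background with
planted consensus motifs), overlapping regulatory architecture (one
enhancer per slot), and the long right tail of real deletion sizes. Passing
tests on this universe therefore demonstrate that the machinery implements
its contracts and recovers planted signal — not that real-data performance
will match any particular number.

`generate_pacbio_like_deletions()` emulates a deep long-read callset on a
3-genome panel: novel calls overlap every base call by < 80% of their own
length, and a subset fully, homozygously deletes background enhancers the
base callset never touched — by default the most tissue-specific ones,
standing in for genuinely tolerant elements that a short-read survey simply
missed.

## Problem sizes used by the checks

The packaged tests run the full protocol at the default universe scale
(2,000 enhancers; 50 repeats × 10 folds with hyperparameter search) for the
signal, permuted-label and null-model checks; oracle equivalence uses 100
random heterogeneous graphs of ≤ 30 nodes at 10⁻⁶ agreement; end-to-end
determinism compares complete output checksums of two pipeline runs on a
300-enhancer universe at 6 repeats. A smaller 400-enhancer universe backs
the unit tests.

## Known limitations

* Gene indispensability and conservation are inputs; the package does not
  recompute them, and median imputation of their gaps is a pragmatic, not a
  principled, choice.
* The enhancer→gene links are taken as given; mispredicted targets
  propagate directly into gene-side features.
* Probabilities are raw tree-vote means; no calibration beyond the forest
  itself is applied, so thresholds (0.5 / 0.95 / 0.05) should be read as
  operating points, not calibrated risks.
* Whether gene centralities should be computed on the full heterogeneous
  graph or the gene–gene layer alone is a genuine modeling fork; this
  package computes them on the full graph (enhancers included), which makes
  gene centrality sensitive to regulatory load as well as interaction
  topology, and flags the alternative as a sensitivity analysis a user can
  run by building the network without regulation edges.
* SNV- or indel-mediated enhancer loss is out of scope; only whole-element
  deletion counts as LoF here.
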
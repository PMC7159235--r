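# enhtol — loss-of-function tolerance scoring for human enhancers

Some enhancers can be deleted from both haplotypes of a healthy genome with
no apparent cost; others are expected to cause fitness defects when lost,
even singly. `enhtol` is for regulatory-genomics researchers who want a
per-enhancer **probability of loss-of-function (LoF) tolerance** to
prioritize non-coding variants: a deletion hitting a high-`P(LoF-tol)`
enhancer is a poor disease-candidate, while low-scoring enhancers are where
causal regulatory variants are more likely to hide.

## The method

1. **Labels.** LoF-*tolerant* enhancers are those fully contained
   (`enhancer ⊆ deletion`, boundary equality included) in a deletion that
   occurs homozygously in ≥ 1 individual and overlaps no coding exon.
   *Low-tolerance* enhancers have strict > 50% reciprocal overlap with
   ultraconserved, reporter-validated elements. The classes are disjoint by
   construction.
2. **Features.** An integrated heterogeneous network ("MegaNet") joins
   directed, tissue-annotated enhancer→gene regulation edges with
   undirected gene–gene interactions (protein–protein, metabolic,
   phosphorylation, signaling; stored as paired directed edges). Per
   enhancer: out-degree EOD, tissue ubiquity ETU, edge tissue-ubiquity mean
   and population variance

   EGTUa = Σᵢ eᵢ / n,  EGTUv = Σᵢ (eᵢ − EGTUa)² / n

   over the per-edge tissue counts (e₁…eₙ); target-gene in-degree (GID),
   closeness (GCC), degree (GDC), PageRank (GPRC) and eigenvector (GEC)
   centralities and indispensability scores (GIS), each aggregated over
   targets as mean ("a") and population variance ("v"); per-tissue EOD/GIDa
   blocks; sequence conservation. Spearman-correlated columns are pruned at
   |ρ| ≥ 0.9.
3. **Classifier.** A random forest trained under a balanced-resampling
   protocol: 50 repeats × (50 sampled positives + all negatives),
   hyperparameter search scored by stratified 10-fold CV mean AUROC, final
   model = the winning repeat's forest. Scores are mean per-tree class
   probabilities; calls at p ≥ 0.5, confident calls at p > 0.95 / p < 0.05.
   A permutation control and a pseudo-negative null-model check guard
   against small-sample overfitting.
4. **Validation.** Tissue enrichment (Fisher's exact), score-distribution
   comparisons (Kolmogorov–Smirnov), group effect sizes (Wilcoxon +
   Cohen's d), genome-count discovery curves, disease-enhancer matching,
   and PWM motif enrichment with Benjamini–Hochberg adjustment.

A seeded synthetic-data module generates every input format the pipeline
consumes (BED, VCF with genotypes, network and interaction TSVs, scalar
tables, FASTA, JASPAR-style PWMs) with controllable class signal and a
ground-truth manifest, so the whole method is testable offline.

## Worked example

```r
library(enhtol)

spec <- fixture_spec(n_enhancers = 400, n_genes = 150, n_tissues = 6,
                     n_samples = 24, chrom_length = 3e6,
                     class_fractions = c(tolerant = 0.2, low = 0.13),
                     seed = 7)
universe <- generate_universe(spec)
#> <synthetic_universe> 400 enhancers (background=268, low=52, tolerant=80),
#>   144 deletions, 24 samples, 6 tissues; seed 7

deletions <- homozygous_noncoding_deletions(universe$deletions, universe$exons)
labels <- label_set(call_lof_tolerant(universe$enhancers, deletions),
                    call_low_tolerance(universe$enhancers, universe$conserved))
#> <label_set> 80 LoF-tolerant, 52 low-LoF-tolerance

net <- build_meganet(
  dplyr::summarise(dplyr::group_by(universe$network, enhancer, gene),
                   tissues = list(sort(unique(tissue))), .groups = "drop"),
  universe$interactions)
#> <meganet> 400 enhancers, 150 genes; 1029 regulation edges,
#>   293 gene-gene interactions; 6 tissue groups

features <- compute_enhancer_features(net, gis = universe$gis,
                                      conservation = universe$conservation)
features <- impute_missing(prune_correlated_features(features, 0.9), "median")
training <- balanced_repeat_train(features, labels, repeats = 10, seed = 1)
#> <balanced_training> 10 repeats; mean AUROC 1.0000 +/- 0.0000;
#>   selected repeat 1 (AUROC 1.0000)

scores <- predict_scores(training$model, features)
head(scores, 3)
#> # A tibble: 3 x 4
#>   enhancer_id          p_lof_tol binary_call confident_call
#> 1 chr1:1010000-1010761     0.836 tolerant    none
#> 2 chr1:1022000-1023856     0.868 tolerant    none
#> 3 chr1:1034000-1035169     0.968 tolerant    tolerant

feature_importance_report(training$model)$groups
#> # A tibble: 4 x 2
#>   group        importance
#> 1 gene             0.716
#> 2 enhancer         0.148
#> 3 conservation     0.102
#> 4 edge             0.0340
```

The labels recover the generator's ground-truth manifest exactly; the
cross-validated AUROC of 1.0 reflects the deliberately strong class
separation of this fixture (signal strength 3), and the `P(LoF-tol)`
column is the per-enhancer probability the classifier assigns to tolerated
loss. The grouped importances show gene-side network features carrying most
of the signal, with enhancer topology, conservation and edge ubiquity
following — the ordering the features were designed to expose.

A command-line wrapper with subcommands
`simulate / curate / build-net / features / train / predict / validate`
ships at `inst/cli/enhtol.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "enhtol.R", package = "enhtol"))')
Rscript $CLI simulate --n-enhancers 400 --seed 7 --out-dir universe
Rscript $CLI curate --enhancers universe/enhancers.bed \
    --deletions universe/deletions.vcf --exons universe/exons.bed \
    --conserved universe/conserved.bed --out-prefix cur
```

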
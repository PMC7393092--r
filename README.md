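# epifinemap

Functional fine-mapping of noncoding GWAS risk variants from epigenetic
feature maps.

Genome-wide association studies report loci, not variants: linkage
disequilibrium means each association signal covers a block of
statistically indistinguishable SNPs, most of them neutral passengers,
and the causal variant is usually noncoding. `epifinemap` prioritizes
the functional variant inside each association block from the regulatory
annotations of its SNPs — open chromatin (DHS), histone marks,
transcription-factor binding sites and pathway membership — on the
premise that true risk variants across different loci share common
regulatory patterns that shuffled annotations do not.

It is aimed at statistical geneticists doing post-GWAS interpretation:
the inputs are ordinary summary statistics (SNP, chromosome, position,
p-value), interval annotation tracks (BED) and gene-set files, and every
stage is an R function that takes and returns tibbles.

## The method

1. **Association blocks.** SNPs with `p > 5e-4` are discarded; lead SNPs
   are chosen greedily by smallest p-value, at least 1 Mb apart; each
   lead collects its most significant flanking SNPs into a
   non-overlapping block of at most 30 members.
2. **Feature map.** Every member SNP gets a binary vector over the
   annotation tracks; features absent in more than 95% of blocks are
   dropped. Control ("false-case") blocks are made by permuting each
   feature column within a block — per-feature marginals survive,
   SNP-level co-occurrence does not.
3. **Uncertainty-weighted network.** Each block is a bag of SNP vectors
   scored by a two-layer network: `K = 50` filters spanning the feature
   axis with ReLU (a per-SNP pattern detector), a linear combiner with a
   sigmoid, and max-pooling over SNPs for the block score
   *f*<sup>(m)</sup> — the multiple-instance assumption that one
   functional SNP makes the block positive. Training minimizes

   LOSS = −(1/B) Σ<sub>m</sub> W<sup>(m)</sup> [ Y<sup>(m)</sup> log f<sup>(m)</sup> + (1−Y<sup>(m)</sup>) log(1−f<sup>(m)</sup>) ] + λ₁‖w‖₁ + λ₂‖w‖₂²

   where the label-confidence weight W steps over the block's minimum
   p-value: 10 below 5e-8, then 8, 6, 4, 2 across successive bands up to
   5e-4, and 2 for every control. The filter bank is pretrained as a
   denoising autoencoder on the SNP vectors; false cases outnumber true
   cases ten to one; chromosomes 1–10 train, 15–22 validate (early
   stopping and tuning), 11–14 test.
4. **Interpretation.** SNPs with score > 0.5 are candidate risk
   variants. A random-forest surrogate (100 trees, mtry 10) trained on
   the network's SNP calls yields Gini importances with label-permutation
   p-values, and categories are tested for over-representation with
   exact hypergeometric and binomial tails. Candidates map to genes via
   3 kb promoters and enhancer–gene links, and blocks carrying a
   genome-wide-significant tag-SNP (p < 5e-8) are flagged.

A bundled generator (`generate_dataset()`) builds self-contained
synthetic datasets — blocks with tiered minimum p-values, sparse binary
features, one planted causal SNP per causal block — so the whole
pipeline is testable offline.

## Worked example

The synthetic benchmark: 25 blocks × 30 SNPs × 200 features, 20 causal
blocks each hiding one causal SNP enriched in 20 causal features
(carrier probability 0.7 vs 0.05 background).

```r
library(epifinemap)

dir <- tempfile("synth")
synth <- generate_dataset(synth_config(), dir)

sumstats <- read_summary_stats(synth$paths$sumstats)
blocks   <- build_blocks(sumstats, select_lead_snps(sumstats))
dplyr::n_distinct(blocks$block_id)
#> [1] 25

tracks   <- read_track_manifest(synth$paths$manifest)
filtered <- filter_features(build_feature_tensor(blocks, tracks))
controls <- generate_control_blocks(filtered$tensor, ratio = 10, seed = 17)

fit <- train_cnn(filtered$tensor, controls, model_config())
fit
#> <cnn_fit> 50 filters x 200 features; stopped at epoch 287
#>   (best validation loss 0.562 at epoch 247)

all_t    <- bind_tensors(filtered$tensor, controls)
test_set <- subset_tensor(all_t, all_t$chrom %in% chromosome_split()$test)
evaluate_model(fit, test_set)
#> <cnn_eval> AUC = 1, F1 = 0.6667 at block-score threshold 0.5

scores <- predict_snp_scores(fit, filtered$tensor)
imp <- snp_importance(filtered$tensor, scores, n_perm = 100, seed = 17)
head(imp[order(-imp$gini), ], 3)
#>   feature category assay    gini perm_p significant
#> 1 feat017 neural   histone  3.10      0 TRUE
#> 2 feat009 neural   TFBS     1.81      0 TRUE
#> 3 feat002 immune   histone  1.69      0 TRUE

pri <- prioritize_variants(scores, blocks,
                           read_gene_annotation(synth$paths$genes),
                           read_enhancer_links(synth$paths$enhancers))
score_recovery(synth$truth, pri$candidates, imp)
#> # A tibble: 1 × 3
#>   snp_recall snp_precision feature_recall
#> 1       0.85          0.85              1
```

Held-out blocks are separated perfectly (AUC 1.0); 17 of the 20 planted
causal SNPs score above 0.5 with 17 of 20 calls correct, and all 20
causal features land in the top 20 Gini importances (the three shown are
all planted). F1 at the fixed 0.5 threshold is lower than the AUC
because block scores are calibrated against a 10:1 weighted control
excess, which keeps some true-block scores under 0.5 even when ranking
is perfect.

`autoplot()` methods cover the fit (loss curves), the evaluation (ROC)
and the importance table; `tidy()`/`glance()` give broom-style
summaries. A command-line front end for every stage ships in
`inst/cli/epifinemap.R`.

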
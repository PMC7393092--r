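---
title: "Methods: uncertainty-weighted functional fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-weighted functional fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind `epifinemap`, the choices we
made where the design was genuinely open, and what the bundled synthetic
benchmark does and does not demonstrate.

## The problem and the model

A GWAS association signal is a *bag* of linked SNPs; at least one member
is assumed functional, but no SNP-level label exists. `epifinemap`
treats this as multiple-instance learning. Each SNP is a binary vector
over `M` regulatory features. A per-SNP scorer

$$s_j = \sigma\!\left(c^\top \mathrm{ReLU}(F x_j + b) + c_0\right)$$

applies `K = 50` filters `F` (each spanning the whole feature axis — a
pattern detector over regulatory annotations, deliberately blind to
neighboring SNPs), and the block score is the max-pool
$f = \max_j s_j$ over the block's real (unmasked) SNP slots: one
strongly functional SNP suffices to call the bag positive.

Negative bags are manufactured, not observed: each control block copies
a true block and independently permutes every feature column across its
SNP slots. Per-feature marginals are conserved exactly (our tests assert
this), while the within-SNP co-occurrence that the filters detect is
destroyed. Ten controls are generated per true block, sampled with
replacement so no divisibility constraint arises.

Because neither bag label is gold-standard, each block carries a
label-confidence weight in the cross-entropy:

$$\mathrm{LOSS} = -\frac{1}{B}\sum_{m=1}^{B} W^{(m)}\!\left(Y^{(m)}\log f^{(m)} + (1-Y^{(m)})\log(1-f^{(m)})\right) + \lambda_1\lVert w\rVert_1 + \lambda_2\lVert w\rVert_2^2$$

with `B = 100` the mini-batch size and `W` a step function of the
block's minimum p-value — 10 below 5e-8, then 8, 6, 4, 2 over
successive ten-fold bands up to 5e-4 — and 2 for every control. The
printed tiers use strict inequalities on both sides, which leaves the
boundary points undefined; we resolve a boundary into the *weaker*
(higher-p) tier, so a minimum of exactly 5e-8 gets weight 8. The
elastic-net penalty covers both layers' weight vectors and excludes
biases, the conventional reading of a penalty on "weights".

## Coordinate and boundary conventions

These conventions are load-bearing and all tested:

* Summary statistics are 1-based; annotation intervals are 0-based
  half-open BED. A SNP at 1-based position `p` overlaps `[start, end)`
  iff `start <= p - 1 < end`.
* Lead selection is greedy by smallest p-value (ties: chromosome, then
  position ascending), removing same-chromosome SNPs within 1 Mb, so
  selected leads are strictly more than 1 Mb apart.
* A SNP qualifying for two blocks goes to the lead with the smaller
  p-value, then the nearer lead, then the lower position — assignment is
  deterministic and order-independent, and blocks never share SNPs.
* Block membership (lead included) caps at 30. The flanking window
  around a lead is a parameter; the default ±1 Mb equals the lead
  spacing radius, the natural choice given that the exclusion zone
  already owns those SNPs.
* The sparse-feature filter drops a feature iff the fraction of blocks
  with no annotated member is *strictly* greater than 0.95; it is
  computed on true-case blocks only, and controls inherit the surviving
  axis (controls are column permutations, so their marginals could not
  change the decision anyway).
* Promoters are the 3 kb strictly upstream of the TSS on the gene's
  strand, TSS excluded: `[tss - 3000, tss)` on `+`, `(tss, tss + 3000]`
  on `-`.
* Candidate calls use score `> 0.5`, strictly.

## Optimization

Parameters are trained by mini-batch SGD with momentum 0.9 and learning
rate 0.01 on the loss above; the max-pool routes each block's gradient
through its current argmax slot only (first index on exact ties).
Inside the likelihood, `f` is clamped to `[1e-7, 1 - 1e-7]`; analytic
gradients match central finite differences to better than 1e-5 in the
tests.

The filter bank is initialized by a tied-weight denoising autoencoder on
the training-split true-case SNP vectors (controls are synthetic
shuffles, not real SNPs, so they are excluded; masked padding slots are
excluded too). Inputs are corrupted by independent zeroing at rate 0.2
and reconstruction uses elementwise cross-entropy — the standard choice
for binary data. This matters more than it may sound: the strongest
co-occurrence structure in the data *is* the causal pattern, so a
well-trained autoencoder already contains a near-separating
representation; on the benchmark a linear probe on the pretrained hidden
layer separates causal from non-causal SNPs essentially perfectly.

Two scheduling choices depart from a plain joint fine-tune, and both
were adopted after the plain schedule demonstrably failed the benchmark:

* **Combiner warm-up** (`warmup_epochs = 50`): the pretrained filter
  bank is frozen while the randomly initialized combiner trains. Without
  it, early joint updates — dominated by the 10:1 weighted control
  excess — can destroy the pretrained features before the combiner
  discovers them, and the outcome swings with the initialization seed.
* **Strong ridge** (`lambda2 = 3e-2`): the weighted max-pool objective
  has a degenerate sharp optimum in which the network memorizes the
  exact annotation pattern of one SNP per training block (a memorized
  row is perfectly absent from that block's shuffles), which generalizes
  to nothing. A substantial L2 penalty makes the memorization solution
  expensive relative to the shared causal detector and lets validation
  loss keep improving long enough (`patience = 40`, `max_epochs = 400`)
  for the detector to sharpen past the 0.5 score threshold.

Early stopping tracks the weighted NLL (penalty excluded) on the
validation chromosomes, and the parameters from the best validation
epoch are returned. `tune_cnn()` runs the same selection protocol as a
random search over learning rate, both penalties, warm-up and
autoencoder length when defaults need revisiting on other data. Batches
mix true and control blocks uniformly at random (seeded) rather than
stratifying; with `B = 100` against ~10% positives, every batch sees
positives in expectation and we saw no benefit from stratification.

Remaining honest caveat: trained trajectories on a problem this small
are seed-sensitive. The shipped defaults are calibrated on the benchmark
conditions below; on other datasets run `tune_cnn()` rather than
trusting them blindly.

## Interpretation stages

The surrogate random forest (100 trees, 10 features per split) is
trained on SNP vectors labeled by the network's own calls
(score > 0.5). Permutation p-values refit the forest under `n_perm`
label shuffles and count `perm_p = #(permuted gini >= observed) /
n_perm`, with ties counting against significance — the conservative
reading of "exceeded". Repressive marks (H3K9me3/H3K27me3) are excluded
before fitting; they are domain-scale marks not specific to individual
SNPs. Category over-representation among significant features is tested
twice, with the exact hypergeometric tail (pmf evaluated in log space
and summed over `X >= k`) and the binomial analogue at background
`K/N`; both appear in the output so the report can name which was used.
The per-SNP annotation display uses one-sided binomial tails with the
category's share of surviving features as the default background.

## The synthetic generator

`generate_dataset()` emulates exactly the statistical structure the
model assumes: blocks of linked SNPs (round-robin across chromosomes
1–22, centers 3 Mb apart so blocks cannot interact through the 1 Mb
rule), block minimum p-values drawn log-uniformly within a weight tier
(equal mixture over the five tiers by default — no empirical tier
distribution is assumed, and equal mass exercises every weight), sparse
Bernoulli(0.05) background features, and in each causal block a single
causal SNP carrying each of the 20 designated causal features with
probability 0.7. Feature vectors are generated first and tracks
reverse-engineered as 1-bp BED intervals — simpler than simulating peak
geometry and sufficient for contract testing. Gene annotations place
each block's lead in a promoter and each causal SNP in an enhancer so
the mapping stage runs end to end.

Causal blocks are the *first* `n_causal_blocks` indices rather than a
random draw: ground truth then does not depend on the random stream, so
changing the seed perturbs noise but never the design. One causal SNP
per causal block keeps recall unambiguous while matching the modeling
assumption that a true block carries at least one functional variant.

The default benchmark is 25 blocks × 30 SNPs × 200 features, 20 causal
blocks, seed 17 — small enough that generation, training and the
random-forest permutations together stay in a few minutes on one CPU,
large enough that the held-out chromosomes contain causal blocks.

**What passing this benchmark shows:** the pipeline's contracts hold
(block construction, filtering, null conservation), optimization
recovers a planted cross-block regulatory pattern, and the importance
stage re-identifies the causal features. **What it does not show:** real
LD (our blocks are positional, not correlational), realistic annotation
geometry or inter-feature correlation, realistic effect sizes, or
calibration of the 0.5 threshold on real GWAS data. The five non-causal
true blocks are genuinely unlearnable positives — by design — which is
why F1 at the fixed threshold sits below the AUC.

## Degenerate inputs and numerical notes

Empty lead sets return empty block tables, not errors; a lead with no
qualifying neighbors forms a singleton block; all-zero blocks shuffle to
all-zero controls; a chromosome absent from every annotation track
yields an all-zero vector. Masked slots are zero-filled, excluded from
max-pooling and from autoencoder training. Probabilities are clamped at
1e-7 from both ends inside every log. Exact p-value ties during lead
selection and member ranking break by (chromosome, position) ascending
for reproducibility; exact score ties in the max-pool take the first
slot.
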
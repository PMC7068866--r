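---
title: "Sampling the uncertainty space of gene signatures"
author: "phenoSamplers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling the uncertainty space of gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Binary phenotype prediction from expression data — metastasis versus
disease-free, survived versus deceased — is badly underdetermined: a
typical study measures tens of thousands of transcripts on the order
of a hundred samples. Given a classifier $L^{*}$ and a gene subset
("genetic network") $g$, write $O(g)$ for the percentage of misclassified
samples and $\mathrm{Acc}(g) = 100 - O(g)$. Because $s \gg n$, the set

$$ M_{tol} = \{\, g : O(g) < tol \,\} $$

of networks predicting the phenotype almost equally well is large: many
distinct small signatures are practically indistinguishable by accuracy.
Interpreting any *single* optimal signature biologically is therefore
fragile. The alternative implemented here is to *sample* $M_{tol}$ with
several priors and to rank genes by their posterior sampling frequency
across all retained high-accuracy networks: genes that keep reappearing
no matter how the space is explored are the robust discriminants, and —
under the hypothesis of biological invariance — the pathway-level signal
should not depend on which sampler found them.

In Bayesian terms each sampler realises, implicitly, a posterior
proportional to prior × likelihood over networks: a prior over gene
subsets (Fisher's-ratio-weighted, holdout-driven, or uniform) and a hard
likelihood that retains a network when its cross-validated accuracy
exceeds a threshold. No explicit posterior factorisation is attempted;
the samplers only need to visit the high-probability region.

## Shared machinery

**Per-gene statistics.** For gene $j$ with class means $\mu_{j1},
\mu_{j2}$ and class variances $\sigma^2_{j1}, \sigma^2_{j2}$, the
Fisher's ratio

$$ FR_j = \frac{(\mu_{j1} - \mu_{j2})^2}{\sigma^2_{j1} + \sigma^2_{j2}} $$

scores univariate discrimination. Variances are unbiased ($n-1$) sample
variances; means are arithmetic (a median option exists). Values are
assumed already normalised, typically on a log2 scale, so the difference
of class means is the log2 fold change; the loader never normalises, and
an optional `log2(x + 1)` flag handles linear-scale input. Genes with
zero pooled variance are degenerate: $FR = \infty$ when the means differ
(ranked first), $0$ otherwise.

**Filtering.** A gene is *discriminatory* when $|\mathrm{log2FC}| \geq
1$ (configurable; the conventional two-fold screen) **and** $FR_j >
0.8$, i.e. class centers separated by more than $\sqrt{0.8} \approx
0.89$ pooled standard deviations. The cutoff is strict; a gene at
exactly 0.8 is excluded. When fewer than 10 genes survive, the cutoff
relaxes automatically to 0.5 with a message — the cutoff is a tuning
parameter, and very sparse survivor sets leave the samplers nothing to
explore.

**Classifier.** A k-NN classifier (default $k = 1$, "nearest
neighbour") with Euclidean distance restricted to the signature's genes,
scored by leave-one-out cross-validation, or — for holdout bags — by
blind prediction of validation samples from training samples only. All
ties are deterministic: equidistant neighbours resolve to the smallest
training index, vote ties to class 1. This makes every accuracy
bit-reproducible.

**Minimum-scale signature.** Genes are ranked by decreasing $FR$ and
the nested prefixes of the ranking are scored by LOOCV; the shortest
prefix attaining the global maximum is the minimum-scale signature. This
nested-prefix sweep is the deterministic form of recursive backward
elimination on an FR ranking (each step removes the lowest-ranked gene
and never re-ranks). Ties on the maximum go to the shorter prefix, and a
cap (default 200) bounds the examined length on very wide survivor
lists. The signature's length is the problem's complexity estimate and
bounds the network lengths the samplers draw.

## The three samplers

**Fisher's ratio sampler (FRS).** The ranked genes are split into
*headers* — the genes carrying the main discrimination — and *helpers* —
genes adding detail. The split point $FR_{min}$ is, by default, the
Fisher's ratio of the last minimum-scale-signature gene (so headers are
at least the minimum-scale genes; the inclusive comparison keeps that
last gene a header). Within each pool, selection weights are
proportional to $FR_j$. Each draw picks a network length uniformly in
$[1, L_{mss}]$, a header count uniformly in $1..\min(\mathrm{length},
\#\mathrm{headers})$ — every network contains at least one header, since
helpers alone cannot discriminate — and fills the network by
inverse-cdf draws without replacement (implemented as successive
renormalised weighted draws, the same distribution as rejecting
duplicates). Networks are scored by LOOCV and retained above the
accuracy threshold.

**Holdout sampler (HS).** A completely different paradigm: 1000 random
75/25 train/validation bags (both counts configurable). Per bag, the
*entire* selection chain — statistics, filter, minimum-scale search —
runs on the training split alone; the bag's signature is then scored
blindly on the validation split. Validation labels can influence only
the retention decision, never the signature: perturbing them provably
leaves every affected bag's signature unchanged (this is tested). Bags
are stratified by class by default — with class imbalance like 29 of
107, unstratified 25% splits occasionally lose a class entirely; an
unstratified mode exists. Validation counts are
$\max(1, \lfloor 0.25\, n_c \rfloor)$ per class. Bags whose training
split yields no discriminatory gene are skipped with a warning.

**Random sampler (RS).** The uniform-prior control: networks of uniform
random length in $[1, L_{mss}]$, genes drawn uniformly without
replacement from the same discriminatory pool. RS uses the least prior
information and is therefore the most explorative — the entropy of its
pre-retention draw distribution is never below FRS's on the same pool
(tested).

**Retention and posterior frequencies.** A network is retained when its
accuracy strictly exceeds the threshold (default 85%, the point found to
give enough explicative networks; a threshold of 0 is read as "retain
everything", which the null protocol below relies on). Each gene's
posterior frequency is its occurrence count across retained networks
divided by the *total number of gene occurrences* (the summed lengths of
the retained networks — not the number of networks; both readings exist
and this one is stated explicitly). Ranking is by decreasing frequency,
ties by probe identifier. Cross-sampler agreement is summarised by
top-$N$ overlaps and Jaccard indices (default top-10; `"top-30"` is the
scale at which one would hand a list to an ontology tool).

## The synthetic study conditions

`simulateExpressionData()` generates the conditions everything is tested
under: 1000 independent Gaussian genes × 80 samples (40 per class), 10
planted discriminatory genes whose class means differ by `effectSize = 3`
within-class standard deviations, `noiseSd = 1`. The scale preserves the
$s \gg n$ character of a real transcriptomic study at desk cost, and
effect size 3 plants an analytically known signal: a planted gene's
population Fisher's ratio is $\mathrm{effectSize}^2/2 = 4.5$, just as a
real study's headline discriminators sit far above the 0.8 cutoff. A
block-correlation option gives the planted genes a shared latent factor,
so correlated genes substitute for one another inside high-accuracy
networks — the equivalent-network phenomenon in its purest form.

What the generator deliberately omits: probe-level noise models, batch
effects, heavy-tailed expression, correlated *null* genes, class
imbalance (configurable but not default). Passing tests therefore show
the samplers recover planted independent Gaussian signal — they do not
certify behaviour under microarray artefacts.

```{r, eval = FALSE}
library(phenoSamplers)
sim <- simulateExpressionData(seed = 1)
cfg <- samplerConfig(nSamples = 1e4, nBags = 200, seed = 1)
fit <- fitDiscriminatoryGenes(sim$experiment, cfg)
frs <- runFisherSampler(sim$experiment, fit$ranked, fit$mss, cfg)
head(geneFrequencies(frs))
```

## Numerical and design choices

* **Variance estimator:** unbiased sample variance. With tens of samples
  per class the difference from the population estimator shifts $FR$ by
  a factor $\frac{n-1}{n}$-ish — genes near the cutoff can flip, which
  is why the estimator is fixed and documented rather than silent.
* **Accuracy ties in the minimum-scale search** are compared with a
  $10^{-9}$ tolerance (accuracies are ratios of small integers; the
  tolerance only guards against float noise) and resolved toward the
  shorter prefix.
* **Seeding:** every stochastic entry point takes a single integer seed
  from `SamplerConfig`; reruns are bit-identical. Samplers run serially;
  there are no parallel substreams.
* **Retention at threshold 0** keeps all networks (a strict `>` would
  drop 0%-accuracy networks, which is never what "no threshold" means).
* **Null-recovery protocol:** on effect-size-0 data the default filters
  correctly reject every gene — the right behaviour, but it leaves
  nothing to sample. Chance-level recovery is therefore measured with
  permissive filters (`foldChangeThreshold = 0`, `frCutoff = 1e-9`) and
  full retention, where the posterior must reproduce the uniform prior:
  expected top-10 overlap with the 10 planted genes is 0.1 genes in
  1000.
* **Problem sizes in the test-suite and acceptance runs:** the samplers
  are exercised at $10^4$–$10^5$ draws and 200–1000 bags on the default
  1000 × 80 conditions; unit tests use smaller instances (tens to
  hundreds of genes) chosen to keep each property sharply attributable.
* **RS pool:** the same fold-change + Fisher's-ratio survivors as FRS.
  Whether the uniform sampler should also drop the FR cutoff is
  genuinely open; applying both keeps the two samplers' posteriors
  comparable over an identical support.
* **Header/helper mix per FRS draw** (uniform length, then uniform
  header count) is a documented choice; the original scheme is
  underdetermined beyond "some headers and some helpers".

## Limitations

* Only two-class problems; no multi-class extension.
* The classifier is k-NN by design (the likelihood the method
  prescribes); other classifiers would test biological invariance more
  broadly but are out of scope.
* Frequencies are *sampling* frequencies under each prior, not
  normalised posterior probabilities — no evidence term is computed.
* Pathway/ontology enrichment of the ranked lists is external to the
  package; the deliverable is the ranked discriminatory gene list and
  the cross-sampler concordance.
* With very small validation splits (a few samples), HS validation
  accuracies are coarse (steps of $100/n_v$), so the 85% threshold can
  act as "no misclassification allowed"; the bag count compensates.
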
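---
title: "Assessing batch-effect adjustment with ontology scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing batch-effect adjustment with ontology scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoscore)
```

## The problem

Integrative transcriptomic analyses pool RNA-seq samples from different
consortia, labs and platforms. Batch-effect adjustment (BEA) is routinely
applied before such analyses, but on *heterogeneous* collections — many
sample types, few samples per type, types unevenly spread over batches — it
is genuinely unclear whether a given adjustment helped or quietly removed
biology. Visual inspection of PCA plots does not scale and is subjective.

The ontology score turns the question into a per-sample measurement. Cell
types are not interchangeable labels: a curated cell-type ontology encodes
how similar two types are expected to be. If an expression matrix is healthy,
the similarity structure among its samples should agree with the similarity
structure the ontology predicts — and a BEA method is beneficial exactly when
it moves the observed structure closer to the expected one.

## The score

Three objects are computed:

1. **Expected similarity matrix `O`.** Every ontology term `t` has an
   ancestor set `A(t)`: the term itself plus all terms reachable over
   subclass (`is_a`) edges. Only subclass edges are used; `part_of` and other
   relations are ignored. Term similarity is either the Jaccard index of the
   two ancestor sets or the cosine of their binary indicator vectors. The
   indicator vectors live on the full term axis, but entries outside either
   ancestor set contribute nothing, so the cosine reduces to
   `|A(t_i) n A(t_j)| / sqrt(|A(t_i)| |A(t_j)|)` and the implementation works
   on sets. Mapping each sample to a term and broadcasting term similarities
   over sample pairs yields `O`.

2. **Observed similarity matrix `D`.** Samples are embedded by PCA on the
   gene-centered expression matrix (default `log2(TPM + 1)`), keeping the
   first 4 components by default. `D[k, l]` is the Spearman correlation of
   the two samples' PC coordinate vectors.

3. **Ontology score `u`.** For each sample `k`,
   `u_k = cor(D[, k], O[, k])` — the (Spearman, by default) correlation
   between how similar sample `k` looks to every sample and how similar it
   ought to look. One score per sample, rather than a single global matrix
   agreement, preserves sample-level detail: scores can be summarised per
   tissue, per consortium, or per combination (`group_scores()`).

The defaults — cosine similarity for `O`, Spearman for `D` and for `u` — are
the reference scheme; `jaccard` and `pearson` variants are available and in
practice change little.

## Reference models

Two nulls calibrate what a score means:

* **Randomized ontology** (`randomize_mapping()`): every sample is
  reassigned a term drawn uniformly with replacement from all non-obsolete
  terms. `D` is untouched; only `O` changes. Scores under this null center
  on zero. Drawing from the full term set (not only mapped terms) mirrors
  the view that any ontology term is an admissible label; a flag restricts
  the draw to observed terms for a harder null.
* **Fixed two-valued ontology** (`fixed_similarity_matrix()`): same-group
  pairs get similarity 1.0, all other pairs 0.25. This retains group
  identity but discards the graded between-type structure; scores under it
  sit between the null and the true ontology, which demonstrates that the
  graded structure — not just group identity — carries information.

`randomization_experiment()` computes `D` once and rescoring is done per
replicate on `O` alone (replicate `i` uses `seed + i`, so replicate subsets
are independently reproducible). Comparisons use two-sided
Wilcoxon–Mann–Whitney rank-sum tests.

## Noise injection and adjustment

`add_gaussian_noise()` creates an artificial batch effect: a
`round(fraction * n)` subset of samples (rounded half away from zero; exact
count guaranteed) receives an independent `N(mu, sigma^2)` draw on every
gene, with defaults `mu = 10`, `sigma = 1`. Selection is stratified across
groups by largest-remainder allocation, so every group contains both the
clean and the noisy batch. Noise is injected by default on the scale the
scoring consumes (post-log); a flag injects on the raw scale instead —
neither mode is asserted as canonical, both are supported. Values are not
clipped: on a log scale negative values are meaningful and clipping would
bias the injected shift.

Two sweeps probe the score's sensitivity: `noise_fraction_sweep()` varies
the contaminated fraction at fixed intensity (the score decreases
monotonically), and `noise_intensity_sweep()` varies `mu` at 50%
contamination (the score drops sharply up to `mu = 10` and plateaus
beyond — once the two batches are fully separated in PC space, stronger
noise cannot separate them further).

`adjust_and_rescore()` closes the loop: it scores the clean, noisy and
adjusted matrices with one configuration and returns the three matched score
vectors. Adjusters are pluggable by name; built-ins are `identity` and
`location_scale`. The registry exists so external adjusters (empirical-Bayes
or factor-based methods from other packages) can be benchmarked through the
same interface; they are deliberately not reimplemented here.

### The baseline adjuster

`adjust_location_scale()` is the common core of location-scale BEA: per
gene, each batch is standardized by its own moments and rescaled to the
overall mean and to the *within-batch* pooled variance. Rescaling to the
total variance would be wrong — the total includes the between-batch mean
separation, i.e. the very effect being removed, and would inflate each
batch's spread by it. Population (divide-by-n) moments make the adjustment
exactly idempotent. With group labels (the default), batch moments are
estimated on group-centered residuals so biological group differences are
retained. There is no empirical-Bayes shrinkage of the per-gene estimates:
this is a baseline, not a reimplementation of shrinkage-based methods.

A subtlety worth knowing when reading benchmark output: a pure *additive
batch shift* is removed essentially exactly, and the score is restored to
its original value. Under the full `N(10, 1)` injection, however, the noise
also adds independent per-sample, per-gene jitter that no per-gene batch
transform can remove; on the synthetic generator below, whose within-group
noise (`epsilon = 0.1`) is much smaller than that jitter, the adjusted
scores recover the shift component but retain the jitter penalty (typically
half to three quarters of the drop at these settings). On real tissue
panels, where biological within-group variance is large relative to
`sigma = 1`, the same adjuster restores scores nearly completely.

`control_gene_probabilities()` implements the companion heuristic for
control-gene selection: `pc = 1 - rank(sd) / max(rank(sd))` with ascending
ranks and average ties, so stable genes receive probabilities near 1. The
rank direction is a documented choice: the motivation — control genes should
have stable expression — forces stable genes to the high end, which pins the
ranks as ascending in the gene's standard deviation.

## The synthetic generator

`make_toy_ontology()` builds a complete branching tree;
`simulate_expression()` diffuses group mean profiles down it by Brownian
drift (root profile i.i.d. standard normal; each child adds `N(0, tau^2)`
per gene; each sample adds `N(0, epsilon^2)` around its leaf's profile).
Brownian drift on a tree is the simplest generative model under which
expected expression distance grows monotonically with ontology path
distance — precisely the assumption the ontology score tests — so a high
score on this generator is a correctness check of the machinery, not a
claim about any particular dataset. Non-negativity is obtained by a global
shift rather than truncation, keeping the drift covariance exact.

Defaults used throughout the tests and the acceptance script: depth-3
binary tree (8 leaf groups), 15 samples per group (120 samples), 500 genes,
`tau = 1`, `epsilon = 0.1`. The drift-to-noise ratio of 10 produces
well-separated groups — the regime of sorted tissue panels — at sizes where
the whole benchmark runs in seconds on one CPU. Under these conditions the
true-ontology median score exceeds 0.9, the randomized null centers on
zero, and the fixed 1.0/0.25 matrix sits in between.

What the generator does **not** emulate: count noise (negative binomial),
library-size variation, gene-gene correlation beyond the tree structure,
dropout, or imperfect sample-to-term curation. Passing tests therefore show
that the pipeline measures what it claims on data satisfying its core
assumption; they do not certify performance on data violating it.

## Numerical choices and degenerate inputs

* PCA component signs are fixed (largest-magnitude loading positive) so
  results are bit-reproducible across runs and platforms.
* Spearman over 4 PC coordinates admits few distinct rank configurations;
  it is deliberately coarse and robust. Pearson is available where finer
  resolution is wanted.
* Ties always use average ranks; `O` columns contain many ties by
  construction (blocks of equal term-pair similarity).
* A score column that is constant (e.g. all samples mapped to one term) has
  no ranking information: the score is `NA`, never 0.
* Correlations are computed on pairwise-complete entries; a score based on
  fewer than 3 pairs is `NA`.
* `include_self = TRUE` (full columns, the literal reading of the score
  definition) is the default; the self pair contributes one tied maximum to
  both columns, and a flag drops it. The two modes differ by at most the
  effect of that one tied rank.
* Obsolete ontology terms are excluded by default, and mapping a sample to
  one is an error rather than a silent drop — manual term curation is
  error-prone and mistakes should surface.
* TSV outputs format floats with 10 significant digits; identical
  configuration and seed give byte-identical files.

## Limitations

The score is relative, not absolute: there is no threshold above which data
are "good". It is meaningful for comparisons — original vs adjusted, one
adjuster vs another, one batch vs another. Its quality is bounded by the
ontology's fidelity and by the correctness of the sample-to-term mapping.
The expected matrix treats every sample of a type identically, so
within-type heterogeneity (e.g. mixed-cell-type tissue samples) is invisible
to `O` and lowers scores even for clean data.
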
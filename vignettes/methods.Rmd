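---
title: "Methods: coverage-based cfDNA screening with a convolutional attention classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based cfDNA screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cfcnv)
```

# Scope and data model

`cfcnv` classifies samples as case or control from low-pass (~0.2×)
cell-free DNA sequencing coverage, and reports which genomic regions drive
the classification. The pipeline assumes alignment, deduplication and depth
computation have already happened upstream; its inputs are per-sample depth
records (bedGraph), chromosome sizes, optional exclusion regions and
per-window GC/mappability tracks, and 0/1 sample labels.

The generative picture behind every stage: for sample $s$ and window $w$,

$$E[c_{sw}] = d_s \cdot L_w \cdot f(\mathrm{GC}_w) \cdot m_w \cdot
\frac{\mathrm{CN}_{sw}}{2},$$

where $d_s$ is the sample's mean depth, $L_w$ the window length, $f$ a
smooth GC-bias curve, $m_w$ mappability, and $\mathrm{CN}_{sw}$ the copy
number (2 = diploid). Each stage removes one nuisance factor: loess
correction divides out $\hat f$ and $\hat m$; row normalization divides out
$d_s L_w$ (windows share one length up to the terminal partial window).
What reaches the classifier is a noisy estimate of $\mathrm{CN}_{sw}/2$.

Coordinates are 0-based half-open (BED convention) throughout; the upstream
literature never states a convention, and BED interoperability decides it.

# Windows

Windows tile each chromosome contiguously; the terminal window is kept even
when shorter than `window_size` (ceiling convention — each chromosome
contributes $\lceil L/\text{size} \rceil$ windows). A window is masked when
the union of exclusion intervals covers at least `min_overlap_fraction`
(default 0.5) of it; no overlap rule is stated upstream for
segmental-duplication removal, so half-coverage is the package's default
and is configurable. `min_overlap_fraction = 0` masks on any 1-bp touch and
`1` only on full containment. Track values (GC, mappability) are
length-weighted means over covered bases only; the covered fraction is
recorded, and windows without track coverage are `NA` and excluded from
bias fitting.

# Coverage counting and sample QC

`count_coverage()` sums depth × overlap bp into each unmasked window. Mean
depth is defined as total aligned bases divided by the total *unmasked*
genome length, so masking does not deflate a sample's apparent depth. QC is
strict-at-the-boundary exactly as the thresholds are worded: a sample fails
with mean depth *lower than* 0.15× or *fewer than* 6 million unique reads;
equality passes.

# Bias correction

Two-stage, in the style of readcount correctors for binned low-pass data:

1. loess (span 0.3, degree 2, symmetric family) of raw window counts
   against GC, fitted on a trimmed eligible set, then divided out;
2. loess of the GC-corrected values against mappability, divided out.

Fitting-eligible windows have both tracks defined, mappability ≥ 0.9 and
value inside the [0.1%, 99.9%] quantiles; ineligible windows are still
*corrected* by the fitted trends (linear interpolation on a 512-point grid,
flat extrapolation, floor at 0.1% of the mean to avoid division blow-ups).
The output is rescaled to preserve the profile mean. Fewer than 50 eligible
windows refuses correction outright rather than fitting garbage. A constant
covariate short-circuits to an identity correction. Correction operates on
binned counts — the only order consistent with a binned-count corrector —
and precedes QC filtering, assembly and normalization.

# Normalization, pruning, imputation

Row normalization divides each sample by its mean, giving every row mean
exactly 1; it is idempotent and invariant to per-row rescaling. Pruning
drops a window when either rule fires, all inequalities strict as worded:

* dropout rule: *over* 80% of samples *lower than* 0.1 normalized coverage;
* mean-difference rule: |control mean − case mean| *less than* 0.01.

The dropout rule is checked first for reason attribution only; the retained
set is identical under either precedence. The "80% of samples" fraction is
evaluated over all samples (the sentence's plain reading), not per group.

Dropout entries (normalized coverage below ε = 0.01; exact zeros always)
are treated as missing and replaced from a rank-`r` factorization $UV^\top$
fitted by Adam-accelerated gradient descent to the observed entries with an
L2 penalty λ on the factors (defaults r = 10, λ = 0.1, 500 epochs, seeded
init). Observed entries are never altered — completion, not smoothing. This
is an in-repo, transparent stand-in for the external single-matrix
imputation tool used upstream, whose parameterization there is not
documented; replacing it keeps the stage testable (exact rank-1 recovery,
rank-3 RMSE bounds, determinism) without an external codebase.

# The classifier

Input ($N$ windows, 1 channel) → conv1D (32 filters, kernel 8, ReLU) →
max-pool 4 → conv1D (64 filters, kernel 8, ReLU) → max-pool 4 → additive
position-wise self-attention → dense 64 (ReLU, dropout 0.4) → dense 16
(ReLU, dropout 0.4) → 1-unit sigmoid. Convolutions are valid (no padding);
pooling is non-overlapping with remainders dropped. The exact layer widths
are this package's defaults (the upstream supplementary table is
unavailable); all are exposed to `grid_search()`, which evaluates the full
cartesian grid by validation AUC with ties broken by parameter count.

Attention is additive scoring: $e_t = v^\top \tanh(W h_t + b)$ over pooled
positions $t$, $\alpha = \mathrm{softmax}(e / \tau)$, context
$c = \sum_t \alpha_t h_t$ fed to the dense head. Two deliberate choices:

* **Temperature $\tau = 0.1$.** With plain softmax ($\tau = 1$) the trained
  model classifies through a diffuse artifact: row-mean normalization
  depresses *every* background window of a high-CNV-burden sample by a few
  percent, and near-uniform attention averages that genome-wide signature
  — with the learned weights then *anti*-correlated with the true CNV
  segments. Sharpening the softmax removes the diffuse-averaging solution:
  the context must be assembled from few positions, and the only positions
  worth attending to are the discriminative ones. At the synthetic
  acceptance geometry this moves recovery from fold enrichment ~0 to ~10
  with test AUC 1.0; $\tau = 0.05$ starts to hurt optimization. The value
  is an architecture constant, fixed once, not tuned per dataset.
* **Window attribution.** The per-sample $\alpha$ is averaged over a
  reference set (default: the training data, after training — "during
  training" is ambiguous upstream and a post-hoc average is reproducible),
  and each pooled position's weight is spread uniformly over the input
  windows in its receptive field, then renormalized to sum to 1. A single
  pooled position degenerates to uniform weights by construction.

Training: Adam on binary cross-entropy, fixed epoch count, no early
stopping, dropout active only in training; the validation set is monitored
only. Inputs are centered per window by training-set means (stored on the
model). One master seed derives the initialization, shuffle and dropout
streams, so runs are bit-reproducible. The published protocol (learning
rate 1e-5, batch 512, 100 epochs) is the package default; it is calibrated
to a ~4500-sample cohort, where an epoch is ~9 Adam steps. On a 400-sample
desk-scale cohort it makes one step per epoch and cannot move the weights
measurably, so the tests and examples use lr 5e-3, batch 32–64, 30–40
epochs — reduced-epoch settings chosen once for that scale.

Prediction threshold semantics are strict: class 1 iff probability is
*above* 0.5; exactly 0.5 is class 0.

Dataset splitting is largest-remainder apportionment of the 75/5/20
fractions (ties broken train > validation > test) with seeded membership;
it reproduces the printed cohort partition 3353/223/894 at n = 4470
exactly, which is the basis of acceptance targets t1–t3.

# Evaluation

Confusion matrix at the strict threshold; accuracy, precision, recall, F1
with undefined denominators reported as `NA`, never 0. The ROC sweeps
unique score thresholds; AUC is the trapezoid integral and equals the
Mann–Whitney pair statistic with half credit for ties (property-tested
against an explicit pair-counting oracle). The prediction–label correlation
is the product-moment coefficient with a two-sided t-test (n − 2 df).
Bootstrap uncertainty resamples (label, prediction) pairs to the original n
(10 000 reps by default); single-class resamples are redrawn and counted;
the interval is the percentile 2.5/97.5 band — the percentile form matches
the interval style reported upstream. Cross-validation is stratified by
label (class-imbalance stability; stratification is not stated upstream)
with a rotation-offset deal so fold sizes differ by at most one both
overall and per class, and reports the fold-accuracy standard deviation.

# Regions, genes, enrichment

Windows are ranked by attention weight (stable sort, genome-order
tie-break) and the top 5000 exported as BED. A gene is annotated when it
overlaps any selected window by ≥ 1 bp in half-open coordinates (abutting
intervals do not overlap); genes are deduplicated in first-overlap rank
order. Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ with universe N, set size K and selection n, after
intersecting both the selection and each set with the universe, with
Benjamini–Hochberg adjustment across sets and significance at adjusted
p < 0.05. Real GO/KEGG retrieval is out of scope; any GMT file works, and
the default universe is all genes overlapping analyzable windows.

# The simulator, and what a green test establishes

`simulate_cohort()` draws per-window GC ~ Beta(5, 5), mappability
concentrated near 1 (range (0.5, 1] by default), per-sample depth ~
Uniform(0.15×, 0.25×) — the low-pass screening regime — and expected counts
from the generative model above, with a quadratic GC-bias curve centered at
GC 0.45 (amplitude = `gc_bias_strength`, invertible by the correction
stage). Case samples carry `n_signal_segments` implanted segments
(`effect_size` multiplicative, expressed per segment with probability
`penetrance`). Noise is Poisson, negative binomial (`dispersion` = size),
or `"none"` for exact expectations; entries are zeroed with probability
`dropout_rate`. Case counts are deterministic (`round(n × fraction)`) for
stable tests. Everything is reproducible from one seed.

The end-to-end acceptance world is 400 samples × 2000 windows (10 Mb toy
genome at 5 kb), 5 segments × 20 windows (5% signal), effect 1.5,
penetrance 0.8, 5% dropout, and **negative-binomial noise with size 50**
(~15% CV at the simulated depth). The noise law is not dictated by the
acceptance statement, and is fixed once on realism grounds: real low-pass
cfDNA window counts are overdispersed well beyond Poisson (residual GC
structure, fragmentation, library effects). Poisson at window-count means
of ~1000 would make group-mean differences of null windows almost surely
below the 0.01 pruning threshold — pruning would then delete essentially
every null window, contradicting the stated "~2000 windows, 5% signal"
geometry and emptying the negative-control matrix entirely.

Recovery scoring: `precision@k` over the ranked windows and fold
enrichment against the truth density `|truth| / n_universe`. `n_universe`
is the *full* simulated window set, not the post-pruning subset: pruning
removes predominantly null windows, so the truth density inside the
retained set is inflated by design and a fold-enrichment bound against it
would be unreachable arithmetic, not a property of the method.

What the green tests establish: the pipeline's stages compose correctly,
the optimizer can exploit genuine multiplicative CNV signal at realistic
noise (AUC ≥ 0.9), it finds nothing in its absence (AUC ≈ 0.5), and the
attention attribution concentrates on implanted segments. What they do not
establish: performance on real cohorts — the simulator has no fragmentomic
structure, no batch or flow-cell effects, no population stratification, no
maternal-condition confounding, a toy genome three orders of magnitude
smaller than hg38, and segments placed on a regular grid. The published
cohort-scale headline metrics are not reproducible from a desk-scale
simulation and are deliberately outside the acceptance surface.

# Numerical and interface choices

* Pipeline configs are JSON (`jsonlite`), not YAML: no YAML parser is
  available in the supported dependency set. One `seed` field derives all
  stage seeds.
* Run manifests digest inputs/outputs with `tools::md5sum`; deterministic
  stages reproduce identical digests under an identical config.
* Ties in ranking break by genome order; ties in grid search by parameter
  count; apportionment ties by train > val > test.
* Loess trends are floored at 0.1% of the profile mean before division;
  degenerate (constant-covariate) fits short-circuit to the identity.
* The imputation loss (observed squared error + λ‖U‖² + λ‖V‖²) is checked
  for non-convergence over the final 20% of epochs and warns with
  diagnostics rather than failing.
* All-zero rows (normalization), single-class cohorts (pruning, training),
  empty truth sets and empty universes are hard errors naming the
  offending object.

# Known limitations

* The attention attribution is faithful to the model, not to biology:
  correlated neighbors of a true segment inside one receptive field share
  its weight (uniform spreading), bounding localization resolution by the
  receptive-field width (~50 windows at the default geometry).
* The low-rank imputer assumes dropout entries are missing at random given
  the factor structure; systematic dropout (e.g. mappability-linked) is
  partially absorbed by the factors but not modelled.
* `grid_search()` trains one model per grid point sequentially; at
  cohort-scale inputs this is compute-bound and the grid should be small.
* The from-scratch network is CPU-only and single-threaded beyond BLAS;
  at the published 10 kb genome-wide scale (~150k raw, ~11k pruned
  windows) training is feasible but slow compared to a GPU framework.
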
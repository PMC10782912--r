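# cfcnv

Copy-number screening of low-coverage cell-free DNA (cfDNA) with a
convolutional attention classifier.

## The problem

Plasma cfDNA sequenced at very low coverage (~0.2×) is routinely produced by
non-invasive prenatal and screening assays. At that depth individual
genotypes are unreadable, but the genome-wide *coverage pattern* still
carries copy-number information: gains and losses shift the expected read
depth of the affected region multiplicatively. `cfcnv` implements a complete
screening pipeline that turns per-sample depth tracks into a cohort feature
matrix and learns a binary case/control classifier from it, for example to
flag a pregnancy complication from an early-gestation blood draw:

1. **Windows** — tile the genome into non-overlapping windows (5–50 kb),
   mask unreliable regions (e.g. segmental duplications), attach GC and
   mappability tracks.
2. **Coverage matrix** — sum base coverage per window per sample, apply
   sample QC (mean depth ≥ 0.15×, ≥ 6M unique reads), remove GC and
   mappability bias by two-stage loess correction, assemble the
   samples × windows matrix, normalize each row by its mean.
3. **Pruning and imputation** — drop windows that are dropout-dominated
   (> 80% of samples below 0.1 normalized coverage) or uninformative
   (case/control mean difference < 0.01); impute dropout entries with a
   regularized low-rank factorization.
4. **Classifier** — a 1D CNN (two conv/max-pool blocks) with a
   position-wise self-attention layer, two dense layers with dropout 0.4
   and a sigmoid output, trained with Adam on binary cross-entropy.
5. **Discovery** — the attention layer yields a 1 × N weight vector over
   windows; the top-5000 windows are exported, annotated with overlapping
   genes, and tested for gene-set over-representation (hypergeometric test,
   Benjamini–Hochberg correction).
6. **Simulator** — a synthetic-cohort generator with GC bias, mappability
   attenuation, Poisson/negative-binomial noise, dropout and implanted CNV
   segments, with ground truth for recovery scoring. Every stage of the
   pipeline is testable without any external data.

## The statistic at the core

For sample *s* and window *w* the expected coverage is modelled as

    E[c_sw] = d_s · L_w · f(GC_w) · m_w · (CN_sw / 2)

with sample depth `d_s`, window length `L_w`, GC bias `f`, mappability
`m_w` and copy number `CN_sw` (2 = diploid). Bias correction divides out
loess estimates of `f` and `m`; row normalization removes `d_s`. What is
left is a noisy per-window estimate of `CN_sw / 2` that the CNN consumes.
Classification quality is summarized by the confusion matrix at the strict
0.5 threshold, precision/recall/F1, the ROC curve with trapezoid AUC
(equal to the Mann–Whitney pair statistic), bootstrap AUC intervals and
prediction–label correlation.

## Worked example

A fully synthetic 120-sample cohort with three implanted gain segments
(effect 1.5, penetrance 0.9):

```r
library(cfcnv)
cfg <- sim_config(n_samples = 120, chrom_lengths = c(chrA = 2e6),
                  window_size = 5000, n_signal_segments = 3,
                  segment_length_windows = 15, effect_size = 1.5,
                  penetrance = 0.9, noise = "negbin", dispersion = 50,
                  seed = 7)
cohort <- simulate_cohort(cfg)
#> synthetic_cohort: 120 samples (60 cases) x 400 windows; 45 signal windows (effect 1.5)

cm <- normalize_rows(cohort_matrix(cohort))
pruned <- prune_windows(cm)
#> pruning_report: 400 -> 355 windows (mean_diff_rule: 45)
cm <- impute_lowrank(pruned$matrix, flag_missing(pruned$matrix), seed = 2)

sp <- split_dataset(nrow(cm$values), seed = 3)
#> split_spec: n=120 -> train 90, val 6, test 24
mcfg <- model_config(conv1_filters = 16, conv2_filters = 32,
                     attention_dim = 32, dense1_units = 32, dense2_units = 8,
                     learning_rate = 5e-3, batch_size = 32, epochs = 40,
                     seed = 4)
mdl <- train_model(build_model(mcfg, ncol(cm$values)),
                   cm$values[sp$train, ], cm$labels[sp$train])

p_test <- predict(mdl, cm$values[sp$test, ])
evaluate_predictions(cm$labels[sp$test], p_test)
#> eval_report (n=24): acc 1.0000, precision 1.0000, recall 1.0000,
#>   F1 1.0000, AUC 1.0000, r 1.000 (p=1.04e-38)
bootstrap_auc(cm$labels[sp$test], p_test, n_reps = 2000, seed = 5)
#> bootstrap_result: mean AUC 1.0000, 95% CI [1.0000, 1.0000] (2000 reps)
```

On this small, strongly separable cohort the held-out test set is
classified perfectly. The attention weights recover the implanted
segments:

```r
w <- attention_weights(mdl, cm$values[sp$train, ])
full_w <- numeric(nrow(cohort$ws$windows))
full_w[match(cm$window_indices, cohort$ws$windows$index)] <- w
rr <- rank_windows(full_w, cohort$ws, top_k = 90)
truth_recovery(rr, cohort$truth, k = 90,
               n_universe = nrow(cohort$ws$windows))
#> precision@90 = 0.422, fold enrichment = 3.75
```

42% of the 90 top-ranked windows are true signal windows versus an 11%
genome-wide truth density — a 3.8-fold enrichment.

A one-shot orchestration of all stages (JSON config, run manifest with
file digests) is available as `run_pipeline("config.json")`, and a thin
CLI lives at `inst/cli/cfcnv.R` (`make-windows`, `simulate`, `impute`,
`evaluate`, `run`, ...).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the generative
model behind the simulator, every tunable parameter with its default and
rationale, the numerical choices (strict thresholds, tie-breaks, loess
settings, attention temperature) and the limitations of synthetic
validation.
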
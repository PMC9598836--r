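# multipen

Multi-omics ensemble networks for survival prognosis estimation.

`multipen` fits a prognosis score for uncensored survival cohorts — the
motivating application is low-grade glioma — from three data blocks:
mRNA expression, miRNA expression and clinical covariates. The model
combines

* **gene-attention layers** (squeeze-and-excitation bottlenecks), one
  per datatype: `a = σ(W₂ · ReLU(W₁x)), x̃ = a ⊙ x`, producing a
  per-gene multiplicative gate in (0, 1) that doubles as a feature
  importance score;
* an **ensemble of residual sub-models** over the fused attended vector
  (two residual blocks with layer normalization before each activation,
  dropout, widths 16/8, learned skip projections where the dimension
  changes) with a tanh output head, ensemble score = arithmetic mean;
* a **pairwise hinge ranking loss** on survival times (a concordance
  surrogate), optimized with Adam;
* **repeated K-fold cross-validation** with strictly leakage-free
  preprocessing (gene filters, log normalization, one-hot clinical
  encoding — all fitted on each training partition only) evaluated by
  the concordance index (C-index);
* **attention-based ranking** of candidate prognostic mRNAs and miRNAs,
  with a permutation test for gene-set enrichment.

A synthetic cohort generator with planted prognostic structure
(negatively coupled miRNA→mRNA pairs, log-linear hazards) makes the
whole pipeline testable end to end without any data download.

## Worked example

Simulate a 125-sample cohort with 40 planted prognostic mRNAs (of 500)
and 20 planted miRNAs (of 100), preprocess, fit, and rank genes:

```r
library(multipen)

co <- generate_cohort(cohort_spec(
  n_samples = 125, p_mrna = 500, p_mirna = 100,
  n_prognostic_mrna = 40, n_prognostic_mirna = 20,
  beta = 10, rho = 0.75, sd_noise = 0.2, zero_rate = 0, seed = 11))

prep <- fit_preprocessor(co$mrna, co$mirna, co$clinical, standardize = TRUE)
dat  <- predict(prep, co$mrna, co$mirna, co$clinical)

cfg <- multipen_config(n_submodels = 5, epochs = 60,
                       learning_rate = 0.01, dropout = 0.2, seed = 1)
fit <- multipen(dat$mrna, dat$mirna, dat$clinical,
                time = co$survival$time, config = cfg)
fit
#> Multi-omics prognosis estimation network
#> Features: 500 mRNA + 100 miRNA + 23 clinical (fused 623)
#> Ensemble of 5 sub-models; trained on 125 samples, final loss 0.0264

scores <- predict(fit, dat$mrna, dat$mirna, dat$clinical)
concordance_index(scores, co$survival$time)
#> [1] 0.983        # in-sample; held-out performance comes from run_experiment()

head(rank_genes(compute_gene_attention(fit, dat)$mrna, 5))
#>   feature_id mean_attention rank
#> 1   MRNA0013      0.9471575    1
#> 2   MRNA0070      0.9453405    2
#> 3   MRNA0369      0.9340203    3
#> 4   MRNA0023      0.9299240    4
#> 5   MRNA0112      0.9266384    5
```

The final training loss is the mean pairwise hinge over comparable
sample pairs (0 = every pair ranked correctly by more than the margin);
the C-index is the fraction of sample pairs whose score ordering matches
their survival ordering (0.5 random, 1.0 perfect). Honest generalization
estimates use the repeated-CV protocol, which refits preprocessing and
model inside every split:

```r
res <- run_experiment(co$mrna, co$mirna, co$clinical, co$survival,
                      config = cfg, k = 5, repeats = 20, seed = 1,
                      standardize = TRUE)
res
#> Repeated cross-validation: 5 folds x 20 repeats = 100 experiments
#> C-index: mean 0.9470, sd 0.0200 (seed 1)
```

`run_experiment(predict_fun = ...)` evaluates any external learner
(e.g. a Cox or ridge model) under the identical split and preprocessing
protocol.

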
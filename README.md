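# batchdissect

Missing-value-tolerant batch effect correction for integrated omics
matrices, by matrix dissection.

## The problem

Integrating several measurement runs — TMT proteomics plexes, sequencing
runs, metabolomics batches — increases cohort size and statistical power,
but introduces *batch effects*: systematic non-biological location and
scale differences between runs. The standard correctors assume a complete
feature × sample matrix, yet integrated omics data is riddled with missing
values (a feature quantified in one plex is often absent from another, and
low-intensity values drop out preferentially). `batchdissect` makes
location/scale batch correction applicable to arbitrarily incomplete
matrices:

* Each feature's **combination** is the set of batches holding at least
  two numerical values for it (the minimum for a per-batch location and
  scale estimate). Features sharing a combination form a **sub-matrix**,
  restricted to those batches' columns; each sub-matrix is adjusted
  independently — with a missing-value-aware parametric empirical-Bayes
  location/scale kernel (ComBat model: standardize, estimate per-batch
  per-feature effects γ̂, δ̂, shrink towards cross-feature priors, remove)
  or a linear-model kernel (OLS with sum-to-zero batch contrasts,
  `removeBatchEffect` semantics) — and the matrix is rebuilt in the input
  order. At most `min(F, 2^n − n − 1)` sub-matrices can arise from `F`
  features in `n` batches.
* **Blocking** (`block = b`) treats groups of neighbouring batches as
  single units *during dissection only*, collapsing the exponential
  combination space (4083 → 57 multi-unit combinations for 12 batches at
  `b = 2`); adjustment still uses true batch labels. Optional **sorting**
  (sparsity, Jaccard, seriation) reorders batches before blocking to
  reduce the data loss blocking incurs.
* **Unique removal** (`ur`) rescues features whose combination is
  one-of-a-kind — otherwise stranded in unadjustable single-feature
  sub-matrices — by cropping as few batches as possible until the
  combination matches a group of other features.

A quality-control battery (missing-value-tolerant Euclidean distances,
silhouette widths by batch and by biology, leave-one-out kNN
misclassification, per-feature coefficients of variation) and a synthetic
multi-batch generator with MNAR censoring and known ground truth round out
the package.

## Worked example

```r
library(batchdissect)

d <- generate_dataset(sim_config(seed = 1))   # 10 batches x 10 samples, 2000
                                              # features, 25% MNAR missing
res <- harmonize(d$matrix, d$design, algorithm = "combat")
print(res$report)
#> batch adjustment report
#>   algorithm: combat, unique removal on
#>   batches: 10 | dissection units: 10
#>   features considered: 2000 / 2000
#>   sub-matrices: before unique removal 38 | after 30 | adjusted 30
#>   rescued unique features: 8 | unresolved: 0
```

The missingness pattern dissects the 2000 features into 38 candidate
sub-matrices; 8 features had unique combinations and were cropped onto
anchor groups (one sub-matrix fewer per rescue), leaving 30 sub-matrices
and no feature lost.

```r
silhouette_scores(tolerant_euclidean(d$matrix),   d$design$batch)$asw  # 0.220
silhouette_scores(tolerant_euclidean(res$matrix), d$design$batch)$asw  # -0.076

common <- intersect(rownames(d$matrix), rownames(res$matrix))
median(feature_cv(d$matrix[common, ]),   na.rm = TRUE)   # 0.147
median(feature_cv(res$matrix[common, ]), na.rm = TRUE)   # 0.017
```

Before adjustment, samples cluster by batch (batch-label average
silhouette width 0.22); afterwards that structure is gone (−0.08, i.e.
batches are intermixed), and the median per-feature coefficient of
variation drops from 0.147 to 0.017 because the artificial between-batch
variance has been removed.

From the shell:

```sh
Rscript inst/scripts/batchdissect.R \
  --data matrix.tsv --description design.csv --output adjusted.tsv \
  --algorithm ComBat --block 2 --sort jaccard --report report.txt
```

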
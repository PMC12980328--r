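# cccr — the Clustermatch Correlation Coefficient in R

Gene co-expression analysis usually starts from Pearson's *r* (linear) or
Spearman's *ρ* (monotonic). Both miss association shapes that are common and
biologically meaningful in transcriptomic data: a symmetric quadratic, a
relationship present only in one sex, or two donor cohorts whose
within-cohort trends run opposite to the pooled trend. `cccr` implements the
**Clustermatch Correlation Coefficient (CCC)**, a clustering-based statistic
that detects such patterns for numerical *and* categorical features, plus
the machinery to run it at pair-census scale and to mine the results for
nonlinear candidates. It is aimed at anyone correlating expression matrices
(bulk or single-cell pseudobulk) with each other or with sample metadata.

## The statistic

Each feature is internally clustered: a numerical feature by empirical
quantile cuts at every cluster count k in a sweep (default 2..10, type-7
quantiles), a categorical feature by its categories. For features x and y,

```
CCC(x, y) = max(0, max over all partition pairs of ARI(π_x, π_y))  ∈ [0, 1]
```

where ARI is the Hubert–Arabie Adjusted Rand Index computed from the
contingency table n_ij with marginals a_i, b_j:

```
ARI = (Σ_ij C(n_ij,2) − E) / (½[Σ_i C(a_i,2) + Σ_j C(b_j,2)] − E),
E   = Σ_i C(a_i,2) · Σ_j C(b_j,2) / C(n,2)
```

CCC is 1 for any monotone relationship, ~0 for independence, exactly
invariant under increasing transforms, and symmetric. Every
(partition × partition) combination is one task in a globally-indexed,
memory-budgeted batch engine with a compiled kernel, so a full 500-gene ×
200-sample pairwise run (124,750 pairs, ~10 million ARI tasks) takes ~20 s
on one CPU. Permutation p-values (add-one estimator, per-pair seeded
streams) are available for any pair.

## Worked example

```r
library(cccr)

## a symmetric quadratic: invisible to Pearson/Spearman, not to CCC
x <- seq(-1, 1, length.out = 200)
y <- x^2
ccc_pair(x, y, ccc_config(n_perm = 99, seed = 1))
#>   feature_i feature_j       ccc best_kx best_ky pvalue n_used degenerate
#> 1         x         y 0.6043738      10       5   0.01    200      FALSE
cor(x, y)                      #> 3.4e-17
cor(x, y, method = "spearman") #> 0.0015
```

CCC finds the quadratic at 0.60 (best partition pair: 10 clusters on x, 5 on
y; permutation p = 0.01, the smallest possible with 99 permutations), while
both linear coefficients are indistinguishable from zero.

```r
## a synthetic suite of motifs, pairwise CCC + Pearson baseline
ds  <- generate_dataset(seed = 1)          # 12 features x 200 samples
res <- ccc_matrix(ds$expression, ccc_config(n_perm = 0))
res$pearson <- baseline_coefficients(ds$expression, "pearson")$value
head(res[order(-res$ccc), ], 6)
#>             feature_i          feature_j   ccc best_kx best_ky pearson
#> 52  group_masked_p1_x  group_masked_p1_y 0.960       2       2 -0.6389
#> 1         linear_p1_x        linear_p1_y 0.921       2       2  0.9888
#> 39  cohort_shift_p1_x  cohort_shift_p1_y 0.883       2       2 -0.4916
#> 22     quadratic_p1_x     quadratic_p1_y 0.337       4       2  0.0526
#> 61 subset_masked_p1_x subset_masked_p1_y 0.206       3       3  0.5247
#> 36     quadratic_p1_y subset_masked_p1_y 0.031       5       2  0.1890
```

The engineered motif pairs top the ranking; for the group-masked and
cohort-shift pairs Pearson is negative — the "wrong" pattern — while CCC
reports the strong association. Metadata association then explains the
group-masked pair:

```r
metadata_associations(
  data.frame(feature_i = "group_masked_p1_x", feature_j = "group_masked_p1_y"),
  ds$expression, ds$metadata)
#>                gene variable        kind    ccc pvalue n_used
#> 1 group_masked_p1_x    group categorical 1.0000     NA    200
#> 2 group_masked_p1_y    group categorical 0.9602     NA    200
#> 3 group_masked_p1_y      age   numerical 0.0113     NA    200
```

The masked gene is *fully* explained by the group label (ccc = 1).

## Command line

The same pipeline is scriptable via `inst/cli/ccc` (or
`Rscript -e 'cccr::ccc_cli()' --args ...`):

```sh
ccc simulate  --pattern suite --n-samples 200 --seed 1 --out-prefix demo
ccc compute   --input demo_expression.tsv --output results.tsv \
              --methods ccc,pearson,spearman
ccc intersect --results results.tsv --q-high 0.30 --q-low 0.30 \
              --output categories.tsv --pairs-out tiers.tsv
ccc select    --results results.tsv --categories tiers.tsv --top-n 100 \
              --output candidates.tsv
ccc metadata  --expr demo_expression.tsv --meta demo_metadata.tsv \
              --pairs candidates.tsv --output gene_meta.tsv
```

All files are plain TSV (`.gz` supported) with `#`-prefixed provenance
headers.

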
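---
title: "The Clustermatch Correlation Coefficient: model, engine, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Clustermatch Correlation Coefficient: model, engine, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The statistic

Pearson's r captures linear association and Spearman's rho monotonic
association; neither sees a symmetric quadratic, a relationship confined to
one group of samples, or two sample cohorts whose within-cohort trends point
the opposite way from the pooled trend. The Clustermatch Correlation
Coefficient (CCC) targets exactly these cases, for numerical and categorical
features alike, by asking a different question: *is there any coarse
clustering of the samples under which the two features sort the samples the
same way?*

Each feature is clustered on its own ("internal clustering"):

* a **numerical** feature is cut at its empirical quantiles $i/k$ for every
  cluster count $k$ in a sweep (default $k = 2,\dots,10$), giving up to
  $|k\text{-range}|$ partitions of the samples;
* a **categorical** feature contributes the single partition defined by its
  categories.

For two features $x$ and $y$ with partition families $\{\pi_x\}$ and
$\{\pi_y\}$, the coefficient is the clamped maximum Adjusted Rand Index over
all partition combinations:

$$\mathrm{CCC}(x, y) \;=\; \max\!\Big(0,\; \max_{\pi_x,\,\pi_y}
  \mathrm{ARI}(\pi_x, \pi_y)\Big) \;\in\; [0, 1].$$

The ARI is the Hubert–Arabie chance-corrected pair-counting agreement,
computed from the contingency table $n_{ij}$ of joint cluster memberships
with marginals $a_i$, $b_j$:

$$\mathrm{ARI} = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}
  {\tfrac12\big[\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}\big] - E},
  \qquad E = \frac{\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}}{\binom{n}{2}}.$$

It equals 1 for identical partitions and has expectation 0 for independent
ones. Because quantile partitions depend only on ranks, CCC is exactly
invariant under strictly increasing transforms of either feature, and
`ccc(x, x) = 1` for any non-constant feature.

## Partitioning conventions

Several small conventions make results bit-reproducible and are fixed once:

* **Quantile estimator.** Cut points are linear interpolations of the order
  statistics with plotting positions $(j-1)/(n-1)$ — the ubiquitous "type-7"
  rule, `stats::quantile(type = 7)`. Any interpolating estimator preserves
  rank-invariance; type 7 is the most widely implemented.
* **Boundary rule.** A value exactly equal to a cut point joins the *lower*
  cluster: a sample's label is the number of cut points strictly below its
  value. Ties in the data therefore always receive equal labels.
* **Compaction.** Empty clusters are removed and labels renumbered
  $0,\dots,k-1$; a partition with fewer than 2 non-empty clusters is
  *degenerate* and dropped from the feature's family. Duplicate partitions
  arising at different requested $k$ are retained — the max-reduction is
  unaffected, and dropping them would complicate the task indexing for no
  numerical gain.
* **Categorical order.** Categories are coded in first-occurrence order, so
  results do not depend on locale collation.
* **Degenerate pairs.** A constant feature (empty partition family), or a
  pair with fewer than `min_samples` (default 10) pairwise-complete samples,
  yields `ccc = 0` with a `degenerate` flag rather than an error or `NA`:
  a pairwise matrix stays rectangular and the flag preserves the distinction.
  Missing values are handled by pairwise-complete restriction; the floor
  prevents partitions of meaninglessly few samples.

## The batched ARI engine

At transcriptome scale the dominant cost is the sheer number of ARI
evaluations: $m$ features with up to 9 partitions each imply up to
$81 \cdot m(m-1)/2$ contingency tables. The engine treats every
(partition of $x$) × (partition of $y$) combination across all requested
pairs as one *task* with a unique global index
($\text{offset(pair)} + p_x \cdot m_y + p_y$), splits the task stream into
contiguous batches sized by a working-memory budget
(`max(1, floor(budget_bytes / per_task_bytes))` tasks per batch, default
budget 4 GiB), evaluates each batch with working buffers reused across
batches, and max-reduces per pair, breaking ties by the lowest global index.

Two backends satisfy one contract: a compiled kernel (`vectorized`, the
default) and a pure-R loop (`reference`) kept as an independently auditable
implementation. Because every intermediate quantity in the ARI formula is a
small integer exactly representable in double precision, the two backends —
and any worker count or batch budget — produce bit-identical results; the
test suite asserts this, and additionally checks the closed form against a
brute-force pair-counting oracle over all 122 set partitions of 6 samples
into at most 3 blocks (14,884 ordered pairs). The engine returns the *raw*
maximum ARI (possibly negative); clamping at 0 is the coefficient layer's
job, which keeps the engine testable against the oracle on anti-correlated
partitions.

## Permutation p-values

With `n_perm > 0`, each pair's null is generated by uniformly random
permutations of the second feature's values with the first held fixed (an
exchangeability null, symmetric in distribution), and the p-value uses the
add-one estimator $p = (1 + \#\{\mathrm{CCC}_{perm} \ge
\mathrm{CCC}_{obs}\})/(1 + n_{perm})$, which never returns 0 and is the
standard Monte-Carlo form. The permutation stream of pair $i$ is seeded by a
fixed integer hash of `(seed, i)` — `(seed * 69621 + i * 10007 + 1) mod
(2^31 - 1)` — so p-values are reproducible and independent of batching or
parallelism, and the machinery runs on a private RNG stream that leaves the
caller's `.Random.seed` untouched. The default `n_perm = 1000` balances
resolution ($p \ge 1/1001$) against cost; the command-line `compute`
subcommand leaves p-values off unless `--pvalues` is given, since a full
pairwise census with permutations multiplies the work a thousandfold.

Since permuting a feature's values permutes its partition labels identically
(quantile cuts depend only on the value multiset), the implementation
permutes the precomputed label matrix rather than re-partitioning — exact,
and roughly an order of magnitude faster.

## Tiers, intersection categories, and candidates

To compare coefficients the way large pair censuses are summarized, each
coefficient's values over all pairs are split into **high** (the
$\lceil q\,N\rceil$ largest, default $q = 0.30$), **low** (the
$\lceil q\,N\rceil$ smallest), and **neither**. CCC is ranked by its value;
Pearson and Spearman are ranked by *absolute* value, since CCC's
non-negative scale is only comparable to a magnitude (the alternative,
signed ranking, would call a strong negative correlation "low"; with
magnitude ranking it is "high", which matches the reading of low = "no
signal"). Ties break by stable input order; the ceiling rule makes counts
deterministic.

Each pair's tier triple (CCC, Pearson, Spearman) is its *intersection
category*: **agreement** when all three tiers are identically high or low,
**disagreement** when at least one high and one low coexist. Among the nine
possible (Pearson, Spearman) tier combinations, exactly **five** contain a
"low" — these five CCC-high disagreement groups are where candidate
nonlinear pairs live. Candidates are selected from chosen groups by CCC
descending (ties by pair order), truncated to `top_n`; selection is by rank,
not significance, so no multiple-testing correction is applied and p-values
are reported raw with their `n_perm` provenance.

A caveat measured during development and worth stating: tier membership is
*relative to the dataset*. In a small feature set, a motif pair whose
|Pearson| is merely *small* (of the same order as null sampling noise,
$\sim 1/\sqrt{n}$) lands in the bottom tier only by chance; the membership is
structurally guaranteed only when Pearson is exactly zero by design, as for
the symmetric quadratic. The tier tests use that structural case; motif
detection itself is tested through the quantitative contracts below.

## The synthetic motif generator

`generate_pair_pattern()` and `generate_dataset()` emulate the canonical
relationship shapes against which the coefficient is evaluated, with
additive Gaussian noise and uniform base distributions — the simplest model
producing the qualitative motifs:

* **linear**: $x \sim U(0,1)$, $y = 2x + 1 + \varepsilon$;
* **quadratic**: $x \sim U(-1,1)$ (symmetric), $y = x^2 + \varepsilon$;
* **cohort_shift**: two cohorts, within-cohort slope $+1$ and offsets
  $\pm 2$ ($x \sim U(0,2)$ vs $U(2,4)$), so both cohorts trend up while the
  pooled least-squares slope is negative;
* **group_masked**: $x = 0$ exactly in one group, $x \sim U(1,3)$ and
  $y = x + \varepsilon$ in the other; the masked group's $y \sim U(3,5)$,
  i.e. the partner gene is upregulated where $x$ is silenced. This placement
  is a deliberate design choice: it makes the pair's CCC robustly exceed
  0.3 with |Pearson| below it, whereas a same-range draw dilutes the pair
  coefficient to ~0.18 (the gene–group association is 1.0 either way);
* **subset_masked**: one subset linear, the other independent noise
  *overlapping the same range* — faithful to the motif it mimics, which
  also means the pair's CCC is genuinely modest (~0.15–0.33 across seeds);
  tests assert a floor of 0.1 for it and 0.3 for the stronger motifs;
* **null**: independent Gaussians.

Defaults are `n_samples = 200`, `noise_sd = 0.1`, `group_fraction = 0.5`
with exact (not binomial) group counts in shuffled order, so the 50/50
group-masked contract `ccc(gene, group) = 1` holds deterministically. All
generation is seeded; `generate_dataset()` derives per-pair seeds from the
dataset seed and re-draws the two-population motifs conditional on the
shared metadata labels (group, cohort), so gene–metadata association can
recover the truth table.

What the generator does *not* emulate: RNA-seq count distributions,
library-size and batch effects, gene–gene correlation structure beyond the
engineered pairs, and realistic missingness. Passing tests on these fixtures
therefore demonstrate the statistic's pattern-detection properties and the
pipeline's correctness, not performance on any particular real dataset.

## Numerical and scale choices

Problem sizes in the tests and the reproduction script were chosen to keep a
full run comfortable on a single desktop CPU: the exhaustive oracle check
uses 6 samples (122 partitions), coefficient-law sweeps use 100–200 samples
over 200 random pairs, p-value calibration uses 500 null pairs at $n = 50$
with 100 permutations, and the scale exercise computes all 124,750 pairs of
500 features × 200 samples (about 10 million ARI tasks, ~20 s with the
compiled backend). The default engine budget of 4 GiB is far more than
these workloads need; the batch planner is exercised separately with small
budgets down to one task per batch.

## Known limitations

* The coefficient is insensitive to the *direction* of association; a sign
  must come from a complementary statistic.
* Permutation p-values are exchangeable-null tests; they do not account for
  sample covariates or batch structure.
* The k-sweep default 2..10 is a convention, not an adaptive choice; very
  small samples may warrant a smaller `k_range` (partitions that collapse
  are dropped automatically).
* `ccc_matrix` precomputes partitions only for complete data; with missing
  values it falls back to per-pair computation, which is slower but keeps
  the pairwise-complete contract exact.
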
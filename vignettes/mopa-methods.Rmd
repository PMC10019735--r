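---
title: "Multi-omics pathway activity scoring: model and methods"
author: "mopa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics pathway activity scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mopa)
```

## The problem

Matched multi-omics profiles — mRNA expression, miRNA expression and DNA
methylation measured on the same patients — each view a biological process
from a different angle. Pathway-level summaries are the standard way to make
such data interpretable, but most enrichment tools score one omics layer at
a time and leave the integration to the reader. This package scores each
pathway **per sample** with a single number that blends all omics layers
(the multi-omics enrichment score, mES), and then explains that score by
apportioning it across the layers per sample group (the omics contribution
rate, OCR).

## The model

### Gene-level transformation

Pathways are gene-centric, so every layer is first expressed in gene units:

* miRNA: a gene receives the arithmetic mean expression of the miRNAs that
  target it (`mirna_to_gene()`); genes with no targeting miRNA get 0.
* methylation: a gene receives the mean beta value of probes falling in the
  2 kb promoter window upstream of its transcription start site
  (`methylation_to_gene()`); genes without an in-window probe get 0.
* mRNA is already gene-level.

The promoter window is strand-aware — `[TSS - w, TSS)` on the plus strand,
`(TSS, TSS + w]` on the minus strand — with the outer edge inclusive and
the TSS itself excluded. "Within w bp upstream" does not by itself fix the
boundary; we chose the closed outer edge so a probe at exactly the window
distance still counts, and treat upstream in the strand's own orientation
because that is what upstream of a TSS means biologically. Positions are
interpreted as 1-based, as distributed in vendor manifests.

Each gene-level layer is min–max normalized per gene by default
(`normalize_layer()`), making the layers scale-comparable before they are
stacked; the layers are then intersected on genes and samples and assembled
into a nonnegative tensor `T` of shape samples × genes × omics
(`assemble_tensor()`). The intersection (not the union) is used because a
tensor needs complete slices. We average raw miRNA values before
normalizing the resulting gene-level layer, rather than normalizing first;
the order is not fixed by the method definition and averaging raw values
keeps the aggregation interpretable as mean expression.

### Non-negative CP decomposition

`decompose()` factorizes `T` into `R` rank-1 nonnegative components

    T ≈ Σ_f  s_f ⊗ g_f ⊗ o_f,

giving loading matrices `S` (samples × R), `G` (genes × R) and `O`
(omics × R). Each component is a recurring multi-omics pattern: which
samples express it (`s_f`), through which genes (`g_f`) and in which layers
(`o_f`). The solver is hierarchical alternating least squares (HALS):
closed-form column updates projected onto the nonnegative orthant, from a
random nonnegative initialization drawn from the supplied seed. Defaults:
`max_iter = 500`, convergence when the relative residual changes by less
than `tol = 1e-7` between sweeps. HALS was chosen over multiplicative
updates because it reaches machine-level residuals on exact low-rank
tensors orders of magnitude faster, which the factor-recovery tests rely
on.

CP factors are only identified up to per-component rescaling, so a fixed
convention matters: after fitting, each component's scale is absorbed into
`S`, leaving `G` and `O` columns unit-norm. Downstream scoring uses `G` and
`O` entries directly; without a convention the absolute score scale would
depend on solver internals. Scores from other implementations of the same
statistic may differ by a monotone transformation — orderings, not absolute
values, are the portable quantity.

`rank_scan()` refits over a grid of ranks and reports residuals for elbow
inspection. For data at real cohort scale (hundreds of samples, ~15k genes)
ranks in the 160–200 range are a reasonable starting point; the synthetic
studies in this package use small ranks (3–20) matched to the planted
structure. The rank cannot exceed the smallest unfolding dimension the
solver supports.

When group labels are available, `select_features_supervised()` keeps the
components whose sample loadings separate the groups (Kruskal–Wallis per
column, Benjamini–Hochberg at `alpha`, capped at `max_features`). This
selector is deliberately a simple, replaceable stand-in: `feature_list`
accepts an externally computed component index list verbatim, so runs
driven by a different selection method can be reproduced exactly.

### Assigning components to samples

Not every component is active in every sample. For sample *i*, its loading
vector over the selected components is min–max scaled to `[0, 1]`
(`minmax_scale_sample()`); a Gaussian-KDE cumulative distribution is fitted
to the scaled vector and evaluated at each entry (`cdf_values()`); the
components with CDF ≥ 0.6 form the sample's assigned set `f̂_i`
(`assign_features()`). The threshold 0.6 is the default because it behaves
robustly across datasets; `threshold_scan()` reports how the mean assigned
set size shrinks (monotonically) as the threshold rises. Choices we fixed
where the statistic's definition is silent: Gaussian kernel with Scott's
rule bandwidth (`sd · n^(-1/5)`), overridable; the CDF is computed per
sample over that sample's own scaled loadings; ties at exactly the
threshold are included; the upper tail is selected (high CDF = strongly
sample-associated). A sample whose set would be empty receives its
maximum-loading component with a warning, so every sample carries at least
one component — as a corollary, the maximum-loading component is always in
`f̂_i`.

### The enrichment score

Gene loadings over the selected components are z-normalized per column
(population standard deviation) and shifted so the column minimum is zero
(`normalize_gene_loadings()`); any consistent variance divisor gives the
same ordering after the shift, so the choice only fixes the scale. The
rank weight of gene *j* in sample *i* is

    r_ij = Σ_{f ∈ f̂_i}  g′_jf · s′_if ,

a nonnegative mixture of the sample's active patterns (`rank_weights()`).
Genes are sorted by descending `r_ij` — ties broken by ascending gene id
for bit-reproducibility — and a weighted Kolmogorov–Smirnov random walk is
taken along the list (`ks_walk()`): the running difference between the
fraction of pathway-member weight accumulated and the fraction of
non-member genes passed,

    d_j = (Σ_{l ≤ j, member} r_(l)) / (Σ_{member} r)
        − #{l ≤ j, non-member} / (q − |p|),

with `q` the number of genes in the dataset and `|p|` the pathway's member
count. The normalizer in the first term is the total weight over **all**
member genes — the only reading under which every walk ends at `d_q = 0`,
as both fractions reach one. The score is

    mES = max(0, max_j d_j) − |min(0, min_j d_j)| ∈ [−1, 1],

attaining +1 exactly when all members head the list and −1 when they trail
it (`mes_from_walk()`, `score_all()`). Because the first term is a ratio,
multiplying a sample's weights by any positive constant changes nothing.
Pathways overlapping the gene universe in fewer than `min_overlap = 2`
genes, covering the whole universe, or with zero member weight are skipped
with a machine-readable reason rather than silently dropped.

### The omics contribution rate

OCR explains, per sample group and pathway, how the score-driving
components distribute over the omics layers. Components assigned to at
least half the samples of a group (`share_frac = 0.5`, boundary inclusive)
form the group's shared set (`group_shared_features()`). For each pathway
gene the strongest shared component is taken — argmax over the normalized
loadings `g′`, ties to the lowest index (`gene_argmax_feature()`) — and the
corresponding `O` columns are summed over the pathway's genes and
normalized to fractions (`compute_ocr()`, `ocr_table()`):

    C_mt = Σ_{j ∈ p_t} O[, argmax_f g′_jf],    OCR_kmt = C_kmt / Σ_k C_kmt.

Every defined OCR vector sums to one. The `O` columns are used exactly as
fitted under the unit-norm convention; the final normalization removes any
per-cell scale. The argmax is taken over the normalized (not raw) gene
loadings, matching how the gene side enters the score. If labels are
absent, cluster labels from `cluster_samples()` can serve as groups. A cell
whose total contribution is zero is reported as undefined, never fabricated.

## Downstream analyses

* `stratify_by_es()` labels the top and bottom `floor(0.2 · n)` samples per
  pathway as high/low score strata (ties broken by sample id);
  `logrank_test()` compares their survival with the two-sample log-rank
  test — the field default where a Kaplan–Meier comparison is shown without
  naming the statistic. A stratum with zero events returns p = 1 with a
  warning rather than an error.
* `cluster_samples()` runs K-means on the raw mES rows (no row scaling;
  Euclidean), best of `n_init` restarts by inertia, deterministic given the
  seed; `adjusted_rand_index()` quantifies agreement with reference labels.
* `gene_association()` runs classic one-way fixed-effects ANOVA of each
  gene's rank weight across groups with Bonferroni correction over the
  genes tested; zero-variance genes are kept at p = 1 so the correction
  multiplier is stable.
* `build_pathway_network()` connects pathways sharing at least `min_shared`
  genes; node annotations (OCR fractions, survival p, gene count) vary by
  group while the topology does not. Exports: SIF (`a<TAB>shares<TAB>b`)
  and GraphML.

## The synthetic-data generators

`generate_tensor()` builds the study conditions all end-to-end tests run
under: by default 3 groups × 40 samples, 1000 genes, 3 omics layers, 4
planted components per group plus 8 background components (total rank 20),
in-group loading elevation `effect = 2`, and half-normal noise with
`noise_sigma = 0.1`. Noise is truncated-at-zero Gaussian because that is
the simplest null respecting the nonnegative CP model. Each group's planted
components concentrate ~70–90% of their omics mass on the group's
designated layer, so an OCR ground truth exists. `generate_gene_sets()`
draws planted pathways from the top-loading decile of a planted component's
gene vector and null pathways uniformly. `generate_survival()` plants an
exponential hazard ratio on the top half of a chosen pathway's score with
independent censoring. `generate_raw_omics()` emits raw miRNA/methylation
inputs with probes placed on both strands, inside and outside the promoter
window, and records hand-computable gene-level expectations.

What the generators emulate is the structural assumption of the method —
group-specific low-rank multi-omics patterns — not the marginal
distributions of real cohort data: no count overdispersion, no bimodal beta
distributions, no batch effects, no missing samples. Tests passing on this
synthetic family show the machinery is correct and the statistic behaves as
designed; they do not certify performance on any particular cohort.

## Numerical choices and degenerate inputs

* Solver tolerance is on the *change* in relative residual; non-convergence
  returns the result with a warning rather than failing.
* Constant per-sample loading vectors cannot be min–max scaled and raise an
  error naming the sample; constant gene-loading columns are zeroed with a
  warning.
* All tie-breaks are deterministic: descending weight sorts break ties by
  ascending gene id, argmax ties go to the lowest component index,
  stratification ties to the ascending sample id.
* Problem sizes in the test suite are chosen to exercise every code path at
  small scale: oracle comparisons use gene universes up to 50, solver
  recovery uses rank-3 tensors of ~80 genes, and the end-to-end recovery
  study uses the generator defaults above over 5 seeds.
* K-means at `k = n` (singleton clusters) switches to Lloyd's algorithm,
  since Hartigan–Wong requires `k < n`.

## Known limitations

* The CP solver is plain R; cohort-scale fits (hundreds of samples, tens of
  thousands of genes, rank ~200) take minutes, not seconds.
* The supervised component selector is a simple univariate test, not a
  regularized multi-task selector; it is intended to be swapped out via
  `feature_list` when a stronger selector is available.
* No pathway-level p-value is attached to mES: the statistic's sampling
  distribution under a null is not defined here, and we deliberately do not
  invent one. Group-difference tests on mES columns are the natural ad-hoc
  alternative.
* Scores are comparable across samples within one fit; comparing absolute
  mES values across fits with different ranks or normalization settings is
  not meaningful.
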
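---
title: "Partitioning transcript variance in replicated animal designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning transcript variance in replicated animal designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestvar)
```

## The problem and the model

When an expression study collects duplicate tissue samples from each of
several genetically identical animals, the variance of every gene can be
split into a component that differs between animals and one that differs
between samples of the same animal. `nestvar` implements that partition and
everything downstream of it: significance tests for excess and
between-animal variance, coexpression modules among the most variable
genes, module eigengenes and their between-/within-animal similarity, and
gene-set enrichment of modules.

The core model is a balanced one-way random-effects layout. For gene $g$,
mouse $i = 1,\dots,n$ and replicate $k = 1,\dots,K$ the log2 abundance is

$$y_{ikg} = \mu_g + b_{ig} + w_{ikg}, \qquad
  b_{ig} \sim N(0, \sigma^2_{bg}),\quad w_{ikg} \sim N(0, \sigma^2_{wg}),$$

and the intraclass correlation $c = \sigma^2_b / (\sigma^2_b + \sigma^2_w)$
measures how much of a gene's variation is between animals. A second model
splits the animal effect further into a cage effect and a
mouse-within-cage effect for co-housed animals. The reference design
throughout is 12 mice housed as pairs in 6 cages with 2 samples per mouse
(24 arrays per tissue), processed in two batches of three cages.

## Estimation and testing

**Variance decomposition** (`decompose_variance()`) uses the closed-form
REML solution for the balanced layout. In the interior (`MSB > MSW`) this
is the familiar ANOVA estimator $\hat\sigma^2_w = \mathrm{MSW}$,
$\hat\sigma^2_b = (\mathrm{MSB} - \mathrm{MSW})/K$; when
$\mathrm{MSB} \le \mathrm{MSW}$ the between component is truncated at zero
and REML pools both strata, $\hat\sigma^2_w = (SSB + SSW)/(nK - 1)$. The
two branches agree at the boundary, and the whole function is verified in
the test suite against a brute-force grid search over the restricted
likelihood to $10^{-6}$. Unbalanced designs fall back to iterative REML
(lme4) with a warning. Estimated between components below $10^{-4}$ are
flagged (`near_zero_between`), the reporting convention used for
density displays of component distributions.

**Excess variance** (`pooled_scale()`, `excess_variance_test()`). The null
that all genes share one variance is anchored by a pooled James–Stein-style
scale: the bias-corrected geometric mean
$\hat\sigma^2 = \exp\{\overline{\ln s^2_g} - (\psi(\nu/2) - \ln(\nu/2))\}$,
where the digamma term is the exact mean of $\ln(s^2/\sigma^2)$ under
$\chi^2_\nu$. Each gene's scaled variance $\nu s^2_g/\hat\sigma^2$ is
referred to the analytic upper tail of $\chi^2_\nu$ ($\nu = 23$ for the
reference design). Using the analytic tail rather than a Monte-Carlo
reference sample makes the test deterministic without changing it. The top
2500 genes by total variance (configurable, and capped at the expressed
count) form the *variable genes* used by the network stage.

**Shrunken F and permutation null** (`shrunken_f()`,
`permutation_pvalues()`). Between-animal significance uses
$F_g = \mathrm{MSB}_g / \tilde\sigma^2_g$ where $\tilde\sigma^2_g$ shrinks
the log within-mouse mean square toward its across-gene mean with the
Lindley-type factor
$B = \min\{1, (G-3)\,\psi'(d/2) / \sum_g (z_g - \bar z)^2\}$,
$z_g = \ln \mathrm{MSW}_g - (\psi(d/2) - \ln(d/2))$, $d = n(K-1)$. With
$B = 0$ this is exactly the classic F. P-values come from permuting
reduced-model residuals (values minus the per-gene mean; the
Freedman–Lane convention): one random relabelling of the sample positions
per round, applied to every gene, with the statistic — including its
shrinkage step — recomputed each round. The null is pooled across genes by
default, which gives resolution below $1/n_{\mathrm{perm}}$; per-gene
pooling is available. We also tried permuting full-model residuals (values
minus mouse means); that variant is conservative (empirical type-I error
about 0.02 at nominal 0.05) and is not used.

One property of the pooled permutation null is worth knowing: genes with
strong true between-animal variance keep that variance inside their
reduced-model residuals, so under permutation it is redistributed into the
pooled null, and p-values of null genes become slightly anti-conservative
when strong alternatives are abundant. This biases the plug-in
$\hat\pi_0$ downward by a few points in such mixtures. For $\pi_0$
demonstrations the package therefore uses the exact classic-F p-values
(whose null is exactly uniform in the balanced normal design); in real
analyses the same caveat applies to any pooled permutation null.

**Multiplicity** (`adjust_pvalues()`, `estimate_pi0()`). Family-wise
control uses step-down Šidák ($1 - (1-p_{(i)})^{m-i+1}$ with a running
maximum); FDR uses Benjamini–Hochberg; Storey q-values multiply the BH
quantity by $\hat\pi_0$. The default $\hat\pi_0$ is the plug-in
$\#\{p > \lambda\}/(m(1-\lambda))$ at $\lambda = 0.5$, capped at 1; a
spline-smoothed $\lambda$-grid variant is available.

**Cage model** (`decompose_cage()`) is the balanced nested ANOVA with
strata cage / mouse-within-cage / within-mouse, truncated component
estimates, and analytic F tests of each stratum against the one below it.

## Coexpression modules

The network over variable genes is unsigned: adjacency is the squared
Pearson correlation across all samples (no soft-threshold search — the
square *is* power 2 on $|r|$). Topological overlap is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu},$$

with unit diagonal. Modules come from average-linkage clustering of
$1 - \mathrm{TOM}$ followed by three deterministic steps:

1. **Adaptive cut.** The tree is cut at the midpoint of the largest gap
   between consecutive merge heights in the upper part of the tree
   (`deep_split` 0–4 widens the searched region; default 2 = the top
   half). A fixed fraction of the maximum height proved fragile in both
   directions — isolated genes stretch the tree top, and TOM compresses
   height contrast — whereas the largest gap tracks the transition from
   branch structure to the agglomerate top.
2. **Membership pruning.** Members correlating below `prune_cor` (default
   0.3) in absolute value with their cluster eigengene are released; this
   removes noise genes chained onto a branch by average linkage. Clusters
   with 25 or fewer members (configurable) are then dissolved to
   unassigned.
3. **Eigengene merging.** Modules whose eigengenes correlate above
   `merge_threshold` (default 0.8) are merged iteratively, largest
   correlation first. Over-splitting by the cut is therefore harmless.

Labels follow the conventional colour order by decreasing size
(turquoise, blue, brown, gold, …; gold occupies the conventional yellow
slot).

The **module eigengene** is the first principal component of the
gene-standardized module submatrix. Its sign makes the strict majority of
members positively correlated (ties resolve toward a positive correlation
sum), and it is rescaled so its variance equals the median member
variance, making eigengene plots read as an average log2 fold-change. The
positively and negatively correlated member subsets are kept and tested
for enrichment separately.

## Profile similarity and enrichment

`split_profiles()` decomposes any profile into a between-mouse part
(per-mouse replicate means) and a within-mouse part (replicate 1 minus the
mouse mean; for duplicates, the half-difference), an exact linear
bijection. `profile_correlations()` returns $r_b$ and $r_w$, the Pearson
correlations of those parts; $r_w$ is refused across tissues because
replicate labels only correspond within one tissue. Significance uses the
Fisher transformation: critical $|r| = \tanh(q/\sqrt{n-3})$. The default
reference takes $q$ from a Student t with 9 df, the convention that
reproduces the working thresholds 0.66 ($n = 11$, used for $r_b$ with 12
mice) and 0.64 ($n = 12$, for $r_w$) at $\alpha = 0.05$; the textbook
standard-normal reference is available. Why $r_b$ conventionally uses
$n - 1$ with $n$ animals is not derivable from first principles here; both
sample-size choices are exposed.

Enrichment is the upper-tail hypergeometric test against user-supplied GMT
collections, with the universe defined as the variable genes present in
the collection, one probe per gene (the largest-variance probe), and
case-insensitive symbol matching. Cross-tissue module overlap uses the
same test with Bonferroni correction; two modules share an enrichment when
each has at least 4 genes of the category at $p < 0.01$. Cross-platform
comparison maps probes by shared gene symbol (candidates below mean
intensity 7 excluded, best-correlated candidate wins) and reports the
sign-aligned correlation of module eigengenes recomputed on the second
platform — sign-aligned because the eigengene sign is a per-platform
majority convention.

## The simulator

`simulate_study()` runs the generative model forward under the reference
design: per-gene Gaussian cage, mouse and within-mouse components; module
structure via shared standard-normal latent factors (one per mouse for
between-animal modules, one per sample for within-animal ones) entering
member genes scaled by a loading; additive per-gene batch shifts; and
background probes — non-expressed genes and negative controls — drawn as a
per-probe baseline ($\mathrm{sd} = \texttt{background\_sd}$) plus smaller
within-probe noise ($\mathrm{sd}/4$). The baseline-dominated background
mirrors real arrays, where probe-to-probe affinity differences dwarf
replicate noise; without it, the max-over-animals detection rule would
flag half the background by chance. Even so, a 95th-percentile threshold
admits 5% of background probes by construction, so detected fractions sit
a few points above the true expressed fraction.

Defaults were chosen once to emulate the reference study: 6 cages × 2 mice
× 2 replicates; expressed log2 means uniform on (8, 14); background
N(5, 0.3); half the genes expressed (the study detected 39–55% per
tissue); baseline components $\sigma^2_b = \sigma^2_w = 0.05$ (log2²);
two batches of three cages; batch shifts off by default. The simulator
reproduces marginal variances, nested correlation structure, planted
module correlation ($\mathrm{loading}^2/\mathrm{total}$) and detection
behaviour; it does not attempt platform-specific noise shapes, probe
cross-hybridization, intensity-dependent variance, or heavy-tailed
biological effects — so green tests demonstrate correctness of the
estimators under the stated model, not fidelity to any particular array
platform.

## Numerical conventions and edge cases

* Percentiles use linear interpolation between order statistics (type 7).
* Quantile normalization maps every column to the mean order statistics;
  ties receive the mean of the quantiles they span; the operation is
  idempotent to $10^{-12}$.
* Batch correction removes a per-gene per-batch median and restores the
  per-gene global median (a Huber M-estimator hook exists); single-sample
  batches are skipped with a warning.
* Zero-variance genes: excluded with a warning from the pooled scale;
  permutation p reported `NA`; an error (naming the gene) in network
  construction, where a constant profile has no correlation.
* Ties: module labels break size ties by first gene position; platform
  mapping breaks correlation ties by probe id order; the eigengene sign
  tie (equal positive and negative members) resolves toward a positive
  correlation sum.
* Problem sizes in the shipped checks — 2000 genes for calibration and
  recovery, 5000 for $\pi_0$, 60-gene networks for planted-partition
  recovery, 200 permutation rounds — were chosen so each property is
  measured well inside its Monte-Carlo tolerance while the whole suite
  runs in well under a minute per check.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = simulation_config(
    n_genes = 3000, frac_expressed = 0.5, n_negative_controls = 300,
    module_spec = list(list(size = 60, loading = 0.6, level = "mouse"),
                       list(size = 40, loading = 0.8, level = "sample")),
    seed = 1),
  n_perm = 500, seed = 1, out_dir = "nestvar_report")
res <- run_pipeline(cfg)
res$table1   # expressed / variable / significance / fold-change summary
res$table2   # module sizes, enrichment placeholder, median icc
```

## Known limitations

* The balanced closed forms require equal replicate counts; the lme4
  fallback is much slower and is per-gene iterative.
* The adaptive gap cut is a deliberate simplification of branch-adaptive
  dendrogram cutting; on real data module boundaries will differ
  gene-for-gene from any specific dynamic-cut implementation, even though
  planted structure is recovered exactly in simulation.
* The pooled permutation null couples genes; see the $\hat\pi_0$ caveat
  above.
* Symbol matching is exact (case-insensitive) with no alias resolution;
  curated annotation maps are out of scope.
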
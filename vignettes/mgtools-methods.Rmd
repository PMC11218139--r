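---
title: "Statistical methods in mgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in mgtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgtools)
```

mgtools is a scriptable statistical engine for shotgun-metagenomics count
tables and companion omics tables (metabolite intensities, gene-function
abundances). This vignette explains the models and procedures it
implements, the conventions and defaults it adopts where the field allows
several, and what its validation on synthetic data does and does not show
about real data.

## Data model and identifier harmonization

Everything downstream operates on a `feature_table`: a samples-by-features
numeric matrix with a feature kind (taxon cluster, metabolite, gene
function) and a tag recording the transformation applied. The
samples-in-rows layout is canonical and enforced at the boundary —
`read_feature_table()` transposes files stored features-in-rows, so no
downstream function needs an orientation argument.

Multi-omics analyses require all datasets to describe the same samples.
`harmonize_samples()` restricts every table and the metadata to the
exact-match intersection of sample ids and puts them in a single
lexicographic order (stable across locales), reporting every dropped id
per input. Exact matching is deliberate: silently case-folding or
whitespace-trimming identifiers is a classic source of sample mix-ups, so
mismatches surface as dropped samples in the report instead. Missing
metadata values stay `NA` and become "excluded sample" in any test using
that variable; they never silently become zero.

## Preprocessing

* `relative_abundance()` divides each sample by its total. Sequencing
  depth is a nuisance parameter; proportions are the minimal
  depth-standardization, and rank-based tests downstream are unaffected
  by the choice of scale within a sample.
* `log_transform()` computes `ln(x + eps)`. "Log-normalized" abundance is
  read as the natural log of relative abundance; the pseudocount default
  is half the smallest non-zero entry of the whole table, a single global
  floor so zeros from different features remain comparable. A fixed
  pseudocount is available when comparability across tables matters.
* `pareto_scale()` is the metabolomics convention `(x - mean)/sqrt(sd)`,
  with the sample (n-1) standard deviation. It shrinks the dominance of
  high-variance intensities without flattening them entirely (as
  unit-variance scaling would). Constant features cannot be scaled; they
  are set to zero and reported, not dropped silently.
* `aggregate_by_group()` collapses contig coverages into genome-cluster
  abundances through a CONCOCT-style assignment; the default statistic is
  the mean of member contigs, matching the convention of expressing a
  genome cluster as the average coverage of its contigs. Unassigned
  contigs are dropped and reported.
* `block_scale()` prepares a table for multi-block decomposition:
  column-centering followed by division of the whole block by its
  Frobenius norm, so each block enters the joint analysis with total sum
  of squares 1. Without this, the wider or noisier block dominates every
  joint component. The returned record inverts the transform exactly.

## Alpha diversity

With within-sample proportions $p_i$ over non-zero features:
$H = -\sum p_i \ln p_i$ (Shannon, natural log), $D = 1 - \sum p_i^2$
(Gini–Simpson), $J = H/\ln S$ (Pielou, $S$ = observed richness). The
Gini–Simpson complement is reported — rather than $\sum p_i^2$ or its
inverse — so that for all three indices larger means more diverse; the
form is recorded in CLI output headers since "Simpson index" is ambiguous
in the literature. $0 \ln 0$ is resolved by summing over non-zero
features only, and $J$ is undefined at $S = 1$ (reported missing, not 0).

## Phylogenetic community structure (MPD/MNTD, NRI/NTI)

For each sample, MPD is the mean cophenetic distance over unordered pairs
of present taxa and MNTD the mean distance to the nearest present
neighbour. Standardized effect sizes compare the observed value to a null
distribution obtained by shuffling taxon labels across the distance
matrix ("taxa.labels" null): each replicate assigns the community to a
uniformly random tip subset of the same size, with one relabelling shared
by all samples of a replicate. Then

$$SES = \frac{obs - \overline{null}}{sd(null)}, \qquad NRI = -SES_{MPD},
\qquad NTI = -SES_{MNTD},$$

so positive NRI/NTI means phylogenetic clustering. The label-shuffle null
with 999 replicates is the most common choice in the community-phylogenetics
literature; both the null model name and replicate count are recorded in
the output so the choice is explicit. Presence/absence (unweighted)
statistics are used; abundance weighting is intentionally not implied by
the data. Degenerate nulls — a star tree makes every subset have the same
MPD — yield missing SES with a `degenerate` flag instead of a spurious 0.
The one-sided rank p `(#{null <= obs} + 1)/(n_null + 1)` is reported
alongside; it never reaches 0 by construction.

The permutation null was validated against exhaustive subset enumeration:
for pools of up to 6 taxa the permutation mean and sd converge on the
exact values over all $\binom{n}{k}$ subsets (agreement within 3
Monte-Carlo standard errors at 9,999 replicates, using the
kurtosis-aware standard error of a sample sd, since these small nulls are
far from normal).

## Ordination and distance-based tests

`bray_curtis()` computes
$d_{ij} = \sum_k |x_{ik}-x_{jk}| / \sum_k (x_{ik}+x_{jk})$ (through
vegan), bounded in [0, 1]. `pca()` wraps the singular value decomposition
of the centered (optionally unit-scaled) matrix; the default is centering
only, which suits community data, while metabolite tables are expected to
be Pareto-scaled upstream. `pcoa()` double-centers $-\tfrac12 d^2$ (Gower)
and eigendecomposes; negative eigenvalues (metric violations, common with
Bray-Curtis) are reported, and explained fractions use the positive part
of the spectrum only. The "MDS" of microbiome practice is metric PCoA,
which is what is implemented. Every ordination axis has its sign fixed so
the largest-magnitude loading (or score, for PCoA) is positive, making
runs and figures comparable across machines.

`permanova()` is the single-factor distance-based test:
$SS_{total} = \frac1N \sum_{i<j} d_{ij}^2$, within-group sums scaled by
group size, pseudo-$F = (SS_B/(a-1))/(SS_W/(N-a))$, and
$R^2 = SS_B/SS_{total}$ — the fraction of community variability the
grouping accounts for. Significance comes from random relabelling with
the +1/+1 correction, so p has resolution $1/(n_{perm}+1)$ and is never
0. On univariate Euclidean data the pseudo-F reduces algebraically to the
classical one-way ANOVA F; the test suite checks this identity to 1e-10
and checks the test's type-I error on null groupings. Multi-factor
designs are out of scope.

`fso()` is single-variable fuzzy set ordination in the Roberts
formulation: similarities $s = 1 - d/d_{max}$, memberships
$\mu_i = (x_i - \min x)/(\max x - \min x)$, apparent values
$\hat y_i = \sum_{j \ne i} s_{ij}\mu_j / \sum_{j \ne i} s_{ij}$, and
$r = cor(\mu, \hat y)$, with a one-sided permutation p under shuffles of
the covariate. A covariate well expressed in community structure (e.g. a
planted gradient) gives $r$ near 1; the suite also checks the null holds
its size.

## Differential abundance and post hoc comparisons

`differential_table()` runs a per-feature omnibus test — Kruskal-Wallis
for independent groups, Friedman (with subject blocks) for repeated
measures — followed by Benjamini-Hochberg adjustment **across features**,
and Dunn's pairwise post hoc with BH **across pairs within each feature**
for features passing `padj <= alpha`. The two-level correction is the
field default where only "corrected P-values" are specified; the method
is a parameter and is recorded in output. Kruskal-Wallis and Friedman use
the base-R implementations (mid-ranks, tie correction, chi-square
approximation); exact small-sample tables are not used, so group sizes
below ~5 deserve caution. Dunn's z follows the tie-corrected formula on
the global mid-ranks; for two tie-free groups $z^2$ equals H exactly,
which the tests assert. Constant features are flagged `degenerate` with
missing p rather than aborting the run, and group means are reported on
whatever transform scale the input table carries (log-relative abundance
for taxa, Pareto-scaled intensity for metabolites).

Correlations (`correlate()`) are Pearson, Spearman, or Kendall tau-b with
tie correction, two-sided, with the t (Pearson/Spearman) or normal
(Kendall) approximation; pairwise-complete deletion handles missing
values.

## KEGG pathway over-representation

The counting unit is the KO, not the feature: a genome cluster
contributes the union of its KOs, because pathway membership is defined
on orthologs, and counting features would double-weight multi-copy
annotations. The default background universe is every KO mapped to at
least one pathway among the input annotations ("annotated-only");
`all-annotated` widens it to every KO seen. For each pathway the
upper-tail hypergeometric p is computed (one-sided over-representation
only; depletion is not reported), BH-adjusted across pathways. The tail
probabilities were validated against brute-force enumeration of all
selections for universes up to 12 KOs.

## Two-block joint decomposition

All three methods take blocks prepared by `block_scale()`, so each block
contributes equal total sum of squares, and all fix component signs by
the largest-|loading| convention.

**DISCO-SCA.** A rank-$R$ simultaneous component analysis of the
column-wise concatenation ($R$ = common + both distinctive ranks) by
truncated SVD, followed by an orthogonal rotation of the component space
chosen to minimize the squared loadings on positions constrained to zero:
a distinctive component of one block must not load on the other block.
The minimization is by iterative majorization — each step zeroes the
constrained positions of the current rotated loadings and solves an
orthogonal Procrustes problem — run from the identity plus 10 seeded
random starts, keeping the best. The stopping rule is a relative decrease
below `tol` (default 1e-8) so near-zero optima are polished rather than
abandoned; because the rotation acts inside the fitted subspace, the SCA
fit itself is unchanged, which the tests assert to 1e-10. Residual
cross-block energy of the distinctive components is reported per block.

**JIVE.** Alternating estimation of a joint structure (best rank-$r$
approximation of the concatenation minus individual structure) and
per-block individual structures (best rank-$r_b$ approximation of the
block minus its joint slice, projected orthogonal to the joint
sample-space basis), iterated until the summed Frobenius-norm change
falls below `tol` (default 1e-7). At a fixed point the joint, individual
and residual matrices are mutually orthogonal, so each block's variance
decomposition sums to one; non-convergence at `max_iter` is returned as a
flag, not an error.

**O2PLS.** Joint weights come from the leading singular triplets of the
cross-block covariance $Y^\top X$. Each block's structured noise —
variation orthogonal to the joint scores — is estimated from the residual
of the joint model part and deflated one component at a time (the Trygg
filter), after which the joint weights are re-estimated on the filtered
matrices. The point of the filter is visible in the tests: with a planted
block-specific component overlapping the joint loading direction,
loading recovery only reaches ~1 after filtering.

Ranks are user-supplied for all three methods; there is no automatic
selection because a single shared component is the typical use and no
selection rule is assumed. A scree of SCA singular values is attached to
DISCO-SCA results to guide the choice. DISCO-SCA and O2PLS are two-block;
JIVE accepts two or more.

## Synthetic data: what the generators emulate

`simulate_community()` draws gamma-mixed Poisson counts: log-normal
baseline abundances (meanlog log 20, sdlog 1 — a realistic two-orders-of-
magnitude abundance range), balanced groups, log-scale offsets of size
`effect` on the affected taxa (alternating sign, so planted changes go
both directions), and multiplicative gamma noise with variance
`dispersion` (default 0.5, moderate microbiome-like overdispersion).
`simulate_paired_blocks()` builds $X_b = T P_b^\top + D_b Q_b^\top + E_b$
with shared scores $T$, block-specific $D_b$, all planted scores drawn
orthonormal **inside the sample-centered subspace** so that
column-centering leaves the planted structure exactly intact — without
this, centering slightly tilts the planted subspaces and no decomposition
could recover them exactly even at zero noise. `simulate_tree()` is a
constant-rate pure-birth (Yule) process.

These generators emulate the *statistical* structure the engine targets —
overdispersed counts with group shifts, low-rank joint/distinctive
variation, phylogenetic signal — but not compositional closure effects,
taxon-taxon correlation, batch effects, or realistic taxonomies. Passing
the validation suite therefore demonstrates correctness of the
algorithms under their own assumptions, not robustness to everything real
data does.

## Numerical choices and problem sizes

Permutation tests use the +1/+1 correction everywhere. All stochastic
functions take an explicit seed, restore the caller's RNG state, and are
bit-reproducible for a fixed seed. Validation problem sizes were chosen
to exercise the asymptotics while keeping the full suite around half a
minute: 200 null datasets for the PERMANOVA size check, 9,999
permutations against exhaustive nulls on 5–6 taxon pools, 20 replicates
per joint-decomposition method at signal-to-noise 10 (`noise_sd = 0.012`
under the default 40 x 30/25 geometry), and 50 replicates of the full
simulate → preprocess → test pipeline at the default study condition (60
samples, 200 taxa, 5 planted effects of size 2).

## Known limitations

Single-factor PERMANOVA only; no dispersion (PERMDISP) companion test; no
rarefaction or compositional (CLR/ILR) transforms; chi-square rather than
exact small-sample rank tests; KO-level enrichment assumes the provided
annotation is the background of interest; and the joint decompositions
assume blocks share exactly the same samples in the same order (enforced,
with harmonization available upstream).
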
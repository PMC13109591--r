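---
title: "Methods: transcriptomic inference for iPSC-derived dopaminergic neuron cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic inference for iPSC-derived dopaminergic neuron cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model of the data

`dantx` reimplements, as a tested pipeline over synthetic data with planted
ground truth, the inference stages used to characterize bulk RNA-seq from
induced pluripotent stem cell (iPSC)-derived dopaminergic neurons carrying
*LRRK2* or *Parkin* mutations: normalization, variance partitioning,
negative-binomial differential expression, differentiation-signature
derivation, non-overlapping signature algebra, pre-ranked GSEA and ORA,
protein-interaction modules via Markov clustering, signed-hybrid
co-expression networks, and pathway-activity linear models.

Counts are modeled as negative binomial: for gene g in sample s,

$$K_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g), \qquad
  \mu_{gs} = s_s \, q_g \, 2^{\sum_e \beta_{ge} x_{es}},$$

with sample size factor $s_s$, baseline abundance $q_g$, planted log2
effects $\beta_{ge}$ active when sample s carries level e, and gene
dispersion $\phi_g$ (variance $\mu + \phi\mu^2$). The synthetic generator
draws from exactly this model, which is also the model the Wald test fits —
the recovery experiments therefore probe estimation and calibration, not
model misspecification (see Limitations).

# The synthetic cohort

`study_metadata()` fixes the cohort layout to the study design: six cell
lines (two healthy donors, one LRRK2 carrier, three Parkin carriers), 34
samples — 12 healthy, 6 LRRK2, 16 Parkin — split 10/24 between two
differentiation laboratories ("place"), with gender and reprogramming
method (Sendai vs lentivirus) as line-level covariates. Defaults chosen
once for the generator, spanning typical bulk RNA-seq:

* baseline means log-uniform on $[2, 2^{12}]$;
* dispersions log-normal(meanlog $= \log 0.1$, sdlog $= 1$), overridable
  with a fixed value (0 gives Poisson draws);
* library-size factors log-uniform on $[0.5, 2]$;
* a batch ("place") effect planted as a +1 log2 additive shift on a random
  10% of genes, mirroring a significant laboratory-of-origin effect;
* planted mutation effects of $|LFC| = 2$: a shared component present in
  both mutation groups (the convergent disease signature) plus
  mutation-specific genes (`make_study_effects()`).

The reference differentiation time course (`simulate_timecourse()`)
emulates a progenitor baseline (day 0) plus neuronal cultures at weeks 2,
4, 6, 8. Marker trajectories are monotone by construction: the log2 shift
ramps linearly from `effect_size/2` at week 2 to `effect_size` at week 8
(the magnitudes per time point are not constrained by any published value;
a ramp keeps every pairwise contrast above the |LFC| > 1 threshold at the
default `effect_size = 3` while remaining monotone). Non-markers are flat.

The planted-partition interactome (`simulate_ppi()`), the latent-factor
co-expression generator (`simulate_coexpr()`), and the toy pathway-weight
generator (`simulate_weights()` with `inject_pathway_shift()`) plant the
ground truth for the MCL, module-detection, and pathway-activity stages
respectively. `simulate_coexpr()` uses positive loadings only: a
signed-hybrid network zeroes negative correlations, so its natural module
notion is a positively co-expressed block.

What the generators do **not** emulate: gene-gene correlation in the count
simulator (genes are conditionally independent given the design), GC or
length biases, outlier samples, isoform structure, and single-cell
sparsity. Passing recovery tests therefore demonstrates correctness of the
inference machinery under the stated model, not robustness to the full
messiness of real libraries.

# Normalization and batch correction

Size factors are plain median-of-ratios: $s_j = \mathrm{median}_g\,
K_{gj}/\tilde K_g$ over reference genes (geometric mean $\tilde K_g > 0$,
i.e. genes positive in every sample). The variance-stabilizing transform is
the documented stand-in $\log_2(K/s_j + 1)$ rather than a
dispersion-trend-based closed form; it feeds only PCA, PERMANOVA and the
co-expression network, never the differential test, so the simplification
affects exploratory geometry only.

Batch correction fits, per gene, least squares on the design and batch
codings jointly (treatment contrasts, alphabetically first level as
reference) and subtracts only the fitted batch component
(`limma::removeBatchEffect` does the fit). Correction defaults to the VST
matrix. The operation is idempotent and leaves the design-projected
component untouched; confounded design/batch combinations are an error
naming the aliased columns. Downstream network construction requires the
`batch_corrected` provenance tag unless explicitly overridden.

# Variance partitioning and marker tests

PERMANOVA uses Euclidean distances on sample vectors, the Gower-centered
inner-product matrix, and sequential (Type-I) sums of squares in the
user-given factor order; the permutation p-value uses the +1 convention
$(1 + \#\{F^* \ge F\})/(1 + n_{perm})$ under free row permutation, with BH
adjustment across factors (the adjustment method is not fixed by the study;
BH is used consistently everywhere in the package). Defaults:
`n_perm = 999`, explicit seed.

The two-way ANOVA batch screen runs per gene on $\log_2(K+1)$ of the raw
counts with place first and condition second (the second factor is a
package choice; the screen is sequential, so order matters only for
unbalanced designs).

The marker panel fits, per marker, a random-intercept model
`expression ~ mutation + (1 | place)` by REML (`lme4`), testing each
mutation level against healthy with a normal approximation on the Wald
statistic — a deliberate simplification of Satterthwaite degrees of
freedom; with two batch levels and 34 samples the approximation is mildly
anti-conservative, which is acceptable for a descriptive marker screen.
A separate two-sided Wilcoxon rank-sum test compares the two places on
pooled normalized expression. Degenerate (constant) markers report p = 1.

# Differential expression

Genes all-zero across samples are removed. Dispersions are estimated by
method of moments from the residual variance of an OLS fit of normalized
counts on the design ($\hat\phi_g = \max((v_g - \bar\mu_g \overline{1/s})
/ \bar\mu_g^2,\ 10^{-8})$), then shrunk 50/50 on the log scale toward a
least-squares mean-dispersion trend $\phi(\mu) = a_0 + a_1/\mu$. This
replaces empirical-Bayes shrinkage, outlier handling and independent
filtering; the simplification costs power, not interface or calibration
(the acceptance suite checks empirical FDR ≤ 0.1 under planted truth).

Each gene is fit by IRLS for the NB GLM with log link and offset
$\log s_j$ (weights $\mu/(1+\phi\mu)$), and contrasts are tested by Wald
statistics with standard errors from the inverse Fisher information
(dispersion fixed at the estimate, no overdispersion factor — matching the
convention of NB Wald pipelines). LFC is the natural-log contrast divided
by $\ln 2$; no LFC shrinkage is applied because the thresholds are applied
to raw LFCs. DEG thresholds are strict: FDR < 0.05 **and** |LFC| > 1
(boundary values excluded; the inclusive/strict choice is not documented in
the source material, strict is symmetric with the FDR inequality).

# Signature algebra

The differentiation signatures demand consistency: "neurons" is the
intersection of the up-lists of all four time-point contrasts, and
"progenitors" the intersection of the down-lists.

The six condition signatures follow the intersection rules (PD up/down from
the three disease-facing contrasts; LRRK2 and Parkin up/down from their
contrast pairs, with the LRRK2-vs-Parkin contrast entering with opposite
signs for the two mutations). Overlaps are then removed symmetrically: any
gene appearing in two or more of the six raw outputs is deleted from all of
them. A sequential removal in an unspecified order would depend on that
order; the symmetric rule is order-free and still guarantees pairwise
disjoint outputs, which the tests assert on random inputs.

# Enrichment

Ranked lists use the signed significance score
$\mathrm{sign}(LFC)\cdot\min(-\log_{10} p, 300)$ with ties broken by gene
identifier. The GSEA enrichment score is the extreme of the weighted
Kolmogorov-Smirnov running sum (hit increments $|r|^w$ normalized over the
set, miss decrements $1/(N-n)$, weight $w = 1$ classic). The null is
gene-set (tag) permutation — `n_perm` random same-size sets — not phenotype
permutation, matching the pre-ranked lineage. NES normalizes by the mean
|null ES| of matching sign; the nominal p is the matching-sign tail with
the +1 convention; FDR is BH across sets; the leading edge collects hits up
to the ES extremum. Set-size bounds default to [5, 5000]. The streaming ES
implementation is checked against an $O(N)$ running-sum recomputation to
1e-12 and against an independent reference implementation.

ORA is the upper-tail hypergeometric $P(X \ge k)$ with enrichment ratio
$ER = (k/|hits|)/(|S|/|U|)$ and BH across sets.

# Protein-interaction modules

Edge lists use the STRING download dialect (integer combined score
0-1000); the 0-1 website scale is auto-detected and rescaled, and the
0.4/0.7 confidence thresholds map to 400/700. The seeded network is the
induced subgraph on the DEG seeds at the chosen threshold; expansion adds
first- and second-order interactors (iterated neighborhood — equivalent to
shortest-path distance ≤ 2 in an undirected graph), ranking candidates by
connections into the current node set (ties by summed score, then name)
and truncating at `max_added` (default 50 per expansion, a desk-scale cap).

MCL runs on the weighted adjacency (weights = score/1000; weighted chosen
as information-preserving) with per-node self-loops at the maximum incident
weight, column normalization, and alternating expansion (matrix squaring)
and inflation (elementwise power 2.0, renormalize) with pruning at 1e-5,
until the matrix moves less than 1e-6 or 100 iterations (then a warning
flag). Clusters are read from the attractor structure; nodes joining
several attractor systems go to the cluster holding the larger column mass,
ties to the lexicographically first. The procedure is deterministic.

# Co-expression networks

Genes are filtered to the top `top_n` by median absolute deviation
(`top_n = 5000` default; the filter size is a package choice). The
signed-hybrid adjacency is $a_{ij} = \mathrm{cor}_{ij}^\beta$ for positive
correlations, 0 otherwise, with Pearson or Spearman correlation. The soft
power $\beta$ is either user-fixed or the smallest integer in 1..20 whose
scale-free fit $R^2 \ge 0.8$ (log-log degree regression over 10 bins),
falling back to 6. On strongly modular synthetic data the scale-free
criterion can select extreme powers (the degree distribution of a planted
two-block network is not scale-free), which crushes the topological
overlap; the recovery experiments therefore fix $\beta = 6$.

TOM is $(\ell_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$ with
$\ell = A^2$ and unit diagonal. Modules come from average-linkage
clustering on $1 - \mathrm{TOM}$ with a deterministic height scan: cut
heights from 0.99 downward in steps of 0.01 until at least two clusters of
size ≥ `min_size` appear (first such height used); smaller clusters are
"grey". This replaces dynamic tree cutting with a reproducible rule; on
unstructured data no height qualifies (average-linkage splits of noise are
extremely unbalanced) and everything is grey. Eigengenes are the unit-norm
first principal component of the z-scored member expression, signed to
correlate positively with the module mean (for perfectly balanced
anti-correlated modules the mean is flat and the largest-loading gene
anchors the sign). Module-trait statistics report Pearson and Spearman
correlations against one-hot trait indicators (per-level indicators; an
ordinal coding is not meaningful for mutation categories) with BH over the
module-by-trait grid per method, plus a per-module group F-test on the
eigengene.

# Pathway activity

Two scorers over the batch-corrected matrix: `ulm` regresses the sample's
z-scored expression on the pathway weight vector (zero weights for
non-members) and reports the slope t-statistic — affine-invariant per
sample; `wsum` is the weighted sum of member expression z-scored against
gene-label permutations (closed-form permutation moments are verified in
the tests). The published footprint weight matrix is not shipped; the
package defines the long TSV format and the generator emits toy weights, so
real weights drop in unchanged. The per-pathway association model is
ordinary least squares — "generalized linear model" in the Gaussian
identity-link sense, appropriate for continuous scores — on
`mutation + gender + reprogramming + place` with treatment coding and BH
over the pathway-by-coefficient grid. Eigengene integration computes PC1 of
the module-eigengene matrix and Spearman correlations of PC1 and each
eigengene against each pathway's activity.

# Numerical and design choices

* Every stochastic operation takes an explicit integer seed; the pipeline
  derives per-stage seeds deterministically from the base seed (kept below
  $2^{31}$).
* Permutation p-values never return 0 (+1 convention).
* IRLS: initialization from the log-linear fit of $(y+0.5)/s$; mean capped
  to $[10^{-10}, 10^{12}]$; convergence at max |Δβ| < 1e-8 within 50
  iterations, non-convergence flags the gene (p = NA).
* PCA and eigengene signs follow a largest-|loading|-positive convention so
  outputs are reproducible across LAPACK implementations.
* Ties in candidate ranking (network expansion), cluster assignment (MCL)
  and ranked lists (GSEA) break lexicographically.
* The four study contrasts (PD vs healthy, LRRK2 vs healthy, Parkin vs
  healthy, LRRK2 vs Parkin) are fixed as the default contrast set.

# Problem sizes

The shipped test suite and the acceptance script run the pipeline at
reduced but non-trivial sizes chosen to exercise every code path with
stable statistics: 300-600 genes and the full 34-sample cohort for
pipeline-level checks, 200-300 genes for per-stage recovery (10-20 seeds),
60-node interactomes for clustering, and permutation counts of 99-999.
These sizes are the package's own defaults for its synthetic studies; all
scale up through the configuration.

# Limitations

* The DE recovery experiments draw data from the same NB family the test
  assumes; they validate implementation, not robustness to
  misspecification.
* The normal approximation in the marker panel and the absence of
  empirical-Bayes moderation in the dispersion estimator make small-sample
  inference less powerful than moderated pipelines.
* The VST stand-in under-stabilizes low counts relative to a
  dispersion-aware transform; exploratory geometry at very low depth will
  differ.
* Printed bookkeeping from the original cohort (refined signature sizes
  414/1644/220) is verified as arithmetic and data-model consistency; the
  gene lists themselves derive from deposited raw sequencing data and are
  not recomputable at desk scale.
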
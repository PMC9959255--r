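---
title: "Methods: differential co-expression analysis of a two-phenotype airway cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression analysis of a two-phenotype airway cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dcx` re-implements, as a tested and fully synthetic-data-driven pipeline,
the computational workflow of a two-phenotype airway-epithelium microarray
study: eosinophilic asthma (EA, at least 1% eosinophils in bronchoalveolar
lavage) versus non-eosinophilic asthma (NEA). This vignette is the
package's own account of the models it implements, the parameters that
matter, and the places where the design was genuinely open.

## 1. The synthetic-data world

No raw data accompanies the study design this package targets, so the
simulator in `simulate_expression()` is the canonical input source and the
ground it generates is the ground every test stands on.

**Expression model.** Data are generated directly on the log2 scale,

$$x_{gs} = \mu_g + \sigma\,\varepsilon_{gs},$$

with per-gene baselines $\mu_g \sim N(8, 1.5^2)$ and residual standard
deviation $\sigma = 0.7$ (the study's design value). Differentially
expressed genes add $\delta = 1$ (a fold change of 2) to the EA samples.
Genes in a planted co-expression module share a single latent factor per
condition:

$$\varepsilon_{gs} = \sqrt{\rho_c}\, F_s + \sqrt{1-\rho_c}\, e_{gs},$$

so every within-module gene pair has correlation exactly $\rho_c$ in
expectation — a closed form the calibration tests exploit. Defaults are
$n = 20$ samples per group, the design's sample size.

**Covariates.** Age is uniform on 20–70 years (the cohort's stated range),
BMI log-normal around 26 kg/m², sex and oral-corticosteroid use Bernoulli.
Covariate effects, when requested, enter linearly and identically for all
genes. These distributions are fixtures: nothing in the analyzed design
documents them, and nothing downstream depends on their exact shape.

**What the generator does not emulate.** Probe-level effects, batch
effects, two-dye ratios, heavy-tailed noise, and correlated differential
expression within modules. A green calibration test therefore establishes
correctness of the estimators under the factor-model world, not robustness
to every artifact of real scans.

**Array scans.** `simulate_array_scan()` renders 16-bit grayscale images:
Gaussian-profile spots (sd = spot radius / 2) at affine-displaced lattice
positions, four flat positioning markers (twice the spot radius, one-pixel
edge ramp) one pitch outside the grid corners, constant baseline (default
1000) plus optional Gaussian pixel noise, clipped to [0, 65535]. The clip
at zero means that at high noise the background mean sits above the
baseline; tests compare against the clipped-noise expectation, not the raw
baseline. Images round-trip losslessly through plain-text PGM (P2); no
binary image formats are read or written because no TIFF/PNG reader is
available in the supported environment.

## 2. Gridding by maximally stable extremal regions

Positioning markers are found as MSER blobs: connected components of the
thresholded image whose area changes slowly as the threshold sweeps.
Images are quantized to 256 levels (16-bit values divided by 257) so the
step parameter `delta` (default 2) has a fixed meaning. Stability at
level $t$ is $(A(t-\Delta) - A(t+\Delta))/A(t)$ along a branch of the
component tree; a branch is identified by its brightest pixel, the branch's
most stable level below `max_stability` (default 0.5) with area inside
[0.5&#960;r&#178;, 2&#960;r&#178;] is reported, and regions whose seed
pixel lies inside a more stable accepted region are collapsed away.
Centroids are intensity-weighted and sub-pixel. The test suite checks the
compiled detector against a brute-force component tree evaluated at every
integer level.

The grid affine is fit by least squares from marker anchors to detected
centroids. With at most eight candidate markers the correspondence is
chosen by exhaustive assignment minimizing the residual; a four-corner
marker layout is rotationally symmetric, so residual ties are broken
towards the affine closest to the identity — the physically correct choice
for a roughly upright scan. With more candidates, the eight most stable
are considered. Spot signal is disc-mean foreground minus annulus-median
background (annulus 1.5–2.5 spot radii); discs leaving the canvas are
flagged `clipped`, non-positive signals `low`. The manual verification
step of interactive gridding software is replaced by the QC summary of
`grid_scan()` plus an optional marker-override table. Sub-grid blocks with
independent affines are not implemented; one affine serves the whole
layout.

## 3. Preprocessing

The pipeline order is background correction, quantile normalization, CV
filtering — in that order, matching the order in which the original
workflow lists them. Background correction replaces non-positive signals
by a small floor (default 1); floor-substitution was chosen over
model-based alternatives (normexp) because it is transparent and exactly
testable. Quantile normalization replaces each column's order statistics
by their cross-column means; ties receive the mean of the reference
quantiles they span. The coefficient-of-variation filter keeps genes with
sd/mean between 0.3 and 10, computed on the *linear-intensity* scale —
on log data that band would be implausible. Note that with $n$
nonnegative observations the sample CV is bounded by $\sqrt{n-1}$, so the
upper bound of 10 only ever excludes genes in cohorts of more than ~100
arrays.

## 4. Differential expression and design-stage power

"ANCOVA" is realized as gene-wise ordinary least squares on intercept +
group indicator + covariates (age, sex, BMI, oral steroid use), which is
the standard equivalent; with no covariates it reduces exactly to the
pooled two-sample t-test. The group coefficient is the log2 fold change
(EA minus NEA), tested two-sided on the residual degrees of freedom, with
Benjamini–Hochberg step-up adjustment across genes. Genes whose residual
variance is numerically zero get p = 1 and a `zero-variance` flag.

`sample_size_efp()` interprets the "FDR-based" design calculation as
expected-false-positive control: the per-gene two-sided level is
$\alpha = \mathrm{E[FP]}/m$ and

$$n = \left\lceil \frac{2 (z_{1-\alpha/2} + z_{\beta})^2 \sigma^2}{\delta^2} \right\rceil$$

with normal quantiles and $\delta = \log_2(\text{fold})$. At $m = 14{,}823$,
fold 2, $\sigma = 0.7$, power 0.8, E[FP] = 4 this yields exactly 20 per
group, reproducing the published design; the original calculator's formula
is not documented, so this interpretation is recorded as such.

## 5. Differential co-expression

Genes are clustered in the EA condition (the condition in which the sought
groups are coherent; configurable) by average-linkage agglomeration on
$1 - r$ distance, tree cut at 0.6 (mean within-cluster correlation roughly
0.4 or more — the cut is not documented in the original workflow and is
exposed in `coex_params()`). Groups smaller than three genes are
discarded: three is the minimum for a t-statistic over pairwise
correlations.

Each group of size $k$ yields $k(k-1)/2$ pairwise Pearson correlations per
condition; coherence is the one-sample statistic
$t = \bar r / (s_r/\sqrt{n_\text{pairs}})$ on the plain r scale (a Fisher-z
option exists but is off by default, matching the cited methodology).
Significance comes from resampling: B (default 1000) random gene sets of
the same size drawn from the same condition's filtered pool, with the
add-one estimator $p = (1 + \#\{t_\text{null} \ge t_\text{obs}\})/(B+1)$,
one-sided because "non-random co-expression" means positive coherence.
A group is a differential co-expression group (DCG) when $p_{EA} < 0.05$
and $p_{NEA} \ge 0.05$, and groups are ranked by the mean pairwise
correlation difference $\overline{\Delta r} = \mathrm{mean}(r_{EA} - r_{NEA})$.

**Known limitation (measured by the acceptance suite).** Because groups
are *selected* by clustering in EA, the resampling p-value in EA is
anti-conservative for them by construction — that is the method's design,
shared with the original. A consequence the tests document honestly: in a
pool of ~500 null genes at $n = 20$ per group (null correlations have
sd $\approx 0.23$), clustering reliably finds a few chance triples with
mean within-group correlation near 0.75. These outrank a genuinely planted
30-gene module whose true correlation difference is 0.7, because the
unweighted pair-mean $\overline{\Delta r}$ does not reward group size. The
planted module is recovered as a DCG with Jaccard ≥ 0.8 in ≥ 95% of seeds,
but it is essentially never rank 1; the corresponding acceptance test is
left failing rather than re-tuned, and users ranking real groups should
weigh group size alongside $\overline{\Delta r}$.

The type-I error of the DCG rule itself is nominal: for *externally
specified* (non-selected) gene sets on null data the flagged fraction is
$\alpha(1-\alpha) \approx 0.0475$, verified by the acceptance suite via
`evaluate_groups()`.

## 6. Networks, attack, enrichment

Graphs load from TSV/SIF edge lists with optional node types (gene, TF,
miRNA, protein), are simplified (self-loops dropped, multi-edges
collapsed) and treated as undirected for centrality by default. Exact
betweenness comes from igraph's Brandes implementation and is verified in
the tests against exhaustive shortest-path enumeration. The topological
attack removes the top node per strategy (betweenness, degree, or a given
order; ties lexicographic), optionally recomputing centrality after every
removal, and records the largest-component trajectory.
`rank_understudied()` scores nodes by centrality rank percentile minus
literature-count rank percentile, marking highly connected but sparsely
studied regulators. Web-based enrichment services are out of scope;
`ora_enrichment()` provides the local equivalent — an upper-tail
hypergeometric test against user-supplied GMT collections with BH
adjustment.

## 7. Clinical statistics

`compare_groups()` gates on Shapiro–Wilk normality in each group at 0.05:
non-normal variables go to a Mann–Whitney U test (normal approximation,
tie-corrected, no continuity correction) with median (IQR) summaries,
normal ones to a pooled-variance t-test with mean ± SD. Categorical
variables use Pearson's chi-squared without continuity correction (the
corrected variant is a flag away; neither variant is privileged by the
source material). The biomarker cut-off is the probability-0.5 point
$-\beta_0/\beta_1$ of a univariate logistic fit (IRLS, tolerance 1e-8, at
most 100 iterations); under complete separation the midpoint of the
closest opposing-class values is returned with a flag, and a Youden-index
alternative on the empirical ROC is available because the original
criterion is unstated. Membrane-thickness measurement sets are summarized
by the harmonic mean, with a warning below the conventional 30
measurements.

## 8. Numerical and reproducibility choices

* Every stochastic stage takes an integer seed; simulators restore the
  caller's RNG state. Identical configuration and seed give bitwise
  identical outputs, including the pipeline's output tables.
* Zero-spread correlation sets map to ±Inf/0 sentinels rather than NaN;
  the add-one resampling estimator keeps p-values strictly positive.
* Degenerate designs (covariate confounded with group) error out naming
  the offending column rather than silently dropping it.
* TSV is the canonical tabular format (gene ids may contain commas); JSON
  carries configuration, grid geometry and the run manifest (no YAML
  parser is assumed). Checksums in the manifest use MD5 from base R's
  tools.
* Expression values are assumed log2 in the statistical layers; the
  intensity-scale path (`as_intensity()`) exists for preprocessing. The
  magnitude of published fold changes is consistent with log2 data, and
  that convention is adopted throughout.
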
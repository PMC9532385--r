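---
title: "Mapping consistent functional connectome hubs by harmonized meta-analysis"
author: "metaHub package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping consistent functional connectome hubs by harmonized meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaHub)
```

## The problem

Voxelwise functional connectome studies disagree about where the brain's
most densely connected regions — its hubs — are located. Much of the
disagreement traces to small samples and to heterogeneity between sites,
scanners and protocols. The remedy implemented here treats each cohort as
one study in a meta-analysis: every subject contributes a normalized
functional connectivity strength (FCS) map, every cohort contributes a
covariate-adjusted mean map and a variance map, and cohorts are pooled
with a random-effects model that explicitly carries a between-cohort
variance component. Inference is nonparametric, via a max-statistic
permutation scheme that controls the family-wise error rate (FWER) over
all gray-matter voxels, followed by a cluster-extent rule.

Downstream of hub identification the package quantifies reproducibility
(leave-one-cohort-out, hub-occurrence probability, subsampling curves),
characterizes each hub's seed-based connectivity profile and clusters
those profiles, and relates hub topography to gene expression with a
balanced gradient-boosting/SVM protocol whose spatial inference rests on
autocorrelation-preserving surrogate maps.

## The model, stage by stage

### Subject-level FCS

For one subject with time series at every gray voxel, the connectome is
the voxel-by-voxel Pearson correlation matrix. FCS of voxel $v$ is the
sum of connection weights

$$\mathrm{FCS}(v) = \sum_{u \ne v} r(v,u)\,
  \mathbf{1}\{r \ge r_0\}\,\mathbf{1}\{r > 0\}\,\mathbf{1}\{d(v,u) > d_0\},$$

with $r_0 = 0.1$ (the boundary value is kept; values below it are
zeroed), negative correlations excluded as neurobiologically ambiguous,
and center-to-center distances $d \le d_0 = 20$ mm removed to avoid
locally shared signal. Whether the 20-mm rule is strict at exactly 20 mm
is not fixed by convention; we exclude pairs at distance $\le 20$ mm (a
literal reading of "terminating within") and expose the cutoff as a
parameter. Each FCS map is normalized to mean 0, SD 1 across gray
voxels. We fix the population SD convention (divide by $n$) so that the
normalization is exactly idempotent and unit tests can assert equality
rather than approximation; with 47k voxels the two conventions differ
by parts in $10^5$.

### Cohort summaries

Per cohort, a voxelwise general linear model removes age and sex
effects:

$$\mathrm{FCS}_i = \beta_0 + \beta_{Age}(Age_i - \overline{Age}) +
  \beta_{Sex}\,Sex_i + \varepsilon_i .$$

Age is centered at the cohort mean. Sex is coded $\pm 0.5$ and also
centered, so $\beta_0$ is literally the covariate-adjusted mean FCS of
the cohort — the quantity the meta-analysis pools. The exported variance
map is the unbiased residual variance (denominator $N - p$, with $p$ the
number of retained design columns), the standard estimator whose
$SD_i^2/N_i$ is the squared standard error of the cohort mean. A
constant covariate column (for example a single-sex cohort) is dropped
with a warning rather than failing the fit. Note one consequence of
centering sex at the cohort mean: the pooled mean estimates the cohort
average at the cohort's own sex composition, so a nonzero sex contrast
shifts all cohort means by $\beta_{Sex}\cdot\overline{Sex}$; recovery
simulations that compare against a generating mean therefore switch the
covariate effects off.

### Random-effects pooling (DerSimonian–Laird)

Per voxel, with cohort means $M_i$, residual variances $SD_i^2$ and
sizes $N_i$:

$$W_i = N_i / SD_i^2, \qquad
  Q = \sum W_i M_i^2 - \frac{(\sum W_i M_i)^2}{\sum W_i}, \qquad
  df = k - 1,$$

$$T^2 = \max\!\left(0,\; \frac{Q - df}
  {\sum W_i - \sum W_i^2 / \sum W_i}\right), \qquad
  I^2 = \max\!\left(0, \frac{Q - df}{Q}\right)\times 100,$$

$$W_i^* = \frac{1}{SD_i^2/N_i + T^2}, \qquad
  M^* = \frac{\sum W_i^* M_i}{\sum W_i^*}, \qquad
  SE = \Big(\sum W_i^*\Big)^{-1/2}.$$

$T^2$ and $I^2$ are floored at zero when $Q < df$ (the universal
truncation; $I^2$ is defined as 0 when $Q = 0$). The standardized effect
is $Z = M^*/SE$ — the pooled normalized FCS compared against the global
mean of zero — and the effect size is Cohen's $d = Z/\sqrt{k}$. The
whole engine is vectorized across voxels; a voxel with a non-positive
cohort variance becomes NaN with a warning instead of poisoning the map.
The test suite cross-checks every statistic against an independent
implementation (metafor's DL estimator) to $10^{-10}$.

### Permutation FWER control and hub thresholding

Each permutation iteration draws an independent random voxel permutation
per cohort and applies it jointly to that cohort's mean and variance
maps — cohorts are spatially decoupled from one another while each
cohort's mean/variance pairing is preserved — then recomputes the
meta-analysis and records the map-wide maximum $Z$. We permute each
cohort independently (rather than one shared permutation) because the
procedure randomizes the correspondence *among* cohorts' maps. One-sided
p values use the add-one convention, $p = (1 + \#\{\max Z \ge
Z\})/(n_{perm}+1)$, so no p value is ever zero; ties in $Z$ share a p
value. Hubs are voxels with $p < 0.001$ in 26-connected clusters larger
than 200 mm$^3$ (both thresholds configurable; 26-connectivity is the
common volumetric convention, and the extent rule is strict "greater
than"). Within each cluster, peaks are local maxima (strictly greater
than all in-mask 26-neighbors) kept greedily in descending $Z$ order at
a minimum separation of 15 mm; equal-$Z$ ties are broken by lowest voxel
index purely for determinism. The add-one floor implies that $\alpha$
must exceed $1/(n_{perm}+1)$ to be attainable — with 999 permutations
the smallest possible p is 0.001, so reduced test runs pair a reduced
permutation count with a correspondingly attainable $\alpha$.

### Reproducibility analyses

Leave-one-cohort-out reruns the entire identification on each $k-1$
subset and reports Dice overlap with the all-cohort mask plus, per
all-cohort peak, the displacement to the nearest reduced-set peak
(nearest-match, no one-to-one constraint). Hub-occurrence probability
(HOP) calls the top-$N$ voxels of each unit (subject or cohort) that
unit's hubs and reports per voxel the fraction of units containing it;
subsampling curves draw random unit subsets of increasing size and trace
mean ± SD of the Dice between the subset's top-$N$ HOP mask and a
reference. Top-$N$ ties are broken by voxel index with a logged warning
— continuous FCS makes ties measure-zero, but fixtures may tie.

### Seed profiles and clustering

Each hub seed is a 6-mm sphere (voxels whose centers lie within the
radius, inclusive); the seed series is the mean over its gray voxels,
correlated with every voxel and Fisher-transformed, $z = \mathrm{arctanh}(r)$
with $|r|$ capped at $1 - 10^{-7}$ to avoid infinities. The z maps then
flow through the identical GLM → pooling → permutation chain — the seed
stage literally reuses those modules, and a composition test asserts
equality with the manual chain. Connectivity profiles divide the
significant map by the eight network labels as percentages of each
network's size (removing the effect of network size), and profiles are
clustered agglomeratively with Euclidean distance and single linkage —
the documented defaults of the classic MATLAB `linkage` routine the
field used — both configurable.

### Surrogate maps and spatially honest tests

Testing whether hub regions differ in some spatial quantity cannot rely
on naive permutation: spatial autocorrelation makes exchanges across
space far too liberal. The package builds surrogate maps that keep the
source map's value multiset exactly and its spatial autocorrelation
approximately: permute the source values (twice, independently); smooth
each permuted field with Gaussian kernels over the `knn = 100` nearest
neighbors at a grid of bandwidths (fractions of the maximum pairwise
distance); for each bandwidth pair fit non-negative scale coefficients
and a nugget by least squares so the candidate's binned variogram (25
equal-width bins up to the 25th distance percentile — only short-range
autocorrelation is matchable or relevant) tracks the source's; rank-
reassign the source's values onto each candidate and keep the candidate
whose finished variogram deviates least from the source's. Two details
matter numerically: a negative fitted nugget must be clamped to zero
with the scale refit (injecting $\sqrt{|a|}$ noise for $a<0$ adds
exactly the roughness the fit says to remove), and a two-scale mixture
is needed because a single smoothing kernel family cannot span the
variogram shapes of realized fields. Rank-sum tests then recompute their
statistic under hub labelings taken from the top-$|hub|$ locations of
each surrogate, and spatial correlations are referred to correlations
with surrogates of one map; both use the add-one p convention, with
optional Bonferroni multiplication for test families.

### Transcriptomic association

Expression samples are labeled hub/non-hub by their nearest voxel
(outside the gray mask: excluded). The balanced protocol trains a
gradient-boosted tree classifier (binary logistic loss, learning rate
0.05, up to 1500 rounds with the round count chosen by 30-fold
cross-validation and early stopping after 50 stalled rounds) on 300
randomly drawn samples per class and evaluates sensitivity, specificity
and accuracy on all held-out samples, repeating the draw 1000 times.
Balanced training keeps the classifier unbiased toward either class, so
chance level is 50% even though the held-out set is imbalanced. Every
count is a parameter, so tests and the acceptance script run reduced
versions — the chance-level property in particular does not depend on
the round search. Per-gene contribution is gain-based importance
averaged over repetitions (reported on a log scale downstream; gain is
the conventional default, the original work does not name its metric),
and each sample's held-out correct-classification rate is accumulated to
define the "easiest" (highest-rate) and "hardest" (lowest-rate) non-hub
subsets for the SVM stage: a radial-basis support-vector classifier with
unit cost on the top-$N$ genes by contribution, features standardized
per gene (SVM defaults are scale-sensitive, so the standardization is
explicit), scored by cross-validation across $N$.

Gene-set scores are the first principal component of the samples ×
set-genes submatrix, sign-aligned to correlate positively with the
set's mean expression and min-max scaled to [0, 1]; developmental
trajectories smooth those scores against $\log_2$(post-conceptional
days) with loess. We use locally *quadratic* loess (degree 2): a locally
linear smoother flattens curved developmental trends, and the package's
own accuracy fixture (a noiseless quadratic) is recovered to within 2%
RMSE only with the quadratic local model. Trajectory differences are
compared against the per-age median absolute deviation (raw MAD, no
consistency constant) of the score across brain regions; ages where the
difference exceeds the MAD are flagged. Parcels (e.g. Brodmann areas)
count as hub regions when strictly more than 50% of their locations fall
in the hub mask.

## The synthetic-data module

The generator produces exactly the statistical structure the pipeline
assumes, with known ground truth:

* **Cohort maps** — subject map = true mean map + cohort effect
  $u_c \sim N(0, \tau^2)$ (i.i.d. per voxel by default; an optional
  spatially smoothed variant exists for realism) + $\beta_{Age}(Age -
  \overline{Age}) + \beta_{Sex} Sex$ + subject noise
  $N(0, \sigma^2_w)$. Ages are uniform on [18, 36] years and sexes
  Bernoulli(0.5), mirroring a healthy-young-adult inclusion window.
  Defaults $\tau^2 = 0.04$ and $\sigma_w = 1$: maps are on the
  normalized (z) FCS scale, so unit subject SD is the natural choice,
  and $\tau^2 = 0.04$ puts typical cohort-level $I^2$ in the
  moderate-to-high range seen in multi-site data. The Gaussian form of
  $u_c$ is our choice; the random-effects framework itself does not
  prescribe a distribution.
* **Planted hubs** are contiguous spheres (so the cluster-extent rule is
  exercised meaningfully) with a mild interior ramp (rim amplitude
  $\times$ 1 up to center $\times$ 1.2) giving each blob a unique peak
  while all hub voxels keep at least the nominal amplitude. With rim
  amplitude $a$, the true effect size is $d \approx a/\sqrt{\tau^2 +
  \sigma_w^2/N}$.
* **Time-series cohorts** draw stationary Gaussian series under a block
  correlation structure (planted high-degree voxels) for the connectome
  stage.
* **Expression matrices** place samples at gray-voxel centers;
  informative genes mimic a co-expressed gene set: each is
  $\sqrt{w}\,L + \sqrt{1-w}\,\varepsilon_j + e\cdot\mathbf{1}[hub]$
  with one shared spatially smoothed latent field $L$ (default scale
  15 mm), gene-specific noise, and a standardized shift $e$ in hub
  samples; uninformative genes are i.i.d. noise. The shared-factor
  share defaults to $w = 0.2$, which together with the label-driven
  component realizes pairwise co-expression correlations near 0.35 at
  $e = 1$ — typical of a co-regulated module. The shared factor is what
  keeps the set's pooled discriminability bounded at $e/\sqrt{w}$
  (fully independent informative genes would drive any classifier to a
  100% ceiling and make classifier comparisons degenerate), and it is
  also why autocorrelation-matched surrogate labelings are genuinely
  uninformative rather than partially learnable.

What the generator does *not* emulate: scanner artifacts, head motion,
hemodynamics, spatially structured subject noise, non-Gaussian
expression distributions, or donor structure in expression data. Tests
passing on this generator therefore certify the statistical machinery —
estimator correctness, FWER calibration, recovery at planted effect
sizes, null behavior of the classifiers — not robustness to acquisition
artifacts, which the upstream preprocessing of real data must handle.

## Numerical choices and degenerate inputs

* Permutation p values: add-one correction; p is never 0; attainable
  $\alpha$ is bounded below by $1/(n_{perm}+1)$.
* DL truncation at $Q < df$; $I^2 = 0$ when $Q = 0$. Under true
  homogeneity roughly half of all voxels sit at the $T^2 = 0$ floor and
  fewer than 5% show $I^2 > 50$ — the sensible homogeneity contrast,
  since $I^2$ is exactly zero only where $Q \le df$.
* Zero-variance voxels in FCS get their connections zeroed with a
  warning; constant maps refuse normalization; empty seed spheres,
  empty groups and rank-deficient designs raise errors.
* Fisher z caps $|r|$ at $1 - 10^{-7}$.
* Cluster labels are ordered by decreasing size (ties by first voxel
  index); peak ties by lowest voxel index; top-$N$ ties by voxel index
  with a warning. All tie rules exist for reproducibility, not science.
* All random stages take explicit integer seeds and draw through an
  isolated RNG scope, so identical seeds give bit-identical outputs
  without disturbing the caller's RNG state.

## Problem sizes used in tests

The suite exercises the full pipeline at sizes a laptop handles in
minutes, chosen so the Monte-Carlo tolerances stated in each test are
meaningful: FWER calibration uses 200 replicates of 12 cohorts × 20
subjects on a 2000-voxel grid with 500 permutations; planted-hub
recovery uses a 2744-voxel grid with three planted hubs at rim effect
size $d \approx 3$; surrogate fidelity averages 30 surrogates over four
source fields of 500 lattice-spaced locations; the classification
checks use 382 + 776 samples with 500 genes (chance level) or 2000
genes of which 150 informative (key-gene recovery; random 150-gene
draws are then key-gene-poor, as draws from a 10k-gene transcriptome
are) with reduced repetition counts. The variogram fixture places locations on a 12-mm lattice
because real cortical expression samples are themselves coarsely and
near-regularly spaced; uniformly random coordinates would create
sub-voxel distance bins whose tiny pair counts make *relative* variogram
error unbounded for any generator.

## Known limitations

* The DL estimator is moment-based: $T^2$ carries a small upward bias
  when within-cohort variances are estimated from few subjects, visible
  in the recovery test at $N = 20$ and negligible by $N = 25$.
* With very few cohorts and identical (duplicated) cohort maps, the
  permutation null is anti-conservative and noise Z values are
  heavy-tailed — a pathology of duplication, not of real multi-cohort
  data; the exchangeability fixtures therefore construct identical
  cohort summaries directly.
* Surrogate variogram fidelity is fundamentally limited at lags shorter
  than the typical nearest-neighbor distance and for source realizations
  whose empirical variograms wiggle around their population shape.
* The transcriptomic protocol assumes complete expression matrices; no
  imputation is provided.
* Volumes only (NIfTI-1); no surface formats; no rsfMRI preprocessing —
  inputs are assumed preprocessed or simulated.
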
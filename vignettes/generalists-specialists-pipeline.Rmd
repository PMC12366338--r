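---
title: "Niche breadth, assembly processes, and co-occurrence structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche breadth, assembly processes, and co-occurrence structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheassembly)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, the null hypotheses behind each permutation scheme,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the methodological literature leaves the design open.

## The analysis in one paragraph

Given a sample × OTU count table from a spatial survey (the package's
defaults assume a 120-quadrat grid at 20 m spacing, but nothing depends on
that), the pipeline (i) classifies OTUs into habitat generalists,
specialists, and neutral taxa by comparing Levins niche breadth with a
marginal-preserving permutation null; (ii) asks whether community turnover
between samples is governed by deterministic selection or stochastic
processes, using phylogenetic (βNTI) and taxonomic (RC-Bray) null models,
the Sloan neutral community model, and the checkerboard C-score; (iii)
summarizes co-occurrence structure as a thresholded correlation network
with modules and Zi–Pi node roles; and (iv) relates richness to light,
plant, topographic, and spatial (PCNM) covariate blocks with a PLS path
model. All stages consume one canonical normalization: relative abundances
are always recomputed from counts, never stored.

## Niche breadth and the classification null

Levins niche breadth for OTU $j$ over $N$ samples is
$B_j = 1 / \sum_{i=1}^{N} P_{ij}^2$ with $P_{ij}$ the fraction of OTU
$j$'s reads found in sample $i$ ($\sum_i P_{ij} = 1$). $B_j$ runs from 1
(all reads in one sample) to $N$ (perfectly even spread) and is invariant
to rescaling an OTU's counts. The per-OTU normalization is deliberate: a
within-sample normalization would break the $B \le N$ bound on which the
classification depends. It remains available
(`levins_niche_breadth(..., normalization = "sample")`) for comparison.

The null model is the *quasiswap count* randomization: null tables with
exactly the observed row sums (sample depths), column sums (OTU totals),
and matrix fill, generated by an `r2dtable`-style fill followed by
marginal-preserving 2×2 updates (via `vegan`'s `quasiswap_count`; draws
are independent re-randomizations, so no serial correlation between null
tables). An OTU whose observed breadth exceeds the 97.5% quantile of its
own null-breadth distribution is a generalist; below the 2.5% quantile, a
specialist; otherwise neutral. Quantiles are empirical (type 7); ties at a
boundary resolve to neutral, the conservative direction. Classifying on
occupied-sample counts instead of breadth is supported
(`measure = "occurrence"`); breadth is the default because breadth is the
quantity whose null distribution the permutations generate. Defaults:
`n_perm = 1000`, `alpha = 0.05`; a warning fires when `n_perm < 2/alpha`,
where the requested tail quantiles are not resolvable.

An important property of this null, visible in the package's own tests: a
table drawn *from* the null classifies almost entirely neutral, but a
generalist is only detectable if its across-sample evenness exceeds what
random placement of the same number of reads would produce. Multinomial
sampling noise is exactly the null's noise, so "evenly distributed on
average" is not enough — real detected generalists are taxa whose local
populations are buffered below sampling variance. The synthetic generator
plants its generalists accordingly (below).

## Assembly processes

**βMNTD/βNTI.** For samples $k, l$ the abundance-weighted between-community
mean nearest taxon distance is
$\tfrac12\big[\sum_j f_{jk}\min_{j'\in l} d(j,j') + \sum_j f_{jl}\min_{j'\in k} d(j,j')\big]$
with $f$ relative abundances and $d$ patristic distances. The null
shuffles the taxa across the tips of the phylogeny (999 randomizations by
default, the conventional count; abundance weighting is the default
because count data are available), and
$\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{obs} - \mu_{null})/\sigma_{null}$.
$|\beta\mathrm{NTI}| > 2$ is read as deterministic selection. The
nearest-taxon minimum-distance kernel is implemented in C++ (`src/`);
patristic distances are computed once and each null is a permutation of
their indices, so 999 nulls over all $\binom{n}{2}$ pairs stay tractable.
Degenerate nulls (a star tree makes every tip shuffle identical) yield
`NA` with a warning rather than a spurious z-score.

**RC-Bray.** For each sample pair, null communities preserve each sample's
richness and read depth; species enter with probability proportional to
their occurrence frequency, receive one read each, and the remaining reads
are assigned multinomially by total relative abundance. Bray–Curtis is
computed for each of the `n_null` null pairs and the observed value's
position is rescaled to $[-1, 1]$. One null stack is drawn per sample and
compared across pairs (draws are independent across samples, so each
pair's null distribution is the intended one); the pairwise comparison
loop is C++.

**Process partition.** βNTI > +2 → heterogeneous selection; < −2 →
homogeneous selection; otherwise RC > +0.95 → dispersal limitation,
RC < −0.95 → homogenizing dispersal, else drift. Fractions are reported
over pairs with defined βNTI (excluded pairs are counted), sum to 1 by
construction, and the deterministic fraction is weakly decreasing in the
βNTI cutoff. Subcommunity runs (generalists / specialists / neutral) use
the subset table re-normalized within the subset and, by default, the tree
pruned to the subset's OTUs (`subcommunity_tree = "full"` keeps the whole
tree).

**Sloan neutral community model.** The model predicts an OTU's occurrence
frequency from its mean relative abundance $p$:
$f_{pred}(p) = 1 - I_d(Nmp,\, Nm(1-p))$, the upper regularized incomplete
Beta at detection limit $d$, with $N$ the mean read depth and $m$ the
migration rate, estimated by nonlinear least squares
(`minpack.lm::nlsLM`, log-spaced grid start; non-convergence reports the
SSE profile over that grid). $R^2 = 1 - SSE/SST$ may be negative on
strongly non-neutral data. The default detection limit is
$d = \ln 2 / N$ rather than $1/N$: under multinomial sampling an OTU at
true relative abundance $a$ is detected with probability
$1-(1-a)^N$, and $\ln 2/N$ is where that probability crosses one half —
the effective hard threshold of count data. The package's own generator
makes the consequence measurable: with $d = 1/N$ migration-rate recovery
on Sloan-generated tables is biased upward by 20–40% across
$m \in \{0.05, 0.1, 0.5\}$, while $d = \ln 2/N$ recovers $m$ to within a
few percent (−13% at the worst case $m = 0.5$). $d$ remains a parameter
for users who prefer the classical convention. The 95% envelope uses
Wilson score intervals around $f_{pred}$ with $n$ = number of samples.

**C-score.** Mean checkerboard units
$CU_{ij} = (r_i - S_{ij})(r_j - S_{ij})$ over OTU pairs of the binarized
table; the null is the sequential checkerboard swap (fixed row and column
totals) with a 30,000-swap burn-in and 1,000-swap thinning — values not
fixed by the methodological literature, chosen long relative to the
mixing time of the matrices in scope and exposed as parameters.
SES = (obs − mean)/sd of the retained null matrices; positive SES =
segregation. The implementation is verified in the tests against
exhaustive enumeration of all 512 binary 3×3 matrices.

## Co-occurrence networks

No single construction recipe is canonical in the literature, so the
defaults follow the dominant convention in microbial network studies and
are all parameters: Spearman correlations on relative abundances among
OTUs present in ≥ 20% of samples, two-sided p from the t approximation,
Benjamini–Hochberg correction over all tested pairs, and edges where
$|\rho| \ge 0.6$ and adjusted $p \le 0.05$. Topology reports node/edge
counts, average degree $2E/N$, unweighted average shortest path length on
the largest connected component (disconnected pairs are otherwise
undefined), mean local clustering with degree-<2 nodes contributing 0, and
the positive-edge ratio. Modules come from seeded Louvain maximization on
absolute edge weights (correlation sign is ignored for partitioning);
module ids are relabelled by decreasing size so partitions are stable
across runs. Node roles use within-module degree z-scores $Z_i$ and
among-module connectivity $P_i = 1 - \sum_m (k_{im}/k_i)^2$ with the
standard thresholds 2.5 and 0.62; non-peripheral nodes are reported as
keystone candidates. Singleton modules get $Z_i = 0$ with a warning.

## Space and environment

**PCNM.** Spatial eigenvectors come from `vegan::pcnm` (truncated
Euclidean distances, distances beyond the threshold replaced by 4× the
threshold, Gower double-centring, positive-eigenvalue axes kept), with the
axes additionally scaled by the square root of their eigenvalues. The
default truncation is the longest minimum-spanning-tree edge — the
smallest value that keeps the neighbour graph connected; on a regular
grid it equals the grid spacing.

**Forward selection** is guarded twice, following the established
practice for spatial eigenvector sets (which are numerous enough to fit
noise): selection starts only if the full-candidate model passes a global
permutation test of its $R^2$; each greedy step then requires the best
candidate's $R^2$ gain to beat `alpha` under response permutation, and
selection stops once the selected model's adjusted $R^2$ reaches the
full-candidate model's adjusted $R^2$ (the crossing axis is kept — on
near-noiseless data the penalized full model is the *lower* adjusted
$R^2$, and rejecting the crossing axis would discard a planted signal the
procedure has already detected). Ties between candidates break by column
index, so the result does not depend on candidate order. Because PCNM
axes are orthogonal, each axis's marginal $R^2$ is its partial $R^2$, and
the implementation exploits this.

**PLS path model.** Blocks of indicators (default: spatial = two PCNM
axes; light = CC, SR, LT; plant = BA, DEN; topography = ASP; response =
richness) measure latent variables reflectively (mode A). The Lohmöller
iteration alternates inner estimation (path scheme by default: regression
coefficients on predecessors, correlations with successors; centroid
scheme available) with outer weight updates until the largest weight
change drops below `tol = 1e-6`; sign indeterminacy is resolved by
aligning each latent with its indicators. Path coefficients are OLS of
each endogenous latent on its predecessors; total effects are
$(I-B)^{-1} - I$, so total = direct + indirect holds to machine
precision; $GoF = \sqrt{\overline{communality} \times \overline{R^2}}$.
The default inner graph lets the spatial and topographic blocks act on
richness both directly and through light and plant — a DAG, so effect
decomposition is unambiguous. Bootstrap percentile intervals
(`n_boot`, seeded) are available for path coefficients; no covariance-based
SEM fit indices are computed, and mode B (formative) measurement is out of
scope. In the degenerate single-indicator case the model collapses, as it
should, to the Pearson correlation.

## The synthetic-data generator

`simulate_structured_table()` emulates the *inferential situation* of a
gridded soil survey, not its biology:

- A latent environmental gradient is a Gaussian random field with
  exponential covariance (default range 60 m on the 240 × 180 m default
  grid), standardized to unit variance. Environmental covariate blocks
  (light: CC, SR, LT; plant: BA, DEN; topography: ASP) are independent
  fields of the same construction.
- **Specialists** get Gaussian kernels
  $\exp(-(g - o_j)^2 / 2\sigma^2)$ on the gradient. The default
  $\sigma = 0.10$ was set once so that specialists occupy roughly 10–20%
  of samples (median occupancy 0.13–0.17 across seeds at the default
  design); optima are type-1 quantiles of the realized gradient, so a
  point kernel ($\sigma = 0$) always matches at least one quadrat, and an
  off-grid optimum under a point kernel leaves an all-zero OTU that is
  flagged `extinct` in the ground truth rather than silently dropped.
- **Generalists** hold a constant expected share in every sample with
  multiplicative lognormal noise of CV 0.05 — *below* multinomial
  sampling variance. This buffering is what makes them detectable at all:
  a generalist planted as plain multinomial draws is statistically
  indistinguishable from the marginal-preserving null (detection
  probability ≈ α), because the null's noise *is* multinomial noise.
- **Background taxa** (the remainder) get wide kernels
  ($\sigma = 1.2$) and a long-tailed lognormal(0, 2) abundance
  distribution. All filtered taxa additionally receive per-cell lognormal
  overdispersion (sdlog 0.8), the dominant noise feature of real amplicon
  counts; without it the null's fill constraint (observed zeros
  concentrated in specialists) pushes a large share of background taxa
  over the generalist boundary.
- Class read-share budgets are 20/40/40% (generalist/specialist/
  background); per-sample counts are completed multinomially so every row
  sums exactly to `community_size` (default 10⁴ reads — survey read
  depths are study choices, so this is a parameter).

`simulate_neutral_table()` draws local relative abundances from the Beta
stationary distribution $\mathrm{Beta}(Nmp, Nm(1-p))$ — exactly the model
`fit_sloan_ncm()` assumes — rather than forward-time neutral dynamics;
that makes migration-rate recovery a clean self-consistency check rather
than a test of two different approximations against each other.
`simulate_phylogeny()` grows a Yule tree and evolves optima by Brownian
motion; `signal_strength` blends the Brownian values with a shuffle of
themselves, so 0 gives optima independent of the tree with an unchanged
marginal distribution — the right null for checking that βNTI flags ~5%
of pairs when no phylogenetic signal exists.

What the generator does **not** emulate: read-level error (no FASTQ,
chimeras, or OTU-picking artifacts), compositional coupling beyond the
multinomial constraint, taxon–taxon interactions (network modules in
synthetic data arise from shared environmental filtering only), temporal
dynamics, and unequal sequencing depth. Passing tests on these communities
therefore demonstrates statistical correctness and calibration of the
methods, not that any particular field system behaves this way.

## Determinism and problem sizes

All randomness flows from integer seeds; the pipeline derives each
stage's seed from the master seed and the stage name, so stages can be
re-run in isolation and a full re-run is byte-identical (asserted in the
test suite by comparing all written outputs of two runs). The test suite
exercises the full default design (120 samples × 1000 OTUs, 1000
permutations) for classification recovery, and a 24-sample, 200-OTU
fixture with 999 tip shuffles for βNTI calibration; the acceptance script
runs βNTI/RC-Bray on a 40-sample spatial subsample with 299 nulls and the
C-score on prevalence-filtered OTUs with 199 sequential-swap matrices —
sizes chosen to keep the full recomputation proportionate while leaving
every statistical property intact.

## Known limitations

- Quasiswap classification power depends on read depth and evenness
  structure; at shallow depth rare specialists collapse into the neutral
  band (their null is already patchy).
- RC-Bray null stacks are held in memory (`n_otus × n_null` integers per
  sample); for very large designs, subsample or lower `n_null`.
- The PLS path model requires complete indicator rows (incomplete rows are
  dropped with a warning) and standardizes internally; coefficients are on
  the correlation scale.
- Spearman networks are not compositionally aware (no SparCC/SPIEC-EASI);
  with strong compositional closure, negative-edge ratios should be
  interpreted cautiously.
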
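---
title: "Models and methods behind SpatialCCIsim"
author: "SpatialCCIsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind SpatialCCIsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpatialCCIsim)
```

# Overview

SpatialCCIsim simulates spatially resolved transcriptomics (SRT) data in
two stages. Stage 1 produces a spatial map: typed cells with coordinates
inside a window, possibly partitioned into regions, and possibly shaped by
cell-cell colocalization (attraction or inhibition between cell types).
Stage 2 produces a gene x cell count matrix for those cells: per-cell-type
zero-inflated negative binomial (ZINB) marginals coupled by a Gaussian
copula, then perturbed by cell-cell interaction (CCI) effects — spatial
dependence of gene expression and gene-gene interactions between
neighboring cells — and by regional differential expression. Every applied
effect is recorded, so the simulated data carry a complete ground truth
for benchmarking CCI inference, spatially-variable-gene detection and
related methods.

Three input scenarios are supported: *paired* (expression and coordinates
from the same cells, e.g. SeqFISH+/MERFISH-class data), *expression only*
(scRNAseq/snRNAseq; the spatial map is generated de novo), and *unpaired*
(expression from one source plus a spatial map of typed cells from
another; the spatial map is inherited, the expression is modeled).

# Stage 1: the spatial map

## De novo regions: random-walk partition

Without a spatial reference the window is the unit square. For $K > 1$
regions it is divided into a $B \times B$ pixel grid ($B = 20$ by default;
larger $B$ gives smoother boundaries), $K$ distinct border pixels are
drawn as seeds, and regions grow cyclically — one pixel per region per
round, each time annexing a uniformly chosen unassigned edge-sharing
neighbor — until the grid is covered. Each region is 4-connected by
construction and regions end up of similar size; no rebalancing is
applied. Seed pixels may be adjacent; nothing in the growth rule requires
separation.

## Data-driven windows: Delaunay outer frame

With coordinates available, the window is estimated from the cell centers.
The default method surrounds every center with four buffer points at
radius $5\times10^{-4}$ (in the data's coordinate units) so boundary cells
end up strictly inside; builds the Delaunay triangulation of the augmented
set; discards triangles containing an outlier edge, defined as longer than
the mean edge length plus 3 SD; and returns the boundary of the union of
the surviving triangles (holes are preserved). Two numerical choices
matter here. First, the edge-length statistics are computed on
non-structural edges only (longer than twice the buffer radius): the vast
number of tiny buffer edges would otherwise drag the threshold down and
over-prune the interior. Second, the union is computed by divide-and-
conquer polygon clipping; clipping snaps vertices to a working grid, so
convex-hull-based windows are dilated by $10^{-6}$ of the coordinate range
before unioning to keep hull-boundary points inside. Faster
approximations — bounding rectangle, convex hull, and 2-5 vertical
sections with per-section hulls — are provided; region-wise estimation
resolves overlaps between neighboring region windows by assigning each
overlap wholly to one side, chosen uniformly at random.

## Cell allocation: Poisson point process + Metropolis-Hastings

Per cell type, the reference pattern is fitted with an inhomogeneous
Poisson point process whose log intensity is polynomial in the
coordinates: degree 3 (10 terms) when the type has more than ten cells,
degree 2 (6 terms) otherwise. The likelihood is maximized with the
Berman-Turner device — a weighted Poisson GLM over the data points plus
dummy quadrature points on a 100x100 grid restricted to the window — which
converges reliably and yields the observed information for coefficient
uncertainty. A caution on interpretation: the raw polynomial basis is
strongly collinear on a bounded window, so individual coefficients have
large variances even when the fitted intensity surface is tight;
functionals of the surface (e.g. its mean log-gradient) are the
identifiable quantities.

New coordinates are drawn by a spatial birth/death/shift
Metropolis-Hastings chain targeting the Poisson process with the fitted
intensity (internally rescaled so the expected count equals the target).
Moves are proposed with equal probability; a birth at a uniform location
$u$ is accepted with probability $\min(1, \lambda(u)|W|/(n+1))$, a death
with $\min(1, n/(\lambda(x)|W|))$, a shift with
$\min(1, \lambda(u)/\lambda(x))$ — the standard reversible kernel for this
target. The default budget is 500{,}000 iterations (tests and examples in
this package use $10^4$-$10^5$, which is ample for the desk-scale windows
and cell counts exercised there). Containment during the chain uses a
256x256 raster lookup for speed; the final configuration is filtered by
the exact polygon test and adjusted to the requested count — surplus
points thinned uniformly at random (the retained points already follow the
intensity; weighting the thinning by acceptance probability would square
it), deficits filled by rejection draws accepted with probability
$\lambda/c$, where $c$ is 1.05 times the maximum fitted intensity over a
200x200 grid. Cells closer than the minimum allowed distance (default
$5\times10^{-4}$, matching the buffer radius) are resolved by visiting
points in random order and keeping a point only if no kept point is within
range, so within each conflict cluster all but one cell are deleted at
random.

## Colocalization: pool inflation and logit selection

Planted attraction/inhibition between cell types is imposed by selection
from an inflated pool. The pool size is the target count times
$\lambda = \left(\sum_j \eta\,(1+|a_j|)\right)^{1+\nu}$ over the
colocalization patterns $j$ with strengths $a_j$ ($\eta = 1.5$ and
$\nu = 0$ by default; with no patterns $\lambda = \max(1, \eta^{1+\nu})$,
and $\lambda$ is clamped at 1 from below). Each pool cell $i$ of type $c$
gets a selection probability through
$\mathrm{logit}(p_{ic}) = \mu_{1,ic} + \mu_{2,ic} + \mu_{3,ic} + \alpha_c$:
$\mu_1$ sums same-type strengths times local same-type density, $\mu_2$
the cross-type terms, $\mu_3 = d^*_i\,\alpha^*$ rewards or penalizes
locally crowded cells (distribution evenness), and $\alpha_c$ is solved by
monotone root finding so the mean probability of type $c$ equals its
target/pool ratio (the mean of logistic curves is strictly increasing in
the offset, so the root is unique; tolerance $10^{-12}$). Exactly the
target number of cells per type is then drawn without replacement with
probability proportional to the remaining weights.

Two design choices here are the package's own. The density $d_{i,t}$ is
the *relative local density*: the count of type-$t$ cells in the
neighborhood divided by its pool-wide mean. This keeps strengths
scale-free while letting the logit respond over several units for
realistic strengths; normalizing by the cell's own neighbor count instead
caps the whole term at $|a|$ and planted patterns become nearly
unrecoverable. Second, the selection is made *self-consistent* with a
small number of Gauss-Seidel iterations (default 3): after a first draw
based on pool densities, each type in turn is re-drawn with densities
computed against the current selected configuration (over its
`contact_k = 3` nearest configuration cells, a deliberately small,
cell-contact-scale neighborhood). Without this, two mutually attracting
types chase independent density fluctuations of the pool and never
coordinate. Same-type *inhibition* is kept anchored to the static pool
densities inside the iterations: self-referential avoidance would
alternate between complementary patterns rather than converge. These
scales, like the inflation parameter, are calibration knobs for the
planted signal level; the defaults were fixed against the package's own
round-trip recovery experiments and are not re-tuned per run.

A structural note on what each estimator can see: the permutation
enrichment score (below) compares observed neighbor-type frequencies with
label shuffles *on fixed positions*. It detects compositional structure —
same-type clumping, cross-type segregation — but is blind to
composition-neutral joint clumping: if two types co-concentrate in the
same pockets while local composition stays at the slide-wide average,
label shuffles reproduce the observed pair counts and the enrichment is
null. Cross-type attraction therefore shows up in nearest-neighbor
distances (which shrink) rather than in enrichment; cross-type inhibition
and same-type attraction show up in both.

## Estimating colocalization from data

Neighbor graphs come in three flavors: symmetrized k-nearest neighbors,
Delaunay edges (optionally pruned by the same mean+3SD rule), and fixed-
radius. For every unordered type pair the observed neighbor-pair count is
compared with its mean over label permutations (2000 by default); the
enrichment is $\log_2(\text{obs}/\text{exp})$ with a 0.5 pseudo-count when
either side is zero (flagged), and the p-value is the two-sided
permutation tail probability with the +1 correction.

# Stage 2: expression

## ZINB marginals with a fallback ladder

Each gene in each cell type (optionally each region) is fitted with a
ZINB: structural-zero probability $\pi$, mean $\mu$, dispersion $\theta$
(variance $\mu + \mu^2/\theta$). Identifiability is adjudicated by BIC
among ZINB, NB, zero-inflated Poisson and Poisson (zero-inflated families
only compete when zeros are present): the extra parameter must earn its
keep, so Poisson-like genes collapse to Poisson, genes without excess
zeros to NB, and all-zero genes are recorded as structural zeros with mean
0. Likelihoods are evaluated on the value/count summary of each gene,
which makes fitting thousands of cells cheap. For large references a
uniform subsample of at most 2500 cells per (type, region) stratum is
used, trading negligible accuracy for speed.

## Gaussian copula

Gene-gene dependence within a cell type is modeled by a Gaussian copula:
latent $Z_i \sim N(0, \Sigma_c)$ with unit diagonal, $U = \Phi(Z)$, and
counts $Y_{ig} = F^{-1}_g(U_{ig})$ through each gene's fitted marginal
CDF — so the marginals are preserved exactly regardless of $\Sigma_c$.
Estimating $\Sigma_c$ from discrete counts requires mapping counts back to
latent scores despite heavy ties. The package's default scores are the
conditional means $E[Z \mid y]$ — the truncated-normal mean over the
count's latent bin, a deterministic, polyserial-style transform — and
$\Sigma_c$ is their sample correlation. The randomized distributional
transform ($u = F(y-1) + V\,(F(y)-F(y-1))$, $V$ uniform) is available as
an option but attenuates strong correlations measurably more: in recovery
experiments at $n = 2000$ with ZINB margins, planted $\rho = 0.3/0.6/0.9$
came back as 0.257/0.514/0.797 under the randomized transform and
0.284/0.554/0.868 under conditional means. Constant genes get identity
rows with a warning; a non-positive-semidefinite estimate is projected to
the nearest correlation matrix (recorded). No shrinkage is applied by
default. Sequencing depth enters generation as a multiplier on the NB mean
only ($\pi$ unchanged), default 1.

## CCI and regional perturbations: the change matrix

All perturbations accumulate in an $n_\text{cells} \times n_\text{genes}$
matrix $\Delta$, initialized at zero. For spatial dependence of gene
expression, cells of the perturbed type (in the stated regions, if any)
with a neighbor-type cell within the interacting distance get independent
$N(\mu, \sigma^2)$ draws at the spec's genes; distances are Euclidean
between cell centers. For gene-gene interactions, qualifying perturbed-
type cells get one draw at the sender-side gene; when bidirectional, each
qualifying neighbor-type cell receives *the same* drawn value (shared with
its nearest qualifying partner) at the receiver-side gene. Regional
effects add draws for all perturbed-type cells in the region. Genes may be
named or drawn as a fraction of the gene universe (uniformly without
replacement, recorded). Overlapping specs add, and the provenance record
ties every nonzero entry to the spec, cells, genes and draws that produced
it.

The update is $Y' = \text{round}\big(\max(0,\;
\mathrm{expm1}(\mathrm{log1p}(Y) + \Delta))\big)$. The log1p/expm1 pair is
an interpretation: effects are "added to log counts", but zero counts must
stay zero under negative effects yet be able to rise under positive ones,
which plain log cannot do. A convenient consequence is exactness at the
mean: group means transform as $e^{\mu}(1+\bar y) - 1$, so an effect
$\mu$ on the natural-log scale is recovered as $\mu/\ln 2$ by the log2
fold-change estimator below. Optional constraints: capping at
$\max(5 \times Q_{97.5}(\text{initial}), \max(\text{initial}))$ (the
quantile taken over all entries), and depth matching, which rescales by
total(initial)/total(updated) and then corrects rounding drift by
largest-remainder apportionment, so totals match exactly.

## Estimating expression CCIs from data

Spatial dependence: per ordered sender/receiver type pair, receivers are
split into those with at least one sender neighbor versus none (groups of
fewer than two cells are skipped), and each gene's enrichment is the log2
fold change between group means with a pseudo-count of 1; p-values come
from shuffling the group assignment. Gene-gene interactions are estimated
only over a supplied gene-pair list (a small curated human
ligand-receptor list ships in `inst/extdata/`): for each pair, the mean
product of the sender-side gene in sender cells and the receiver-side gene
in receiver cells over adjacent cell pairs is compared with non-adjacent
pairs, again as a pseudo-counted log2 fold change with a permutation
p-value from redrawing the adjacent set.

# Multi-cell output and metrics

Spot-level data are made by tiling the window's bounding box into $s
\times s$ equal squares with $s = \lceil\sqrt{n_\text{squares}}\rceil$,
summing expression per square and reporting square centers as
coordinates. Squares intersecting the window are kept even when empty;
squares wholly outside are dropped. Aggregation conserves total counts
exactly.

Fidelity and benchmarking metrics: coverage percentages between simulated
and reference windows (total, overlap, reference-only, simulation-only,
all relative to the reference area); absolute and relative bias; Pearson
correlation and MSE between effect-size vectors; and, for ligand-receptor
benchmark tables, balanced accuracy over a declared interaction universe
(default: the LR list crossed with ordered type pairs) plus the normalized
F1 — observed F1 over the mean F1 of size-matched random predictions, with
both scores zero when there are no true positives.

# The synthetic reference generator

`generateReference()` produces desk-scale fixture bundles (default 500
cells x 200 genes, 3 types — comparable to the smallest single-cell SRT
datasets in routine use) with fully known structure: per-type ZINB
catalogues (lognormal means with a per-type signature block, zero
inflation 0.05-0.4, dispersion 0.5-3), one planted copula block, optional
planted colocalization through the real selection machinery, and optional
planted expression perturbations through the real $\Delta$ pipeline.
Identical seeds give bit-identical bundles. What it deliberately does not
emulate: within-type continuous heterogeneity (each type is homogeneous),
batch or segmentation artifacts, and tissue-shaped windows (maps are
generated on the unit square). Passing round-trip tests on these fixtures
therefore demonstrates internal consistency of the generators and
estimators — not robustness to the full messiness of real tissue data.

# Study sizes used by the checks

The test suite and the acceptance script run at sizes chosen to make the
statistical checks well-powered yet quick: marginal recovery uses 50 genes
at 5000 cells each with parameters in the identifiable regime (zero
inflation 0.15-0.3, means 6-12, dispersion 2-3 — at this sample size the
dispersion MLE has a relative SE of 3-6%, so recovery within 10% is a
meaningful but attainable bar there, while weakly expressed genes would
fail it for purely statistical reasons); copula recovery uses two genes at
2000 cells; colocalization round trips use 500-cell maps over 20 seeds;
expression-CCI round trips use 400-cell maps across effect sizes 0.1-0.5;
the M-H checks draw 1000-1500 points with chains of 30-40 thousand
iterations.

# Known limitations

Cell types are treated as homogeneous groups; unlabeled subtypes are
blended. The colocalization machinery plants patterns at the contact
scale of its density neighborhood — long-range gradients should be
expressed through region structure or intensity models instead. The
enrichment estimator cannot certify composition-neutral joint clumping
(see above). Window estimation assumes the point cloud is dense enough
that triangle pruning carves true concavities rather than noise; for very
sparse types, use the convex or rectangular window. Intensity models use
raw polynomial bases and should be fitted on coordinates of moderate
numeric range (normalize first if coordinates are in large absolute
units).
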
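---
title: "Methods: models, parameters and design choices in hicdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hicdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicdyn)
```

`hicdyn` quantifies chromatin-architecture dynamics over a
differentiation time course from binned Hi-C contact matrices, together
with trans-contact statistics and 3D FISH distance statistics. This
vignette is the package's account of the underlying models, the
parameters that matter, and the places where a design decision was
genuinely open.

## Contact-matrix model and normalization

A contact map is a symmetric non-negative matrix over a genome-wide bin
table, stored as upper-triangle triplets with 0-based dense bin ids.
All analyses run at two resolutions: 500 kb for compartments and trans
statistics, 40 kb for TAD calling.

**Masking.** Bins with a zero marginal, plus the lowest 2% of non-zero
marginals (`mask_quantile`), are masked before balancing. Low-coverage
bins destabilize iterative correction and carry no usable signal; the
2% default is our own choice — upstream pipelines apply a similar
low-coverage filter without documenting the exact cutoff — and a masked
bin is excluded from *every* downstream statistic (expected profiles,
PC1, deciles, Z-scores), never re-imputed.

**ICE balancing.** We seek weights $w_i$ with
$b_{ij} = w_i w_j x_{ij}$ and equal unmasked row sums (scaled to 1).
The update divides each bias by its current relative marginal; on
symmetric matrices the undamped update oscillates between two bias
sequences, so we apply the square-root-damped step
$b \leftarrow b\,\sqrt{s/\bar s}$, which converges monotonically
(typically < 20 iterations at `tol = 1e-5`, capped at
`max_iter = 200` with a warning and a `converged` flag). The
convergence criterion is the maximum relative deviation of row sums.

**Expected and O/E.** The expected value at distance $d$ is the mean
balanced value over all unmasked pairs at $d$ within a chromosome
(implicit zeros included; diagonal excluded); the trans expected is a
single scalar mean over all unmasked inter-chromosomal pairs. O/E
divides by these, so the per-distance mean of O/E is 1 by construction.

## Compartment calling and switching

PC1 is computed per chromosome: O/E → Pearson correlation matrix →
leading eigenvector (scaled by the square root of the leading
eigenvalue). Because the diagonal is excluded from O/E, each diagonal
cell is imputed with its column's off-diagonal mean before the
correlation — a numerical convenience that lets a dense BLAS
correlation be used and has negligible leverage ($1/n$ of a column).
The eigenvector sign is arbitrary, so each chromosome is oriented to
correlate positively with a per-bin reference track (gene density, or
any active-chromatin proxy); A is positive, B negative. Chromosomes
with fewer than `min_bins = 10` usable bins are skipped.

Switching is classified per bin from a time course with replicates
(T ≥ 2 time points, R ≥ 2 replicates): a one-way ANOVA F-test across
time points with p < α (default 0.05) *and* at least one positive and
one negative time-point mean. Numerical choices:

- bins whose values are identical across all samples have no
  within-group variance; the F statistic is 0/0 and we assign p = 1
  (no evidence of change) rather than propagate NaN;
- the category is the sign sequence of time-point means with
  consecutive duplicates collapsed; an exactly-zero mean inherits the
  previous sign (leading zeros inherit the first non-zero sign), i.e.
  ties break toward "no transition";
- 4-segment sequences (A–B–A–B, B–A–B–A) are merged into A–B / B–A by
  their first and last sign, matching how such rare oscillations are
  reported in practice;
- bins with any missing replicate value are excluded and counted.

With α = 0 no bin switches; with α = 1 every sign-changing bin
switches; under a no-switch simulation the call rate stays below α
(the sign-change requirement makes the test conservative — a strongly
A or B bin cannot produce a sign change from replicate noise alone).

**Saddle plots.** Bins are assigned to deciles of the PC1 track
(per sample, on its own track — whether the original analyses shared
decile edges across time points is not recoverable, and per-sample
edges are the self-contained reading); each unmasked pair contributes
its O/E value to its decile-pair cell; the cell stores log2 of the
mean. The difference between two samples is taken as the difference of
the log2 grids. The alternative reading (log2 of the grid difference)
is ill-defined for negative differences, which settled the choice.
Empty cells are `NA`, never 0.

**Decay curves.** Cis pairs are classed A–A/B–B/A–B by the sign of the
chosen track; at each distance the class mean is divided by the
all-pairs mean, so the pair-count-weighted mean of the three classes
is 1 at every distance. Distances where a class has fewer than
`min_pairs = 20` pairs are reported `NA`.

## TAD boundaries

Two independent callers operate on balanced 40 kb maps.

*Directionality index*, window 2 Mb (50 bins): upstream/downstream
contact sums A and B give
$DI = \mathrm{sign}(B-A)\left[(A-E)^2/E + (B-E)^2/E\right]$ with
$E = (A+B)/2$. Domain segmentation is a deterministic run-length rule —
a domain opens at the start of a stretch with $DI \ge$ `pos_thresh`
and closes at the end of the next stretch with $DI \le$ `neg_thresh`
(defaults: the 0.9/0.1 track quantiles) — rather than the original
HMM: the HMM's fitted parameters are not reproducible from any
published description, and the run-length rule is deterministic and
directly testable. Thresholds are exposed and logged.

*Insulation score*, square 500 kb (12 bins; the window used in the
original studies at this resolution is not stated, and 500 kb is the
common choice): log2 of the mean contact in the upstream×downstream
square over the chromosome mean of that statistic, defined only where
the full square fits. Boundaries are local minima whose strength — the
smaller drop from the two nearest flanking local maxima — reaches
`min_strength = 0.1`; the filter is monotone, so raising the threshold
can only remove boundaries.

**Boundary comparison.** Two sets are compared by greedy one-to-one
nearest matching within a tolerance (80 kb between replicates, 200 kb
between time points), since nothing published states how multiple
matches inside the tolerance were counted; greedy closest-first
matching is order-independent and each boundary is used once.
Jaccard = shared / union. TADs inherit the switch category covering
the majority of their span (51% rule; plurality when no category
reaches 51%), and boundary-class enrichment compares a class's
category distribution with the union set's by
log2(share ratio) + chi-squared.

## Trans-contact statistics

Replicates are pooled (entry-wise mean of balanced maps) before trans
analysis. For an anchor bin, all inter-chromosomal balanced values are
extracted, values strictly above the $1-{\rm trim}$ quantile (trim =
0.005) are removed — rare extreme trans values are typically
artefactual — and the remainder is Z-scored; the trim is computed per
anchor on its own trans vector. Partner bins are labelled A/B by the
compartment track for rank-sum comparisons.

The gene-set score sums balanced counts over all unordered
promoter-bin pairs on different chromosomes (promoter = TSS bin; genes
sharing a bin each count in their pairs). The permutation null redraws,
per chromosome, the same number of genes as the seed set from a
user-supplied universe, without replacement and excluding the seed
genes (the exclusion makes the null strictly "other gene sets"; with
any realistically sized universe the effect on calibration is
negligible). The empirical p uses the add-one correction
$p = (1 + \#\{S_{null} \ge S_{obs}\})/(n+1)$, so p is never 0. Whether
the original universe was all genes or expressed genes is not stated;
the universe is an explicit argument (`universe_filter` semantics are
the caller's), and the choice is logged by the pipeline. Network edges
are flagged for display when the late-time-point pair count strictly
exceeds the genome-wide median trans count of the late map, and
annotated with the median-normalized log2 fold change (pseudocount for
zero counts, flagged per edge).

## Category enrichment

Intervals are assigned to 500 kb bins by midpoint and genes by TSS —
single-category assignment with no fractional counting. Enrichment is
log2(class share / background share) with a chi-squared test of
observed counts against expected counts proportional to the
background distribution (the "gene density" normalization: the
background is all genes, or the union peak set). Stage-specific peaks
have no ≥ 1 bp overlap in any other stage; constitutive peaks overlap
every other stage (any-overlap chaining, the default reading of an
unstated rule). DE modelling is consumed, not refit: DE flags and
q-values are input columns, and the DE set is flagged genes with
max FPKM ≥ 5; the peak stage is the argmax time point with ties
resolved to the earliest stage (counted and reported).

## FISH statistics

Diploid cells show exactly two spots per locus channel (focus channels
unconstrained). Distances are normalized by
$x_{norm} = x_{raw} \cdot V_{ref}^{1/3} \cdot V^{-1/3}$ with
$V_{ref}$ the mean nucleus volume of a reference condition (an
argument, not a constant). Proximity (< 2 µm, i.e. twice the 1 µm spot
diameter) is called on *normalized* distances, matching how the
distance distributions are reported; focus overlap (< 1 µm, strict) is
called on *raw* distances because the threshold encodes physical spot
size — calling it on normalized distances is exposed only through the
threshold argument. Periphery distances are taken from the input table
(a distance-transform export) and normalized by the same volume rule
by default, with a flag to disable. Group comparisons use the
rank-sum test (2 groups) or Kruskal–Wallis followed by Dunn's pairwise
z-tests with Bonferroni adjustment (Dunn's classical correction),
implemented with the standard tie-corrected formula.

## What the generators emulate — and what they do not

The simulators exist so that every analysis is validated as a
parameter-recovery test with planted truth written next to the data.

`sim_hic` builds a toy genome (default 4 chromosomes × 10 Mb at
500 kb) with: alternating A/B base blocks (≈ 50/50), a planted
switching fraction (default 0.19) with category mix 0.33/0.49/0.08/0.10
— the study-scale dynamics the package targets — multiplicative
expectations (cis $\propto d^{-\alpha}$, α = 1, homotypic boost 1.6,
long-range B–B gain 0.15 per stage beyond 10 Mb, trans base with an
A–A boost and an optional hub gain at chosen stages), and
negative-binomial counts (dispersion 0.1, overdispersed like real
Hi-C; dispersion 0 gives deterministic rounded counts). `sim_tad_map`
plants square domains (1 Mb default) on a 40 kb grid. `sim_tracks`
emits genes, stage-peaked FPKM, simulated q-values and peak BEDs with
configurable odds ratios tying late-stage genes/peaks to B→A bins.
`sim_spots` places spots uniformly in ellipsoidal nuclei (lognormal
volumes, mild anisotropy), plants an exact proximity fraction
(non-proximal cells are rejected back beyond a 2.3 µm normalized
margin so the planted rate *is* the true rate), supports aneuploid
cells and focus channels, and computes exact center-to-surface
periphery distances along the radial ray.

What passing recovery tests shows: the estimators are unbiased and
correctly calibrated under a multiplicative block model with NB noise.
What it does not show: robustness to features of real Hi-C the
generator omits — translocations, copy-number variation, mappability
structure, restriction-fragment effects, distance-dependent noise,
X-inactivation (a real analysis would exclude or flag sex
chromosomes; the toy genome has none), and nested/hierarchical TADs.
FISH simulation starts from spot centers: segmentation error, optical
anisotropy in z, and probe efficiency are out of scope.

## Problem sizes and runtime

The bundled checks run at deliberately modest sizes chosen to exercise
every code path: 2000 bins × 8 samples for switch recovery, 50
simulated data sets for type-I control, 30-bin toys for the balancing
and eigenvector oracles, 250-bin maps (× 3 seeds) for TAD junction
recovery, 1000 permutations for the hub test and 200 data sets × 199
permutations for null calibration, 500 cells for FISH recovery. The
full suite runs in under a minute on one CPU; tolerances in the tests
are stated next to each check and reflect binomial/simulation error at
those sizes, not instrument precision.

## Known limitations

- ICE assumes a single multiplicative bias per bin; copy-number-driven
  marginal differences are "corrected" rather than detected.
- PC1 compartment calling fails on chromosomes where the leading
  eigenvector tracks something other than compartmentalization (e.g.
  p/q arm structure on real data); inspect the saddle plot before
  trusting signs.
- The DI segmentation is deliberately simpler than the original HMM;
  absolute domain counts differ even where junction positions agree.
- The permutation test conditions on the seed set's chromosome
  distribution only; matching on expression or gene length, when
  needed, must be done through the universe argument.
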
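---
title: "Methods: aging-signature and spatial-niche analysis with nichetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aging-signature and spatial-niche analysis with nichetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nichetrack` analyses how the hippocampal neurogenic niche ages, from
two complementary angles: *real time* (ordered young/middle/old
cohorts) and *pseudotime* (a latent activation or differentiation
coordinate inferred from expression). This vignette explains each
model, its assumptions, the tunable parameters, and the design choices
made where the methodology was genuinely open. It states no empirical
result beyond what the package's tests and `scripts/acceptance.R`
themselves compute.

## Normalization, variable genes and markers

Counts are library-size normalized,
`lognorm = ln(1 + counts * 10^4 / total)`, the standard scaling for UMI
data; a cell with zero counts yields an all-zero column and a warning
rather than an error, since synthetic and subset data can legitimately
contain such cells. Variable genes are ranked by standardized variance:
observed count variance against a loess trend (span 0.3, chosen fixed
for reproducibility rather than tuned per dataset) of log10 variance on
log10 mean, with standardized values clipped above at `sqrt(n_cells)`
so single outlier cells cannot dominate a gene's rank. Markers are
one-vs-rest two-sided Wilcoxon rank-sum tests on `lognorm` with
Benjamini–Hochberg correction within each group and the conventional
cutoffs (adjusted p < 0.05, `avg_log2fc` > 0.25, where the fold change
is computed on `expm1`-backtransformed means with a +1 stabilizer).
A rank test makes no distributional assumption about zero-inflated
expression; its p-values are consumed as a ranking device for
downstream feature selection, not as inferential endpoints.

## Module scores with binned controls

A gene set's per-cell score is the mean `lognorm` of the set genes
minus the mean over pooled control genes. All genes are placed in
`score_bins = 24` equal-frequency bins of mean expression (ties broken
by gene id so the binning is deterministic), and each set gene draws
`score_ctrl = 100` controls from its own bin, excluding itself, with
replacement only when the bin is smaller than the request — small
synthetic matrices must not fail. Equal-frequency rather than
equal-width bins keep the procedure stable on zero-inflated means. The
sampling order is canonical (set genes in sorted id order, candidates
sorted, one `sample.int` call each under the given seed), which makes
scores invariant to gene and cell ordering and lets an independent
brute-force recomputation reproduce them exactly. The bin and control
counts follow the convention of the widely used single-cell scoring
tool; both are configuration-exposed.

## Real-time trends: fuzzy c-means on age profiles

Per population, genes are summarized as mean `lognorm` per age and
z-scored across the three ordered ages. Because z-scoring rescales
every profile to the same magnitude, a gene whose age variation is pure
sampling noise would be amplified into a spurious clean trend. The
profile matrix therefore excludes rows whose standard deviation across
the age means fails to exceed both an absolute floor
(`min_profile_sd = 0.02` lognorm units) and twice the gene's estimated
standard error of those means — the noise-aware analogue of the
low-variation filter customary before soft clustering of time courses.
The multiplier 2 corresponds to requiring roughly a 2-sigma excess over
noise; it is self-calibrating across cell counts. Standardization uses
the population-sd convention (divide by n); sample-sd is available via
`sd_type`.

Profiles are clustered by fuzzy c-means with `c = 8` clusters,
minimizing the usual weighted objective with membership update
`u_ij ∝ d_ij^(−2/(m−1))` and `u^m`-weighted centre update. Centres are
initialized by seeded k-means++; convergence is declared when the
largest membership change falls below 1e-6 (cap 200 iterations), and
the per-iteration objective is recorded — the alternation guarantees it
never increases, which the tests assert on every run. The fuzzifier
defaults to `m = 1.25`: the tool the procedure is modelled on estimates
its fuzzifier internally without reporting it, and a fixed, fairly
crisp value is reproducible while still letting ambiguous genes show
split memberships. Profiles coinciding with several identical centres
split membership evenly (hence exactly `1/c` when all profiles are
identical); a single exact hit gets membership 1.

A cluster is an *up* (*down*) trend when its centre increases
(decreases) strictly across the three ages. A gene joins a trend set
when its highest membership lands in such a cluster and reaches
`membership_threshold = 0.5` — a majority of its membership mass, the
natural default where the methodology is silent.

## Pseudotime: principal curves and gene modules

All trajectories in the package are single-branch and use one
algorithm: a principal curve fitted by Hastie–Stuetzle alternation over
the leading PCs (PCA on gene-standardized `lognorm`, deterministic sign
convention: the largest-magnitude loading of each component is
positive). The curve is initialized on PC1; each round smooths every
coordinate against the current arc-length position with a cubic
smoothing spline (df = 6 — flexible enough for one bend, stiff enough
not to chase noise), resamples the curve at 200 arc-length points, and
projects each cell to its nearest segment. A round that would increase
the mean squared projection distance is rejected, so the recorded trace
decreases strictly; convergence tolerance is 1e-4. Pseudotime is the
min-max-scaled arc position, oriented so a declared root population
(the quiescent stem cells, or the inflammatory spots in the spatial
case) sits at low `t`; flips are logged. Degenerate inputs (all points
identical, or a collapsed arc) are errors, never silent gradients.

Gene modules along pseudotime come from smoothing each gene (df = 6) on
a 100-point grid, z-scoring the fitted profile, and clustering with
seeded k-means (10 restarts). Modules are renumbered by the mean peak
position of their genes, so module 1 always peaks earliest — the
numbering the signature construction relies on. Constant genes cannot
be profiled and are reported as unassigned. The module count defaults
to 4, the granularity used throughout the lineage, activation and
spatial analyses.

## The NAS and CAS signatures

The *Neurogenic Aging Signature* intersects real-time trend genes of
the quiescent stem cells with pseudotime modules of their activation
trajectory: up-trend genes with the early stem-enriched module
(default module 1), down-trend genes with the late fate-committed
modules (default modules 3 and 4). Genes of the intermediate module 2
are excluded by default — their association with either end of the
trajectory is ambiguous. The *Core Aging Signature* takes the
whole-tissue spatial trend (pseudobulk of dentate-gyrus spots per age)
and keeps genes showing the same trend in at least
`min_shared_celltypes = 2` of the five main niche populations
(astrocytes, qNSCs, granule cells, endothelial cells, microglia).
Both constructions are pure set operations with per-gene provenance,
and the CAS is monotone non-increasing in the sharing threshold.

## Differentiation score and age classifier

The differentiation-score model follows a five-step recipe: markers
across the three lineage stages (top 50 per stage by fold change — the
underlying study reports using "top" markers without a count, and 50
per stage keeps the feature space comfortably above the final 100);
principal-curve target over the first 7 PCs scaled to [0, 1] with
quiescent cells low; a 500-tree random forest (impurity importance,
seeded — the algorithm named by the study's tooling, with otherwise
default hyperparameters); retention of the top 100 features; and a
refit on that core set, which is the model used for all predictions.
Prediction requires every core feature to be present and is invariant
to cell order and to anything outside the feature set.

The age classifier balances its training set exactly — 70 % of the
least-populated age class, the same count sampled from each other
class — so prior imbalance cannot masquerade as age signal. A
multinomial elastic net is tuned by 10-fold cross-validated
misclassification over mixing values {0.1, 0.5, 0.9} × 20 log-spaced
penalties per mixing value (the study tuned both parameters without
printing its grid); the selected pair is refit and evaluated on the
held-out remainder. Fold assignment and the split derive from the seed.

## Spatial hierarchy and pseudo-space

Spot neighbourhoods use array coordinates, where the hexagonal
neighbours of `(r, c)` are `(r, c ± 2)` and `(r ± 1, c ± 1)` — exact
and independent of the pixel dialect; a pixel-distance fallback (within
1.1× the pitch) exists as the independent oracle in tests. Inflammatory
spots are those with interferon-γ-response module score strictly
greater than 0; rings grow by breadth-first expansion within the region
mask — nearest neighbours (NNS), then `n_ens_layers = 2` extended
layers (ENS1, ENS2) — and the classes partition the masked spots by
construction. The pseudo-spatial axis is the same principal-curve
machinery applied to spots, oriented so inflammatory spots sit below
the outermost populated ring on average; its gene modules are numbered
inside-out.

## Microniches and co-occurrence

Circles of radius 55 µm are tiled along a reference polyline (the
hand-drawn subgranular-zone line in the imaging workflow) at centre
spacing `2r(1 − overlap)`; the default `overlap = 0.5` reads "50 %
overlap" linearly along the line, giving spacing = radius. The
alternative reading — 50 % shared lens area, spacing ≈ 0.8079 r — is
available via `overlap_mode = "area"`. Centres keep one radius of
clearance from both ends, and any leftover arc is split symmetrically
between the ends so that traversing the polyline backwards yields the
same circles; a line shorter than one diameter yields a single midpoint
circle with a warning. Cells are counted on closed discs (a cell
exactly on the rim counts).

The co-occurrence test reduces each circle to two presence indicators
and permutes the B indicator across circles, conditioning on the circle
geometry and both presence totals; the two-sided p-value uses the
standard `(1 + #extreme) / (1 + n_perm)` form and the odds ratio a
Haldane-corrected 2×2 table. Two caveats shape how the test should be
used. First, overlapping circles share cells, so neighbouring
indicators are dependent and the permutation null understates the
variance; calibration analyses therefore use tangent circles
(`overlap = 0`). Second, both labels become more likely in
better-populated circles, which couples the indicators even under
independent labels; the effect vanishes when cells are dense and labels
rare (presence rates of order one per circle from many cells). The
calibration and power benchmarks in the tests and acceptance script use
exactly those conditions. The proximity analysis centres a disc on
every centre-labelled cell and reports the fraction with at least one
target inside, a doubly-labelled cell never counting as its own target;
under uniform placement this fraction has the closed form
`1 − exp(−ρπr²)`, which serves as its oracle.

## What the generators emulate — and what they do not

`simulate_lineage_atlas` draws negative-binomial counts
(`NB(mu, theta)`, `mu = libsize × relative rate`) with four planted
structures: per-stage marker blocks; a latent activation coordinate
`t ∈ [0, 1]` (low in qNSCs, mid in aNSPCs, high in NB/IMN) driving four
sequential lineage modules as logistic activations with staggered
midpoints (module 1 decreasing — the stem-identity program); monotone
age blocks whose total log-shift `2δ` is split between the two age
steps by a per-gene breakpoint drawn from U(0.25, 0.75), so trend
*shapes* vary as real age responses do rather than collapsing onto a
single z-profile; and, by default, coupling of the age blocks to `t`
(up-regulated aging genes decline along activation and vice versa),
reproducing the overlap between real-time trends and early/late
pseudotime modules that motivates the NAS construction. The quiescent
stage's latent coordinate drifts down by 0.05 per age step by default —
the deeper-quiescence phenotype of the aged niche. Defaults
(δ = 0.5 per step, library sizes ~2.5k UMI, θ = 2, 800 genes) are
single-cell-realistic.

`simulate_spot_grid` builds a compact hexagonal lattice (12 × 12 by
default, ~144 spots — a dentate-gyrus-sized region mask) with spot
library sizes around 20k UMI and θ = 10, reflecting that a Visium spot
pools several cells; an inflammatory block of 150 genes (the size of a
hallmark pathway) is multiplied by `1 + A·exp(−d/λ)` around planted
hotspot centres, default amplitude 2 and decay 250 µm, the
few-hundred-micrometre spread of inflammatory foci in aged tissue.
`simulate_tissue_cells` places cells uniformly and assigns two binary
labels independently, exclusively (B relocated outside an exclusion
radius of every A), or attractively (B weighted toward A).

None of the generators include doublets, ambient RNA, batch effects,
segmentation errors or cell-type deconvolution truth. Passing tests on
these simulations therefore demonstrate that the *procedures* recover
what was planted under realistic noise — not that any biological claim
transfers to a particular real dataset.

## Problem sizes and numerical conventions

The test suite and acceptance script run the pipeline at sizes chosen
to make the statistical checks decisive while staying desk-scale: 300
cells per age for trend recovery, 300 cells per lineage stage for the
differentiation model, 450 cells for each classifier fit, 144-spot
lattices, 220–300 microniche circles with 500 calibration replicates
(499 permutations each). Key tolerances: fuzzy c-means membership
convergence 1e-6; principal-curve MSE improvement 1e-4; PCA loading
orthonormality 1e-8; module-score oracle agreement 1e-12. Ties are
always broken deterministically (gene id order), and every stochastic
step takes an explicit seed, so equal seeds give bit-identical results.

## Known limitations

* Trajectories are single-branch by design; lineages with true
  branching need a different pseudotime backbone.
* The marker test is a rank-sum screen, not a count-model inference;
  its p-values should not be reported as differential-expression
  results.
* The strict score > 0 rule for inflammatory spots inherits the
  module score's centring: in tissues where the gene-set signal is weak
  relative to score noise, the call set will be noisy at the boundary.
* The co-occurrence permutation test is calibrated for tangent circles
  with rare labels over dense cells; heavily overlapping circles or
  near-saturated presence call for a different null.
* The age classifier's accuracy is an internal validation on held-out
  cells of the same dataset, not a cross-dataset transfer claim.
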
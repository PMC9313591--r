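---
title: "Quantifying flower symmetry variation and its evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flower symmetry variation and its evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalspectrum)
```

## What the package does

`petalspectrum` characterises corolla (petal-whorl) symmetry across a clade
and asks how that symmetry evolved.  The pipeline has two independent arms:

1. **Morphometrics**: closed 2D outlines of flowers, photographed from the
   front and from the side, are aligned by their landmarks (generalised
   Procrustes analysis), decomposed by elliptical Fourier analysis (EFA),
   purged of within-specimen left--right noise, averaged per taxon,
   summarised by PCA into a morphospace, clustered into symmetry
   phenotypes with a majority rule over internal validity indices, and
   finally screened for adaptive-optimum shifts on a phylogeny under a
   multivariate Ornstein--Uhlenbeck (OU) model scored by a phylogenetic
   BIC.
2. **Introgression**: trio D-statistics (ABBA--BABA) on a biallelic
   genotype matrix, in three trio-arrangement modes, with block-jackknife
   significance and Benjamini--Hochberg correction across trios.

Because the raw images and genotypes of any particular study are not
needed to exercise the method, the package ships seeded synthetic
generators for all three input kinds (outlines, trees with OU traits, and
trio genotypes) with known ground truth.  `demo_config()` +
`run_pipeline()` runs the whole pipeline end to end on such data.

## Outlines and their conventions

An `outline` is an ordered, implicitly closed polyline, stored
counter-clockwise (positive shoelace area).  Coordinates are continuous
planar units with no physical scale: the full Procrustes step removes
scale, so units are irrelevant downstream.  Landmarks are stored as vertex
indices; front views carry four (left-middle, right-middle, top, bottom)
and side views three (tube base, upper-lip tip, lower-lip tip).

Conventions that the source-material workflow leaves unstated are fixed
here once and tested:

* **Point density.** Default 300 resampled vertices — more than 8 vertices
  per harmonic at 32 harmonics, so lobed shapes are never aliased.
* **Start vertex.** After resampling, the outline starts at the top
  landmark (front) or tube base (side).  Fourier coefficients depend on
  the start point, so a deterministic rule is what makes coefficients
  comparable across specimens.
* **Raster ingestion.** Binary masks are traced by marching squares
  (`grDevices::contourLines` at level 0.5) after 3x3 binomial smoothing of
  the padded mask.  The smoothing places the contour with sub-pixel
  accuracy and removes the staircase bias that would otherwise inflate
  perimeters by several percent; a traced disk of radius 20 px recovers
  its perimeter to better than 1%.  The raster y axis is flipped on
  ingestion so one orientation convention (counter-clockwise positive)
  holds everywhere.
* **Landmark snapping.** Nearest vertex, ties broken toward the lower
  index — deterministic and testable.

## Alignment and the Fourier decomposition

`gpa_align()` performs full generalised Procrustes alignment **on the
landmark configurations only** (translate to centroid, scale to unit
centroid size, rotate by the 2D orthogonal Procrustes solution, iterate
against an evolving consensus until the root-mean-square consensus change
drops below `tol = 1e-10`), then applies each specimen's similarity
transform to its whole outline.  Aligning on landmarks and letting the
outline follow mirrors the landmark-then-EFA order of the underlying
workflow; no first-harmonic Fourier normalisation is applied, because it
would fight the landmark alignment.

After convergence the whole set is rigidly rotated so the consensus
bilateral axis — top-to-bottom landmark direction for front views, tube
base to lip midpoint for side views — lies along +x.  This choice makes
the symmetry algebra exact (next section).

`efa_forward()` uses the classical chord-length parameterisation: with
per-segment increments $\Delta x_p, \Delta t_p$, cumulative length $t_p$
and perimeter $T$,

$$a_n = \frac{T}{2 n^2 \pi^2} \sum_p \frac{\Delta x_p}{\Delta t_p}
  \left[\cos\frac{2\pi n t_p}{T} - \cos\frac{2\pi n t_{p-1}}{T}\right],$$

with the sine analogue for $b_n$ and the $y$ analogues for $c_n, d_n$;
offsets $A_0, C_0$ are arc-length averages (exact for the polygon).  The
implementation is validated against closed forms (a circle of radius 2
yields $a_1 = d_1 = 2$ to $10^{-3}$), against invariances (translation
moves only offsets; rotation acts as the known 2x2 rotation on the
$(a, c)$ and $(b, d)$ pairs), and by round-trip (`efa_inverse`) error
below $10^{-4}$ of centroid size at 64 harmonics.

## Symmetry decomposition

With the bilateral axis on +x, mirroring an outline across its symmetry
axis and restoring the traversal direction maps coefficients as
$(a_n, b_n, c_n, d_n) \mapsto (a_n, -b_n, -c_n, d_n)$ and
$C_0 \mapsto -C_0$.  The $(b_n, c_n, C_0)$ block is therefore *exactly*
the mirror-antisymmetric subspace.  `remove_asymmetric_component()`
zeroes it, which equals averaging the shape with its mirror image in
coefficient space; the output is exactly mirror-invariant and keeps
exactly the symmetric-subspace power.

Two removal modes exist because conventions in the literature differ on
which subspace a "symmetry" function should zero.  The default removes
the **asymmetric** block, matching the stated goal of discarding
within-specimen variation between opposing halves; `component =
"symmetric"` zeroes the other block instead for analyses of the
asymmetry itself.  Removal is applied to front views only (left--right
noise is a within-specimen artefact there); side views pass through, as
their upper/lower asymmetry is biological signal.  Asymmetry removal is
done per specimen, before per-taxon averaging: averaging first would let
one specimen's noise leak into the taxon mean.

## Harmonic-count calibration

`calibrate_harmonic_count()` chooses the smallest $N$ at which the *mean*
cumulative power fraction across outlines reaches the threshold (default
0.99, `N_max = 64`).  Two deliberate choices: the mean of per-outline
fractions (rather than a per-outline worst case) defines "achieved" on
average, and the fractions are normalised by the power of a *full*
reference decomposition (half the vertex count), not by the first
`N_max` harmonics — otherwise the fraction at `N_max` would be 1 by
construction and the cap flag could never trigger.

## Morphospace, clustering, clade occupancy

`fit_pca()` eigendecomposes the covariance of centred, **unscaled**
coefficient vectors — after Procrustes scaling, coefficients share units,
so correlation scaling would only inflate noise harmonics.  Loadings get
a deterministic sign (largest-magnitude entry positive).  The first three
PCs feed clustering and shift detection.

`select_k_majority()` fits K-means (`stats::kmeans`, Lloyd iterations,
k-means++ seeding, best of 10 restarts, deterministic under seed) for
every K in 2..20 and lets ten internal validity indices vote:
Calinski--Harabasz, mean silhouette, Davies--Bouldin, Dunn, C-index, gap
statistic (50 seeded uniform reference sets in the principal-axis
bounding box, one-standard-error rule), Hartigan's rule (threshold 10),
Krzanowski--Lai, Ball--Hall (largest successive drop) and Xu (minimum).
The chosen K is the modal vote, ties broken toward smaller K.  The
majority *mechanism* is the method; a ten-index battery with standard
published formulas realises it, and the battery is configurable.  On
three tight, widely separated Gaussian blobs the rule recovers K = 3 with
at least 70% of votes: the defectors are Hartigan's rule and the Xu
index, whose standard formulations over-split data with near-zero
within-cluster variance — worth knowing when reading a vote table.

`clade_hull_occupancy()` reports the 2D convex hull (shoelace area) of
each clade's taxa on chosen axes; clades with fewer than three
non-collinear taxa are flagged degenerate with area 0.

## Ornstein--Uhlenbeck shift detection

Traits (PC scores) follow a multivariate OU process with optimum shifts
on edges.  The conventions:

* **Shift placement.** A shift acts from the *start* of its edge onward.
  The simulator (`sim_ou_traits`) and the inference design matrix
  (`ou_design_matrix`, entries $1 - e^{-\alpha (T_i - s_e)}$ on root-to-tip
  paths) share this convention, so simulation and inference agree by
  construction.
* **Stationary root.** The root state is drawn from (and modelled as) the
  stationary distribution, giving tip covariance
  $V_{ij} = \tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}$ with $d_{ij}$
  the patristic distance.
* **Shared $\alpha$.** The traits are PCs of a single structure, so one
  selection strength is shared across them by default; `sigma2`,
  `theta0` and the shift deltas remain per-trait.  (Whether the original
  analysis shared $\alpha$ is unstated; sharing is the more parsimonious
  default for correlated descriptors of one organ.)
* **Measurement error** is not modelled: no within-species variance
  enters the shift analysis.

`fit_fixed_config()` profiles the likelihood: for a given $\alpha$,
$\theta_0$ and $\beta$ come from generalised least squares after
whitening with the Cholesky factor of the correlation matrix, and the
ML variance per trait in closed form; $\alpha$ is then optimised on a
16-point log grid of phylogenetic half-lives (0.05x to 10x tree height)
refined by golden-section search in the bracketing interval.

**Candidate configurations.** For each $\alpha$ on the grid, the traits
and the full shift design are whitened and *forward group selection* runs
over edges (groups across traits): at each step the edge with the largest
whitened residual group-correlation enters and coefficients are refitted,
recording the nested support sets up to `s_max`.  The union over the grid,
de-duplicated and always including the empty set, is the candidate list.
A regularised group-penalised path would harvest similar nested supports;
greedy forward selection was chosen because it is deterministic,
dependency-free, and in recovery simulations places the true edges in the
candidate list in over 90% of replicates — the subsequent information
criterion, not the path, decides what survives.  On small trees (at most
1000 subsets) the candidate list is simply *all* edge subsets up to
`s_max`, which is also what makes exact-oracle tests possible.

**Scoring.** Every candidate is refitted and scored with
$\mathrm{pBIC} = -2\log \hat L + p \log n + 2 s \log m$, where $n$ is the
tip count, $m$ the edge count, $s$ the number of shifts and $p$ the free
parameter count ($q(2+s) + 1$ with shared $\alpha$).  The $2 s \log m$
term prices the combinatorial *placement* of the shifts and is what makes
the criterion conservative; the original criterion's determinant terms
are approximated by this placement penalty, and the approximation is
validated behaviourally — null simulations (100 tips, three traits,
50 replicates) select the empty configuration in over 90% of runs, and
three-shift simulations (128 tips, shifts of 4 stationary SDs on disjoint
mid-tree clades) recover the true edges essentially always.  Backward
elimination from the best candidate (drop any shift whose removal lowers
the pBIC, to a fixpoint) guards against over-selection along a single
greedy path.

Two identifiability facts the user should know: a shift on one of the two
root edges is exactly confounded with the intercept plus a shift on its
sibling (the fits tie), and shifting a large majority of tips by one
common delta is better explained as a background shift plus the
*complement* — recovery experiments must place shifts on disjoint
mid-tree clades, as `pick_clade_edges()` does.

## D-statistics

`site_pattern_sums()` accumulates frequency-weighted pattern sums per
site — ABBA $(1-p_1) p_2 p_3 (1-p_O)$, BABA $p_1 (1-p_2) p_3 (1-p_O)$,
BBAA $p_1 p_2 (1-p_3)(1-p_O)$ — per contiguous jackknife block, and
$D = (\mathrm{ABBA} - \mathrm{BABA}) / (\mathrm{ABBA} + \mathrm{BABA})$.
Three trio arrangements are supported: **BBAA** (the pair sharing derived
alleles most often are sisters, oriented so $D \ge 0$, matching the
all-positive heatmap convention; three-way ties are flagged and broken
lexicographically), **min** (smallest $|D|$ over the three possible
sister pairs), and **tree** (arrangement fixed by a given species tree).
Significance is by delete-one-block jackknife ($Z = D/SE$, normal two
sided $p$); zero jackknife variance with $D \ne 0$ yields $p = 0$ with a
degeneracy flag, and a zero pattern denominator makes the trio's $D$
undefined — reported as `NA` by the scan rather than an error.
`bh_adjust()` (a thin wrapper over `stats::p.adjust`) corrects across all
trios of one mode jointly, before heatmaps are built.  Jackknife blocks
default to contiguous twentieths of the site list; block count is
configuration, since the appropriate block size depends on linkage, which
synthetic data does not model.

## The synthetic generators — what they emulate and what they do not

* **Front outlines** are radial functions
  $r(\theta) = 1 + L(\theta)\cos(k\,\psi(\theta))$ with lobing depth
  $L(\theta) = L_0 (1 + g \sin\theta)$ modulated dorsoventrally, an
  angular warp $\psi$ biasing upper vs lower lobe angles, optional extra
  lateral lobes (7-lobed corollas), and left--right noise applied
  *anti-symmetrically* (a perturbation minus its mirror, scaled to the
  requested SD) so that `asymmetry_sd` maps exactly onto the
  antisymmetric $(b, c)$ coefficient block.
* **Side outlines** are a constant-width tube of controlled length and
  constant centreline curvature joined to two lips of controlled length
  ratio and reflex angle; parameters that would self-intersect the tube
  are rejected.
* **Trees** are pure-birth, rescaled to unit height — the simplest model
  under which OU parameters are identifiable; real chronograms are
  consumed, not inferred.
* **Traits** follow the exact OU transition recursion, so tip
  distributions are exact, not Euler-discretised.
* **Genotypes** are pattern-mixture draws (`BBAA` with probability
  $p_b$, `ABBA` with $p_d + f_e$, `BABA` with $p_d$, the rest
  uninformative), because D-statistics are functions of site-pattern
  frequencies alone; the closed-form expectation
  $D = f_e / (2 p_d + f_e)$ calibrates the estimator.  The explicit
  `p_bbaa` knob controls the concordant-pattern mass.

What the generators do **not** emulate: photographic segmentation error,
petal texture and occlusion in real outlines; linkage, rate variation,
missing data and genotyping error in real matrices; non-ultrametric or
non-binary trees.  Passing tests therefore demonstrate correctness of the
algebra and calibration of the statistics under the stated generative
models, not robustness to every artefact of real data.

## Problem sizes and numerics

The simulation studies run at sizes chosen to give stable rates while
remaining routine on a single CPU: 2000 tips for the stationary-variance
check, 2000 replicates for the 4-tip covariance check, 50 replicates of
100-tip null trees and 5 replicates of 128-tip three-shift trees for the
shift detector, 200 replicates of $10^5$ sites for the D-statistic null
calibration, and a 24-taxon demonstration pipeline.  Numerical choices:
GPA tolerance $10^{-10}$ on consensus change (max 100 iterations);
Cholesky-based whitening everywhere (no explicit inverses); the
$\alpha$ grid above with golden-section refinement and a guard that never
returns less than the grid optimum; K-means restarts re-seeded on the
rare empty-cluster collapse; floats written to CSV at 12 significant
digits to make pipeline reruns byte-identical.

## Known limitations

* One specimen tree tip per taxon: collapsing multiple conspecific
  samples is left to the user.
* No between-group or phylogenetically corrected PCA; ordinary PCA is
  the summarised method.
* No convergent-regime merging, bootstrap support for shifts, or
  Bayesian shift inference.
* No $f_4$-ratio, $f$-branch or windowed introgression scans.
* Variance fractions, cluster counts and shift counts on any *real*
  data set are data-dependent quantities; the package asserts only the
  properties its generators control.
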
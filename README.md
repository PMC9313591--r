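# petalspectrum

Tools for quantifying **flower (corolla) symmetry variation** across a
clade and studying **how that symmetry evolved** — built for botanists and
evolutionary biologists working with two-view flower outlines, a
phylogeny, and genome-wide biallelic genotypes.

Corolla symmetry in many radiations (the motivating case is the tropical
*Rhododendron* vireyas) is not a clean radial/bilateral dichotomy but a
spectrum: lobing depth, dorsoventral gradients, lateral petal doubling,
tube curvature and unequal lips all contribute.  The package turns that
spectrum into numbers and models:

* **Outline morphometrics** — landmark-guided full generalised Procrustes
  alignment, then elliptical Fourier analysis (EFA).  Each closed outline
  becomes per-harmonic quadruples `(a_n, b_n, c_n, d_n)`; with the
  bilateral axis mapped to +x, the `(b_n, c_n)` block is *exactly* the
  mirror-antisymmetric subspace, so within-specimen left–right noise is
  removed by zeroing it (`remove_asymmetric_component()`).  Harmonic
  count is calibrated to a target cumulative power fraction
  (`calibrate_harmonic_count()`, default 99%).
* **Morphospace** — per-taxon mean shapes, covariance PCA with shape
  reconstruction along axes, convex-hull clade occupancy, and K-means
  phenotype clustering where the number of clusters is chosen by
  **majority rule over ten internal validity indices**
  (`select_k_majority()`, K from 2 to 20).
* **Ornstein–Uhlenbeck shift detection** — multivariate OU model of PC
  scores on a phylogeny with optimum shifts on edges
  (`detect_shifts()`).  Candidates come from forward group-selection
  paths over a grid of selection strengths; every candidate is refitted
  by profiled maximum likelihood and scored with a **phylogenetic BIC**
  `pBIC = -2 logL + p log n + 2 s log m`, whose placement penalty makes
  it conservative (null trees select zero shifts ≥ 90% of the time).
* **Introgression** — trio **D-statistics** (ABBA–BABA),
  `D = (ABBA − BABA) / (ABBA + BABA)` from frequency-weighted site
  patterns, in three trio arrangements (most-frequent-BBAA, minimum-|D|,
  species-tree), with block-jackknife Z-scores, Benjamini–Hochberg
  correction across trios, and most-significant-per-pair heatmap
  matrices (`d_scan()`, `heatmap_matrix()`).
* **Synthetic generators** — parametric front/side corolla outlines
  (`gen_front_outline()`, `gen_side_outline()`), pure-birth trees with
  exact OU trait simulation and known shifts (`gen_tree()`,
  `sim_ou_traits()`), and pattern-mixture trio genotypes with a
  closed-form expected D (`sim_genotypes()`).  Every downstream stage is
  tested against the ground truth these provide.

## Worked example

```r
library(petalspectrum)

# six specimens, three taxa, lobing depth increasing across taxa
flowers <- lapply(1:6, function(i) {
  depth <- c(0.1, 0.12, 0.3, 0.32, 0.5, 0.52)[i]
  p <- flower_params("front", petal_count = 5, lobe_depth = depth,
                     asymmetry_sd = 0.02, n_points = 240, seed = i)
  ob <- gen_front_outline(p)
  ob$specimen_id <- paste0("spec", i)
  ob$taxon_id <- paste0("taxon", ceiling(i / 2))
  resample_uniform(canonicalize_orientation(ob), 240)
})
aligned <- gpa_align(flowers)
N <- calibrate_harmonic_count(aligned$outlines, threshold = 0.99)
cat("harmonics for 99% power:", N, "\n")
#> harmonics for 99% power: 6

coefs <- lapply(aligned$outlines, efa_forward, N = as.integer(N))
coefs <- lapply(coefs, remove_asymmetric_component)   # drop left-right noise
means <- mean_shape_per_taxon(coefs, specimen_table(aligned$outlines))
fit_pca(means)
#> <morphospace_model> 3 taxa, 24 dims; PC1..3 explain 99.4%/0.6%/0.0%

# introgression arm: simulated trio with 10% admixture excess over a 10%
# discordance baseline, so E[D] = 0.1 / (0.2 + 0.1) = 1/3
gt <- sim_genotypes(trio_sim_spec(n_sites = 1e5, p_discordance = 0.1,
                                  f_excess = 0.1, seed = 1))
ps <- site_pattern_sums(gt, c("P1", "P2", "P3"))
jk <- jackknife_significance(arrange_trio(ps, "BBAA"))
sprintf("D = %.3f (expected 1/3), Z = %.1f", jk$D, jk$Z)
#> D = 0.330 (expected 1/3), Z = 44.7
```

The first number is the harmonic count at which the aligned outlines
reach 99% cumulative Fourier power (6 here — five-lobed shapes put their
information in the low harmonics).  The PCA line shows that with only
lobing depth varying, one axis carries essentially all between-taxon
shape variance.  The D-statistic recovers the generator's closed-form
expectation with an enormous jackknife Z, as it should at 10^5 sites.

A full end-to-end run (both views, clustering, clade hulls, OU shifts,
all D modes, manifest with hashes) on bundled synthetic data:

```r
cfg <- demo_config("demo-dir", seed = 1)   # writes inputs + YAML config
res <- run_pipeline(validate_config(cfg))  # ~4 s, byte-reproducible
```

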
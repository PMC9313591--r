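Package: petalspectrum
Title: Quantifying Flower Symmetry Variation and Its Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising corolla symmetry variation across a
    clade and studying its evolution. Implements elliptical Fourier analysis
    of closed flower outlines with landmark-guided generalised Procrustes
    alignment, bilateral symmetry decomposition of Fourier coefficients,
    harmonic-power calibration, per-taxon mean shapes, principal-component
    morphospaces with convex-hull clade occupancy, K-means phenotype
    clustering with majority-rule selection of the cluster number across a
    battery of validity indices, detection of adaptive-optimum shifts on a
    phylogeny under a multivariate Ornstein-Uhlenbeck model scored by a
    phylogenetic Bayesian information criterion, and ABBA-BABA D-statistics
    with block-jackknife significance and Benjamini-Hochberg correction.
    Includes seeded synthetic generators for flower outlines, trees with
    Ornstein-Uhlenbeck traits, and trio genotype matrices so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
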
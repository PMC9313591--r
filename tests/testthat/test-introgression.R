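test_that("site-pattern sums follow the frequency weights", {
  gt1 <- genotype_table(matrix(c(0, 2, 2, 0), 1L, 4L),
                        c("P1", "P2", "P3", "OUT"), "OUT")
  ps <- site_pattern_sums(gt1, c("P1", "P2", "P3"))
  expect_equal(c(ps$abba, ps$baba, ps$bbaa), c(1, 0, 0))
  # two fixed sites: ABBA then BABA
  gt2 <- genotype_table(rbind(c(0, 2, 2, 0), c(2, 0, 2, 0)),
                        c("P1", "P2", "P3", "OUT"), "OUT")
  ps2 <- site_pattern_sums(gt2, c("P1", "P2", "P3"))
  expect_equal(c(ps2$abba, ps2$baba, ps2$bbaa), c(1, 1, 0))
  # invariant sites contribute nothing
  gt3 <- genotype_table(matrix(0L, 1L, 4L), c("P1", "P2", "P3", "OUT"), "OUT")
  ps3 <- site_pattern_sums(gt3, c("P1", "P2", "P3"))
  expect_equal(c(ps3$abba, ps3$baba, ps3$bbaa), c(0, 0, 0))
  expect_error(site_pattern_sums(gt1, c("P1", "P2", "PX")), "absent")
  expect_error(site_pattern_sums(gt1, c("P1", "P1", "P2")), "distinct")
})

test_that("intermediate frequencies and fixed dosages agree when fixed", {
  # two individuals per population, all fixed: weights equal the 0/1 case
  g <- rbind(c(0, 0, 2, 2, 2, 2, 0, 0), c(2, 2, 0, 0, 2, 2, 0, 0))
  gt <- genotype_table(g, rep(c("P1", "P2", "P3", "OUT"), each = 2L), "OUT")
  ps <- site_pattern_sums(gt, c("P1", "P2", "P3"))
  expect_equal(c(ps$abba, ps$baba, ps$bbaa), c(1, 1, 0))
})

test_that("the D-statistic is the normalised pattern difference", {
  expect_equal(d_statistic(list(abba = 120, baba = 120)), 0)
  expect_equal(d_statistic(list(abba = 300, baba = 100)), 0.5)
  expect_equal(d_statistic(list(abba = 0, baba = 5)), -1)
})

test_that("trio arrangement modes agree with hand enumeration", {
  ps <- make_pattern_sums(abba = 300, baba = 100, bbaa = 200)
  # the three arrangement Ds are 0.5, 0.2 and -1/3
  bb <- arrange_trio(ps, "BBAA")
  expect_equal(bb$D, 1 / 3, tolerance = 1e-12)
  expect_gte(bb$D, 0)
  expect_identical(bb$trio, c("C", "B", "A"))   # BC pair are sisters
  mn <- arrange_trio(ps, "min")
  expect_equal(mn$D, 0.2, tolerance = 1e-12)
  tre <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tm <- arrange_trio(ps, "tree", species_tree = tre)
  expect_identical(tm$trio[3L], "C")
  expect_equal(tm$D, 0.5, tolerance = 1e-12)
  expect_error(arrange_trio(ps, "tree"), "species tree")
  tre2 <- ape::read.tree(text = "((A:1,X:1):1,C:2);")
  expect_error(arrange_trio(ps, "tree", species_tree = tre2), "lacks")
})

test_that("swapping P1 and P2 negates D exactly", {
  for (s in 1:5) {
    sums <- petalspectrum:::with_seed(s, stats::runif(3, 0, 100))
    ps <- make_pattern_sums(sums[1L], sums[2L], sums[3L])
    d12 <- d_statistic(petalspectrum:::arrangement_sums(ps, c(1L, 2L, 3L)))
    d21 <- d_statistic(petalspectrum:::arrangement_sums(ps, c(2L, 1L, 3L)))
    expect_equal(d12, -d21, tolerance = 1e-12)
  }
})

test_that("D_min is bounded by the other modes", {
  tre <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  for (s in 1:10) {
    sums <- petalspectrum:::with_seed(100L + s, stats::runif(3, 1, 100))
    ps <- make_pattern_sums(sums[1L], sums[2L], sums[3L])
    dmin <- abs(arrange_trio(ps, "min")$D)
    expect_lte(dmin, abs(arrange_trio(ps, "BBAA")$D) + 1e-12)
    expect_lte(dmin, abs(arrange_trio(ps, "tree", species_tree = tre)$D) + 1e-12)
  }
})

test_that("jackknife significance behaves at its degenerate edges", {
  bl <- matrix(rep(c(12, 8, 5), each = 10L), 10L, 3L,
               dimnames = list(NULL, c("abba", "baba", "bbaa")))
  jk <- jackknife_significance(list(blocks = bl))
  expect_equal(jk$D, 0.2)
  expect_equal(jk$SE, 0)
  expect_true(jk$degenerate)
  expect_equal(jk$p, 0)
  expect_error(jackknife_significance(list(blocks = bl[1L, , drop = FALSE])),
               "insufficient")
  # hand check of the delete-one formula on a tiny case
  bl2 <- rbind(c(10, 5, 0), c(6, 6, 0), c(9, 3, 0))
  colnames(bl2) <- c("abba", "baba", "bbaa")
  jk2 <- jackknife_significance(list(blocks = bl2))
  tot <- colSums(bl2)
  Dm <- vapply(1:3, function(b) {
    a <- tot[1L] - bl2[b, 1L]; bb <- tot[2L] - bl2[b, 2L]
    (a - bb) / (a + bb)
  }, numeric(1))
  expect_equal(jk2$SE, sqrt(2 / 3 * sum((Dm - mean(Dm))^2)), tolerance = 1e-12)
  expect_equal(jk2$Z, jk2$D / jk2$SE, tolerance = 1e-12)
})

test_that("jackknife depends on the block partition, not site order within blocks", {
  spec <- trio_sim_spec(n_sites = 2000L, f_excess = 0.08, block_size = 100L,
                        seed = 33L)
  gt <- sim_genotypes(spec)
  ps <- site_pattern_sums(gt, c("P1", "P2", "P3"))
  # permute sites within each block
  ord <- unlist(lapply(split(seq_len(2000L), gt$blocks), function(ix)
    petalspectrum:::with_seed(7L, sample(ix))))
  gt2 <- genotype_table(gt$genotypes[ord, ], gt$populations, gt$outgroup,
                        gt$blocks[ord])
  ps2 <- site_pattern_sums(gt2, c("P1", "P2", "P3"))
  a1 <- petalspectrum:::arrangement_sums(ps, c(1L, 2L, 3L))
  a2 <- petalspectrum:::arrangement_sums(ps2, c(1L, 2L, 3L))
  expect_equal(jackknife_significance(a1), jackknife_significance(a2))
})

test_that("BH adjustment matches the step-up hand calculation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5L)), rep(1, 5L))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("heatmap matrices keep the most significant trio per pair", {
  res <- data.frame(P1 = c("a", "b", "c"), P2 = c("b", "a", "b"),
                    P3 = c("c", "c", "c"), mode = "BBAA",
                    abba = 1, baba = 1, bbaa = 1,
                    D = c(0.1, 0.4, 0.2), SE = 0.1,
                    Z = c(2, 5, 1), p = 0.1, n_blocks = 10L, p_adj = 0.2)
  hm <- heatmap_matrix(res[1L, ])
  expect_equal(sum(!is.na(hm$D)), 1L)
  hm2 <- heatmap_matrix(res[1:2, ])
  expect_equal(hm2$D["a", "c"], 0.4)   # the |Z| = 5 trio wins its cell
  expect_identical(rownames(hm2$D), sort(unique(res$P2[1:2])))
  res_bad <- res
  res_bad$mode[2L] <- "min"
  expect_error(heatmap_matrix(res_bad), "mix")
})

test_that("the all-trio scan adjusts p-values jointly", {
  # 4-population table: P4 is a noisy copy of P3, so every trio carries
  # information but the (P3, P4) sister pair is nearly identical
  spec <- trio_sim_spec(n_sites = 5000L, f_excess = 0.1, seed = 17L,
                        n_individuals = 2L)
  gt <- sim_genotypes(spec)
  p3 <- gt$genotypes[, gt$populations == "P3", drop = FALSE]
  p4 <- petalspectrum:::with_seed(18L, {
    flip <- matrix(stats::rbinom(length(p3), 1L, 0.05), nrow(p3))
    abs(p3 - 2L * flip)
  })
  gt4 <- genotype_table(cbind(gt$genotypes, p4),
                        c(gt$populations, rep("P4", 2L)), "OUT", gt$blocks)
  tab <- d_scan(gt4, "BBAA")
  expect_equal(nrow(tab), choose(4L, 3L))
  ok <- !is.na(tab$p)
  expect_true(any(ok))
  expect_true(all(tab$p_adj[ok] >= tab$p[ok] - 1e-15))
  expect_true(all(tab$D[ok] >= 0))              # BBAA-mode orientation
  expect_no_error(heatmap_matrix(tab))
})
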
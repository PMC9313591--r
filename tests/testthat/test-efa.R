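test_that("GPA superimposes similar configurations exactly", {
  tri <- rbind(c(0, 0), c(2, 0), c(1, 1.5))
  o1 <- outline(rbind(tri, c(0.5, 1)), view = "side")
  o1 <- attach_landmarks(o1, tri)
  R90 <- matrix(c(0, 1, -1, 0), 2L, 2L)
  o2 <- o1
  o2$points <- 3 * o1$points %*% R90 + 5
  res <- gpa_align(list(o1, o2))
  l1 <- res$outlines[[1L]]$points[res$outlines[[1L]]$landmarks, ]
  l2 <- res$outlines[[2L]]$points[res$outlines[[2L]]$landmarks, ]
  expect_lt(sqrt(mean((l1 - l2)^2)), 1e-9)
  # duplicates receive identical transforms
  res2 <- gpa_align(list(o1, o1, o2))
  tr <- res2$result$transforms
  expect_equal(tr[1L, -1L], tr[2L, -1L], ignore_attr = TRUE)
  expect_error(gpa_align(list(o1)), "at least 2")
  # collinear landmarks are degenerate
  bad <- outline(rbind(c(0, 0), c(1, 0), c(2, 0), c(1, 1)), view = "side")
  bad$landmarks <- c(1L, 2L, 3L)
  expect_error(gpa_align(list(bad, bad)), "collinear")
})

test_that("GPA meets its stopping contract on random sets", {
  res <- make_aligned_flowers(n = 10L, asymmetry_sd = 0.05, seed = 2L)
  expect_true(res$result$converged)
  expect_lt(abs(petalspectrum:::centroid_size(res$result$consensus) - 1), 1e-9)
  # bilateral axis on +x: consensus top and bottom landmarks differ in x only
  cons <- res$result$consensus
  expect_lt(abs(cons[4L, 2L] - cons[3L, 2L]), 1e-9)
  expect_gt(cons[4L, 1L] - cons[3L, 1L], 0)
})

test_that("a circle decomposes into its closed-form first harmonic", {
  circ <- make_circle_outline(2, 512L)
  cf <- efa_forward(circ, 8L)
  expect_lt(abs(cf$an[1L] - 2), 1e-3)
  expect_lt(abs(cf$dn[1L] - 2), 1e-3)
  expect_lt(abs(cf$bn[1L]), 1e-3)
  expect_lt(abs(cf$cn[1L]), 1e-3)
  expect_gt(harmonic_power(cf)[1L], 0.9999)
})

test_that("translation changes only the offset terms", {
  ob <- resample_uniform(gen_front_outline(
    flower_params("front", lobe_depth = 0.3, n_points = 240L)), 240L)
  sh <- ob
  sh$points <- sweep(ob$points, 2L, c(-5, 7), `+`)
  c0 <- efa_forward(ob, 24L); c1 <- efa_forward(sh, 24L)
  expect_lt(max(abs(c0$an - c1$an), abs(c0$bn - c1$bn),
                abs(c0$cn - c1$cn), abs(c0$dn - c1$dn)), 1e-12)
  expect_equal(c1$A0 - c0$A0, -5, tolerance = 1e-9)
  expect_equal(c1$C0 - c0$C0, 7, tolerance = 1e-9)
})

test_that("the inverse transform round-trips and degrades gracefully", {
  ob <- resample_uniform(gen_front_outline(
    flower_params("front", lobe_depth = 0.3, dorsoventral_gradient = 0.2,
                  n_points = 320L)), 320L)
  cs <- sqrt(sum(scale(ob$points, scale = FALSE)^2))
  rec <- efa_inverse(efa_forward(ob, 64L), 320L)
  expect_lt(mean(sqrt(rowSums((rec$points - ob$points)^2))), 1e-4 * cs)
  # round-trip error is non-increasing in N
  errs <- vapply(c(4L, 8L, 16L, 32L, 64L), function(N) {
    r <- efa_inverse(efa_forward(ob, N), 320L)
    mean(sqrt(rowSums((r$points - ob$points)^2)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  # N = 1 reconstructs an ellipse: constant turning direction
  e1 <- efa_inverse(efa_forward(ob, 1L), 100L)
  p <- e1$points
  v1 <- p[c(2:100, 1L), ] - p
  cross <- v1[, 1L] * v1[c(2:100, 1L), 2L] - v1[, 2L] * v1[c(2:100, 1L), 1L]
  expect_true(all(cross > 0) || all(cross < 0))
  # all-zero harmonics collapse to the offset point
  z <- efa_coefficients(1e-300, 0, 0, 0, A0 = 3, C0 = -2)
  z$an <- 0
  pt <- efa_inverse(z, 10L)$points
  expect_true(all(abs(pt[, 1L] - 3) < 1e-12 & abs(pt[, 2L] + 2) < 1e-12))
})

test_that("harmonic power fractions are normalised and monotone", {
  cf <- efa_coefficients(an = c(4, 2), bn = c(0, 0), cn = c(0, 0),
                         dn = c(0, 0))
  expect_equal(harmonic_power(cf), c(0.8, 1.0))
  ob <- gen_front_outline(flower_params("front", n_points = 240L))
  f <- harmonic_power(efa_forward(ob, 32L))
  expect_true(all(diff(f) >= 0))
  expect_lt(abs(f[32L] - 1), 1e-12)
  zero <- efa_coefficients(0, 0, 0, 0)
  expect_error(harmonic_power(zero), "zero total power")
})

test_that("harmonic-count calibration matches shape complexity", {
  circles <- lapply(1:4, function(i) make_circle_outline(i, 128L))
  expect_equal(as.integer(calibrate_harmonic_count(circles, 0.99, 32L)), 1L)
  flowers <- lapply(1:4, function(i)
    resample_uniform(gen_front_outline(
      flower_params("front", petal_count = 5L, lobe_depth = 0.3,
                    n_points = 240L, seed = i)), 240L))
  n99 <- calibrate_harmonic_count(flowers, 0.99, 64L)
  expect_gte(as.integer(n99), 5L)      # lobing needs the k-th harmonic
  capped <- calibrate_harmonic_count(flowers, 0.999999, 4L)
  expect_equal(as.integer(capped), 4L)
  expect_false(attr(capped, "reached"))
  expect_error(calibrate_harmonic_count(list(), 0.99), "no outlines")
})

test_that("coefficient mirroring is an involution that commutes with the transform", {
  res <- make_aligned_flowers(n = 4L, asymmetry_sd = 0.03, seed = 9L)
  ob <- res$outlines[[1L]]
  cf <- efa_forward(ob, 24L)
  expect_identical(mirror_coefficients(mirror_coefficients(cf)), cf)
  # aligned outlines have the bilateral axis on +x; mirroring the outline
  # across it must equal mirroring the coefficients
  mo <- ob
  mo$points[, 2L] <- -mo$points[, 2L]
  mo$landmarks[c(1L, 2L)] <- mo$landmarks[c(2L, 1L)]
  mo <- canonicalize_orientation(mo)
  cf2 <- efa_forward(mo, 24L)
  mc <- mirror_coefficients(cf)
  expect_lt(max(abs(cf2$an - mc$an), abs(cf2$bn - mc$bn),
                abs(cf2$cn - mc$cn), abs(cf2$dn - mc$dn)), 1e-9)
  # symmetric shapes are fixed points
  sym <- remove_asymmetric_component(cf)
  expect_identical(mirror_coefficients(sym), sym)
})

test_that("asymmetry removal zeroes exactly the antisymmetric block", {
  cf <- efa_coefficients(an = 2, bn = 0.3, cn = -0.1, dn = 1, C0 = 0.5)
  out <- remove_asymmetric_component(cf)
  expect_equal(c(out$an, out$bn, out$cn, out$dn), c(2, 0, 0, 1))
  expect_equal(out$C0, 0)
  expect_identical(remove_asymmetric_component(out), out)
  # power conservation: output power equals the symmetric-subspace power
  ob <- make_aligned_flowers(n = 3L, asymmetry_sd = 0.05,
                             seed = 4L)$outlines[[1L]]
  cf2 <- efa_forward(ob, 16L)
  powtot <- function(x) sum((x$an^2 + x$bn^2 + x$cn^2 + x$dn^2) / 2)
  out2 <- remove_asymmetric_component(cf2)
  expect_identical(powtot(out2), sum((cf2$an^2 + cf2$dn^2) / 2))
  # the output equals the coefficient-space average with the mirror
  avg <- (coef_to_vector(cf2) + coef_to_vector(mirror_coefficients(cf2))) / 2
  expect_equal(coef_to_vector(out2), avg)
  # the symmetric-removal mode keeps only the asymmetric block
  alt <- remove_asymmetric_component(cf2, component = "symmetric")
  expect_true(all(alt$an == 0) && all(alt$dn == 0))
  expect_identical(alt$bn, cf2$bn)
})

test_that("per-taxon means are coefficient-wise averages with taxon counts preserved", {
  c1 <- efa_coefficients(1, 0, 0, 1, specimen_id = "s1", view = "front")
  c2 <- efa_coefficients(3, 0, 0, 1, specimen_id = "s2", view = "front")
  st <- data.frame(specimen_id = c("s1", "s2"), taxon_id = "tx",
                   clade = "A", view = "front")
  m <- mean_shape_per_taxon(list(c1, c2), st)
  expect_length(m, 1L)
  expect_equal(m[["tx"]]$an, 2)
  # identical specimens average to themselves
  m2 <- mean_shape_per_taxon(list(c1, c1), st)
  expect_equal(m2[["tx"]]$an, c1$an)
  # 168 specimens over 95 taxa collapse to exactly 95 mean sets
  counts <- c(rep(2L, 73L), rep(1L, 22L))     # 73*2 + 22 = 168
  st3 <- data.frame(specimen_id = paste0("s", 1:168),
                    taxon_id = rep(paste0("t", 1:95), counts),
                    clade = "A", view = "front")
  cfs <- lapply(seq_len(168L), function(i)
    efa_coefficients(i, 0, 0, 1, specimen_id = paste0("s", i), view = "front"))
  expect_length(mean_shape_per_taxon(cfs, st3), 95L)
  orphan <- efa_coefficients(1, 0, 0, 1, specimen_id = "zz", view = "front")
  expect_error(mean_shape_per_taxon(list(orphan), st3), "missing")
})

test_that("coefficients are rotation-equivariant and start-point invariant", {
  ob <- resample_uniform(gen_front_outline(
    flower_params("front", lobe_depth = 0.3, dorsoventral_gradient = 0.2,
                  n_points = 240L)), 240L)
  cf <- efa_forward(ob, 16L)
  phi <- 0.7
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  rot <- ob
  rot$points <- ob$points %*% R
  cfr <- efa_forward(rot, 16L)
  for (n in c(1L, 5L, 16L)) {
    expect_equal(unname(c(cf$an[n], cf$cn[n]) %*% R),
                 unname(cbind(cfr$an[n], cfr$cn[n])), tolerance = 1e-9)
    expect_equal(unname(c(cf$bn[n], cf$dn[n]) %*% R),
                 unname(cbind(cfr$bn[n], cfr$dn[n])), tolerance = 1e-9)
  }
  # cyclic relabelling + re-canonicalisation gives identical coefficients
  shift <- 57L
  cyc <- ob
  n <- nrow(ob$points)
  ord <- c(shift:n, 1:(shift - 1L))
  cyc$points <- ob$points[ord, ]
  cyc$landmarks <- match(ob$landmarks, ord)
  cyc <- canonicalize_orientation(cyc)
  cfc <- efa_forward(cyc, 16L)
  expect_lt(max(abs(cfc$an - cf$an), abs(cfc$bn - cf$bn),
                abs(cfc$cn - cf$cn), abs(cfc$dn - cf$dn)), 1e-9)
})
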
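test_that("the design matrix matches its closed form", {
  tr <- gen_tree(4L, 2L)
  dep <- petalspectrum:::tree_depths(tr)
  X <- ou_design_matrix(tr, log(2))
  paths <- petalspectrum:::edge_paths(tr)
  for (i in 1:4) {
    on <- paths[[i]]
    expect_equal(unname(X[i, on]),
                 1 - exp(-log(2) * (dep$tip_depth[i] - dep$edge_start[on])))
    expect_true(all(X[i, setdiff(seq_len(nrow(tr$edge)), on)] == 0))
  }
  # a root edge with tip depth 1 gives 1 - exp(-ln 2) = 0.5
  root_edges <- which(dep$edge_start == 0)
  vals <- X[, root_edges]
  expect_true(all(abs(vals[vals > 0] - 0.5) < 1e-12))
  # alpha -> 0 limit: X / alpha -> T_i - s_e
  Xs <- ou_design_matrix(tr, 1e-8)
  e <- paths[[1L]][1L]
  expect_lt(abs(Xs[1L, e] / 1e-8 - (dep$tip_depth[1L] - dep$edge_start[e])),
            1e-6)
  expect_error(ou_design_matrix(tr, 0), "alpha")
})

test_that("the stationary covariance evaluates and factorises", {
  tr <- gen_tree(6L, 4L)
  V <- ou_covariance(tr, 1, 2)
  expect_equal(unname(diag(V)), rep(1, 6L))       # sigma2/(2 alpha) = 1
  D <- stats::cophenetic(tr)
  i <- which(D == max(D), arr.ind = TRUE)[1L, ]
  expect_equal(V[i[1L], i[2L]], exp(-max(D)), tolerance = 1e-12)
  for (s in 1:3) {
    trs <- gen_tree(50L, 100L + s)
    expect_no_error(chol(ou_covariance(trs, 2, 1)))
  }
  expect_error(ou_covariance(tr, -1, 1), "alpha")
})

test_that("fixed-configuration fits recover parameters and flag collinearity", {
  tr <- gen_tree(10L, 3L)
  const <- matrix(7, 10L, 1L, dimnames = list(tr$tip.label, "trait1"))
  f0 <- fit_fixed_config(tr, const, integer(0))
  expect_equal(unname(f0$theta0), 7, tolerance = 1e-6)
  expect_lt(f0$sigma2, 1e-8)
  # recovery on a known single-shift simulation
  tr2 <- gen_tree(200L, 8L)
  e <- pick_clade_edges(tr2, k = 1L, min_tips = 30L, max_tips = 80L)
  y <- sim_ou_traits(tr2, ou_sim_spec(alpha = 2, sigma2 = 1, theta0 = 0,
                                      q = 1L,
                                      shifts = data.frame(edge = e, beta = 5),
                                      seed = 6L))
  f1 <- fit_fixed_config(tr2, y, e)
  expect_lt(abs(f1$beta[1L, 1L] - 5) / 5, 0.15)
  # both root edges plus the intercept are collinear
  dep <- petalspectrum:::tree_depths(tr)
  roots <- which(dep$edge_start == 0)
  expect_error(fit_fixed_config(tr, const, roots), "collinear")
})

test_that("candidate generation honours its contracts", {
  tr <- gen_tree(60L, 5L)
  y <- sim_ou_traits(tr, ou_sim_spec(alpha = 2, sigma2 = 1, q = 2L, seed = 2L))
  cands <- candidate_configurations(tr, y, s_max = 4L)
  expect_true(any(vapply(cands, function(S) length(S) == 0L, logical(1))))
  expect_false(any(duplicated(vapply(cands, paste, character(1),
                                     collapse = "+"))))
  expect_error(candidate_configurations(tr, y, s_max = nrow(tr$edge)), "s_max")
  # a strong single shift lands in the candidate list in nearly all replicates
  hits <- 0L
  for (r in 1:10) {
    trr <- gen_tree(100L, 700L + r)
    er <- pick_clade_edges(trr, k = 1L, min_tips = 15L, max_tips = 40L)
    yr <- sim_ou_traits(trr, ou_sim_spec(alpha = 2, sigma2 = 1, q = 1L,
                                         shifts = data.frame(edge = er,
                                                             beta = 4),
                                         seed = 800L + r))
    cc <- candidate_configurations(trr, yr, s_max = 4L)
    if (any(vapply(cc, function(S) er %in% S, logical(1)))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("pBIC reduces to BIC and prices shifts as specified", {
  tr <- gen_tree(30L, 2L)
  y <- sim_ou_traits(tr, ou_sim_spec(alpha = 1, sigma2 = 1, q = 3L, seed = 3L))
  f0 <- fit_fixed_config(tr, y, integer(0))
  # s = 0: ordinary BIC of the no-shift OU fit (p = 2q + 1)
  expect_equal(score_pbic(f0),
               -2 * f0$loglik + (2 * 3 + 1) * log(30), tolerance = 1e-12)
  # equal logL, s = 0 vs s = 1 differ by exactly q log n + 2 log m
  f1 <- f0
  f1$edges <- 5L
  expect_equal(score_pbic(f1) - score_pbic(f0),
               3 * log(30) + 2 * log(58), tolerance = 1e-12)
  expect_error(score_pbic(list()), "fitted")
})

test_that("maximised likelihood is monotone over nested configurations", {
  tr <- gen_tree(40L, 6L)
  y <- sim_ou_traits(tr, ou_sim_spec(alpha = 2, sigma2 = 1, q = 2L, seed = 9L))
  es <- pick_clade_edges(tr, k = 3L, min_tips = 4L, max_tips = 15L)
  chain <- lapply(0:3, function(s) es[seq_len(s)])
  lls <- vapply(chain, function(S) fit_fixed_config(tr, y, S)$loglik,
                numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("whitened GLS equals the direct covariance solve", {
  tr <- gen_tree(15L, 8L)
  alpha <- 1.3
  y <- sim_ou_traits(tr, ou_sim_spec(alpha = alpha, sigma2 = 1, q = 1L,
                                     seed = 4L))
  e <- pick_clade_edges(tr, k = 1L, min_tips = 3L, max_tips = 8L)
  Z <- cbind(1, ou_design_matrix(tr, alpha)[, e, drop = FALSE])
  C <- exp(-alpha * stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
  # oracle: explicit inverse-covariance GLS
  Ci <- solve(C)
  beta_direct <- solve(t(Z) %*% Ci %*% Z, t(Z) %*% Ci %*% y)
  L <- chol(C)
  Zw <- backsolve(L, Z, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  beta_white <- qr.coef(qr(Zw), yw)
  expect_lt(max(abs(beta_direct - beta_white)), 1e-8)
})

test_that("detection equals exhaustive enumeration on small trees", {
  for (s in 1:3) {
    tr <- gen_tree(6L, 40L + s)
    e <- pick_clade_edges(tr, k = 1L, min_tips = 2L, max_tips = 4L)
    y <- sim_ou_traits(tr, ou_sim_spec(alpha = 3, sigma2 = 0.5, q = 2L,
                                       shifts = if (length(e))
                                         data.frame(edge = e, beta = 3)
                                       else NULL,
                                       seed = 50L + s))
    ds <- detect_shifts(tr, y, s_max = 2L)
    # independent oracle: score every edge subset of size <= 2
    subsets <- c(list(integer(0)),
                 lapply(seq_len(nrow(tr$edge)), identity),
                 utils::combn(nrow(tr$edge), 2L, simplify = FALSE))
    best <- Inf; best_S <- NULL
    for (S in subsets) {
      f <- tryCatch(fit_fixed_config(tr, y, S), error = function(e) NULL)
      if (is.null(f)) next
      p <- score_pbic(f)
      if (p < best) { best <- p; best_S <- sort(as.integer(S)) }
    }
    expect_equal(ds$pbic, best, tolerance = 1e-6)
    expect_equal(sort(ds$edges), best_S)
  }
})

test_that("results are invariant to trait-row permutation", {
  tr <- gen_tree(30L, 11L)
  y <- sim_ou_traits(tr, ou_sim_spec(alpha = 2, sigma2 = 1, q = 2L,
                                     shifts = data.frame(
                                       edge = pick_clade_edges(tr, 1L,
                                                               5L, 12L),
                                       beta = 3),
                                     seed = 12L))
  ds1 <- detect_shifts(tr, y, s_max = 3L)
  perm <- sample(nrow(y))
  ds2 <- detect_shifts(tr, y[perm, , drop = FALSE], s_max = 3L)
  expect_equal(ds1$edges, ds2$edges)
  expect_equal(ds1$pbic, ds2$pbic, tolerance = 1e-9)
})

test_that("tip-label mismatches are mapping errors", {
  tr <- gen_tree(10L, 1L)
  y <- sim_ou_traits(tr, ou_sim_spec(seed = 1L))
  rownames(y)[1L] <- "wrong"
  expect_error(detect_shifts(tr, y), "missing")
})
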
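# Detection of adaptive-optimum shifts on a phylogeny under a multivariate
# Ornstein-Uhlenbeck model.  Candidate shift configurations are harvested
# from seeded forward group-selection paths on whitened data across a grid
# of selection strengths; every candidate is refitted by profiled maximum
# likelihood and scored with a phylogenetic BIC whose placement penalty
# (2 s log m) prices the choice of s shift edges among m.

#' Ornstein-Uhlenbeck design matrix of shift effects
#'
#' Entry `(i, e)` is `1 - exp(-alpha * (T_i - s_e))` when edge `e` lies on
#' the root-to-tip path of tip `i` and 0 otherwise, where `T_i` is the tip
#' depth and `s_e` the depth of the edge's start node (shifts act from the
#' start of an edge, matching [sim_ou_traits()]).
#'
#' @param tree an [ape::phylo] tree.
#' @param alpha selection strength (> 0).
#' @return Tips-by-edges matrix.
#' @export
ou_design_matrix <- function(tree, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  nt <- ape::Ntip(tree)
  dep <- tree_depths(tree)
  paths <- edge_paths(tree)
  X <- matrix(0, nt, nrow(tree$edge))
  for (i in seq_len(nt)) {
    es <- paths[[i]]
    X[i, es] <- 1 - exp(-alpha * (dep$tip_depth[i] - dep$edge_start[es]))
  }
  rownames(X) <- tree$tip.label
  X
}

#' Stationary Ornstein-Uhlenbeck tip covariance
#'
#' `V_ij = sigma2 / (2 alpha) * exp(-alpha * d_ij)` with `d_ij` the
#' patristic distance between tips (stationary root state); symmetric
#' positive definite for distinct tips.
#'
#' @param tree an [ape::phylo] tree.
#' @param alpha,sigma2 OU parameters (> 0).
#' @return Tips-by-tips covariance matrix.
#' @export
ou_covariance <- function(tree, alpha, sigma2) {
  if (alpha <= 0 || sigma2 <= 0) stop("alpha and sigma2 must be > 0")
  D <- stats::cophenetic(tree)
  sigma2 / (2 * alpha) * exp(-alpha * D)
}

# correlation-scale matrix exp(-alpha * d_ij) and its Cholesky whitening
ou_whitener <- function(D, alpha) {
  C <- exp(-alpha * D)
  L <- chol(C)                      # upper triangular, C = t(L) %*% L
  logdet <- 2 * sum(log(diag(L)))
  list(C = C, L = L, logdet = logdet)
}

whiten <- function(L, M) backsolve(L, M, transpose = TRUE)

# profiled log-likelihood of q independent traits sharing alpha:
# GLS for (theta0, beta) and the ML variance given alpha
ou_profile_loglik <- function(alpha, D, X_builder, Y) {
  wh <- ou_whitener(D, alpha)
  Z <- X_builder(alpha)
  Zw <- whiten(wh$L, Z)
  Yw <- whiten(wh$L, Y)
  qr_z <- qr(Zw)
  if (qr_z$rank < ncol(Zw)) return(list(loglik = -Inf, singular = TRUE))
  coefs <- qr.coef(qr_z, Yw)
  res <- Yw - Zw %*% coefs
  n <- nrow(Y)
  v <- colSums(res^2) / n                       # ML scale per trait
  v <- pmax(v, 1e-300)
  ll <- sum(-n / 2 * log(2 * pi * v) - wh$logdet / 2 - n / 2)
  list(loglik = ll, coefs = coefs, v = v, singular = FALSE)
}

#' Fit an Ornstein-Uhlenbeck model with a fixed shift configuration
#'
#' For the edge set `S`, maximises the Gaussian likelihood of
#' `y = theta0 + X_S(alpha) beta + eps`, `eps ~ N(0, V(alpha, sigma2))`,
#' independently per trait with a shared `alpha`: `theta0`, `beta` and the
#' variance are profiled out by generalised least squares and `alpha` is
#' optimised on a log grid of phylogenetic half-lives refined by
#' golden-section search.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits tips-by-q trait matrix, rownames matching tip labels.
#' @param S integer vector of shift edges (row indices of `tree$edge`);
#'   may be empty.
#' @param alpha_grid optional vector of alpha values searched before
#'   refinement.
#' @return A list of class `"shift_model"`: `edges`, `alpha`, `sigma2`,
#'   `theta0`, `beta` (edges x traits), `loglik`, `n_tips`, `n_edges`,
#'   `q`, and `shared_alpha = TRUE`.
#' @export
fit_fixed_config <- function(tree, traits, S = integer(0), alpha_grid = NULL) {
  traits <- as.matrix(traits)
  Y <- align_traits(tree, traits)
  S <- sort(unique(as.integer(S)))
  if (length(S) && any(S < 1L | S > nrow(tree$edge)))
    stop("shift edge outside the tree")
  D <- stats::cophenetic(tree)
  D <- D[tree$tip.label, tree$tip.label]
  h <- max(tree_depths(tree)$tip_depth)
  if (is.null(alpha_grid)) alpha_grid <- default_alpha_grid(h)
  builder <- function(alpha) {
    if (length(S) == 0L) return(matrix(1, nrow(Y), 1L))
    cbind(1, ou_design_matrix(tree, alpha)[, S, drop = FALSE])
  }
  # collinearity is an input defect, not an optimisation failure: check at
  # a reference alpha
  ref <- ou_profile_loglik(alpha_grid[ceiling(length(alpha_grid) / 2)],
                           D, builder, Y)
  if (ref$singular)
    stop("collinear shift configuration: design matrix is rank deficient")
  lls <- vapply(alpha_grid, function(a)
    ou_profile_loglik(a, D, builder, Y)$loglik, numeric(1))
  i <- which.max(lls)
  lo <- alpha_grid[max(1L, i - 1L)]; hi <- alpha_grid[min(length(alpha_grid), i + 1L)]
  opt <- stats::optimize(function(la)
    ou_profile_loglik(exp(la), D, builder, Y)$loglik,
    interval = log(c(lo, hi)), maximum = TRUE, tol = 1e-6)
  alpha <- exp(opt$maximum)
  fit <- ou_profile_loglik(alpha, D, builder, Y)
  if (fit$loglik < max(lls)) {           # guard: keep the grid optimum
    alpha <- alpha_grid[i]
    fit <- ou_profile_loglik(alpha, D, builder, Y)
  }
  coefs <- matrix(fit$coefs, ncol = ncol(Y))
  beta <- if (length(S)) coefs[-1L, , drop = FALSE] else
    matrix(0, 0L, ncol(Y))
  rownames(beta) <- if (length(S)) paste0("edge", S) else character(0)
  structure(list(edges = S, alpha = alpha, sigma2 = 2 * alpha * fit$v,
                 theta0 = coefs[1L, ], beta = beta, loglik = fit$loglik,
                 n_tips = nrow(Y), n_edges = nrow(tree$edge), q = ncol(Y),
                 shared_alpha = TRUE),
            class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("<shift_model> %d shift(s) [%s], alpha = %.4g, logL = %.4f%s\n",
              length(x$edges), paste(x$edges, collapse = ", "),
              x$alpha, x$loglik,
              if (!is.null(x$pbic)) sprintf(", pBIC = %.4f", x$pbic) else ""))
  invisible(x)
}

align_traits <- function(tree, traits) {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop("traits must have rownames matching the tree tip labels")
  miss <- setdiff(tree$tip.label, rownames(traits))
  if (length(miss))
    stop("tips missing from traits: ", paste(miss, collapse = ", "))
  if (any(!is.finite(traits))) stop("traits must be complete (no NA)")
  traits[tree$tip.label, , drop = FALSE]
}

default_alpha_grid <- function(height, n = 16L) {
  # phylogenetic half-life ln(2)/alpha from 0.05x to 10x tree height
  hl <- exp(seq(log(0.05 * height), log(10 * height), length.out = n))
  rev(log(2) / hl)
}

#' Candidate shift configurations from forward selection paths
#'
#' For each selection strength on a log-spaced grid of phylogenetic
#' half-lives, whitens the traits and the shift design by the inverse
#' Cholesky of the OU correlation and runs forward group selection (edges
#' as groups across the traits): at each step the edge with the largest
#' whitened residual group-correlation enters, the coefficients are
#' refitted, and the support is recorded.  The union of the nested
#' supports over the grid, de-duplicated, always including the empty set,
#' is returned.  When exhaustive enumeration of all subsets up to `s_max`
#' is small (at most `exhaustive_limit` subsets) it is used instead.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits tips-by-q trait matrix.
#' @param s_max maximum number of shifts (default 10).
#' @param alpha_grid optional grid of selection strengths.
#' @param exhaustive_limit subset-count threshold below which all edge
#'   subsets of size at most `s_max` are enumerated.
#' @return A list of integer edge vectors (first element: `integer(0)`).
#' @export
candidate_configurations <- function(tree, traits, s_max = 10L,
                                     alpha_grid = NULL,
                                     exhaustive_limit = 1000L) {
  Y <- align_traits(tree, traits)
  m <- nrow(tree$edge)
  s_max <- as.integer(s_max)
  if (s_max < 1L) stop("s_max must be >= 1")
  if (s_max >= m) stop("s_max must be smaller than the edge count")
  n_subsets <- sum(choose(m, 0:s_max))
  if (n_subsets <= exhaustive_limit) {
    cands <- list(integer(0))
    for (s in seq_len(s_max))
      cands <- c(cands, utils::combn(m, s, simplify = FALSE))
    return(cands)
  }
  h <- max(tree_depths(tree)$tip_depth)
  if (is.null(alpha_grid)) alpha_grid <- default_alpha_grid(h)
  D <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
  supports <- list(integer(0))
  for (alpha in alpha_grid) {
    wh <- ou_whitener(D, alpha)
    X <- ou_design_matrix(tree, alpha)
    Xw <- whiten(wh$L, X)
    Yw <- whiten(wh$L, Y)
    ones_w <- whiten(wh$L, matrix(1, nrow(Y), 1L))
    S <- integer(0)
    Zw <- ones_w
    repeat {
      qr_z <- qr(Zw)
      R <- Yw - Zw %*% qr.coef(qr_z, Yw)
      cn <- sqrt(colSums(Xw^2))
      score <- sqrt(rowSums(crossprod(Xw, R)^2)) / pmax(cn, 1e-12)
      score[S] <- -Inf
      score[cn < 1e-10] <- -Inf
      e <- which.max(score)
      Zc <- cbind(Zw, Xw[, e])
      if (qr(Zc)$rank < ncol(Zc)) { score[e] <- -Inf; next }
      S <- c(S, e)
      Zw <- Zc
      supports <- c(supports, list(sort(S)))
      if (length(S) >= s_max) break
    }
  }
  unique(supports)
}

#' Phylogenetic BIC of a fitted shift model
#'
#' `pBIC = -2 logL + p log n + 2 s log m` with `n` tips, `m` edges,
#' `s` shift edges, and `p` the count of free numeric parameters (per
#' trait: `sigma2`, `theta0` and `s` optimum deltas, plus one shared
#' `alpha`).  The `2 s log m` term prices the combinatorial placement of
#' the shifts; lower is better.  With `s = 0` this is the ordinary BIC of
#' the no-shift OU fit.
#'
#' @param model a [fit_fixed_config()] result.
#' @return A number.
#' @export
score_pbic <- function(model) {
  if (!inherits(model, "shift_model") || is.null(model$loglik))
    stop("model must be a fitted shift_model")
  s <- length(model$edges)
  p <- model$q * (2L + s) + 1L
  -2 * model$loglik + p * log(model$n_tips) + 2 * s * log(model$n_edges)
}

#' Detect optimum shifts on a phylogeny
#'
#' Generates candidate configurations ([candidate_configurations()]),
#' refits each by profiled maximum likelihood ([fit_fixed_config()]),
#' scores them with the phylogenetic BIC ([score_pbic()]), applies
#' backward elimination from the best configuration (any shift whose
#' removal lowers the pBIC is dropped, to a fixpoint), and returns the
#' minimal-pBIC model with the full scored candidate table attached.
#'
#' @param tree an [ape::phylo] tree with >= 4 tips.
#' @param traits tips-by-q trait matrix (rownames = tip labels).
#' @param s_max maximum number of shifts.
#' @param seed integer seed (the search is deterministic; kept for
#'   interface stability).
#' @param alpha_grid optional selection-strength grid.
#' @return The best `"shift_model"` with elements `pbic` and `candidates`
#'   (a data.frame: configuration, size, loglik, pbic).
#' @export
detect_shifts <- function(tree, traits, s_max = 10L, seed = 1L,
                          alpha_grid = NULL) {
  if (ape::Ntip(tree) < 4L) stop("need at least 4 tips for shift detection")
  Y <- align_traits(tree, traits)
  cands <- candidate_configurations(tree, Y, s_max = s_max,
                                    alpha_grid = alpha_grid)
  fits <- lapply(cands, function(S)
    tryCatch(fit_fixed_config(tree, Y, S, alpha_grid = alpha_grid),
             error = function(e) NULL))
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]; cands <- cands[keep]
  pbics <- vapply(fits, score_pbic, numeric(1))
  tab <- data.frame(
    config = vapply(cands, function(S) paste(S, collapse = "+"), character(1)),
    size = lengths(cands),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    pbic = pbics)
  best <- fits[[which.min(pbics)]]
  best_pbic <- min(pbics)
  # backward elimination to a fixpoint
  repeat {
    if (length(best$edges) == 0L) break
    improved <- FALSE
    for (e in best$edges) {
      S2 <- setdiff(best$edges, e)
      f2 <- fit_fixed_config(tree, Y, S2, alpha_grid = alpha_grid)
      p2 <- score_pbic(f2)
      if (p2 < best_pbic) {
        best <- f2; best_pbic <- p2; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  best$pbic <- best_pbic
  best$candidates <- tab
  best
}
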
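#' Principal-component morphospace of shape coefficients
#'
#' Eigendecomposition of the covariance of centred, unscaled coefficient
#' vectors (elliptical Fourier coefficients are commensurate after
#' Procrustes scaling, so no correlation scaling is applied).  Loadings
#' follow a deterministic sign convention: the largest-magnitude entry of
#' each loading is positive.
#'
#' @param mean_shapes either a named list of per-taxon [efa_coefficients()]
#'   (see [mean_shape_per_taxon()]) or a numeric matrix with one row per
#'   taxon.
#' @return A list of class `"morphospace_model"` with `mean`, orthonormal
#'   `loadings`, `eigenvalues`, per-taxon `scores`, `var_frac`, and (for
#'   coefficient input) a `template` used by [reconstruct_axis_shape()].
#' @export
fit_pca <- function(mean_shapes) {
  template <- NULL
  if (is.list(mean_shapes) && !is.data.frame(mean_shapes)) {
    template <- mean_shapes[[1L]]
    x <- t(vapply(mean_shapes, coef_to_vector,
                  numeric(4L * mean_shapes[[1L]]$N)))
    rownames(x) <- vapply(mean_shapes, function(cf) cf$taxon_id, character(1))
  } else {
    x <- as.matrix(mean_shapes)
    if (is.null(rownames(x))) rownames(x) <- paste0("t", seq_len(nrow(x)))
  }
  if (nrow(x) < 3L) stop("need at least 3 taxa for a morphospace")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  ev <- pc$sdev^2
  structure(list(mean = pc$center, loadings = load, eigenvalues = ev,
                 scores = scores, var_frac = ev / sum(ev),
                 template = template),
            class = "morphospace_model")
}

#' @export
print.morphospace_model <- function(x, ...) {
  k <- min(3L, length(x$var_frac))
  cat(sprintf("<morphospace_model> %d taxa, %d dims; PC1..%d explain %s\n",
              nrow(x$scores), length(x$mean), k,
              paste(sprintf("%.1f%%", 100 * x$var_frac[seq_len(k)]),
                    collapse = "/")))
  invisible(x)
}

#' Project a coefficient vector into a morphospace
#'
#' `scores = t(loadings) %*% (x - mean)`; projecting the model mean gives
#' the zero vector.
#'
#' @param model a [fit_pca()] model.
#' @param x an [efa_coefficients()] or numeric vector matching the model
#'   dimension.
#' @return Numeric score vector (one entry per component).
#' @export
project_scores <- function(model, x) {
  if (inherits(x, "efa_coefficients")) x <- coef_to_vector(x)
  if (length(x) != length(model$mean))
    stop(sprintf("dimension mismatch: %d vs model %d",
                 length(x), length(model$mean)))
  drop(crossprod(model$loadings, x - model$mean))
}

#' Reconstruct the outline at a position along a principal axis
#'
#' Inverse Fourier transform of `mean + multiple * sd_axis * loading_axis`
#' where `sd_axis` is the square root of the axis eigenvalue.
#' `multiple = 0` returns the mean shape.
#'
#' @param model a [fit_pca()] model fitted on coefficient input.
#' @param axis component index.
#' @param multiple position in standard deviations along the axis.
#' @param n_points reconstruction vertex count.
#' @return An [outline()].
#' @export
reconstruct_axis_shape <- function(model, axis, multiple = 0, n_points = 300L) {
  if (axis < 1L || axis > ncol(model$loadings)) stop("axis out of range")
  if (is.null(model$template))
    stop("model was not fitted on coefficient input; no shape template")
  v <- model$mean + multiple * sqrt(model$eigenvalues[axis]) *
    model$loadings[, axis]
  efa_inverse(vector_to_coef(v, template = model$template), n_points)
}

#' Convex-hull morphospace occupancy per clade
#'
#' 2D convex hull of each clade's taxa on the chosen score axes, with the
#' shoelace area.  Clades with fewer than 3 taxa (or collinear taxa) are
#' flagged degenerate with area 0.
#'
#' @param scores score matrix with taxa as rownames (e.g. `model$scores`).
#' @param clades named character vector mapping taxon to clade (or a
#'   data.frame with columns `taxon_id`, `clade`).
#' @param axes pair of column indices (default `c(1, 2)`).
#' @return A data.frame (clade, n_taxa, area, degenerate) with the hull
#'   vertex coordinates attached as attribute `"hulls"` (a named list).
#' @export
clade_hull_occupancy <- function(scores, clades, axes = c(1L, 2L)) {
  if (is.data.frame(clades)) {
    clades <- stats::setNames(as.character(clades$clade), clades$taxon_id)
  }
  taxa <- rownames(scores)
  miss <- setdiff(taxa, names(clades))
  if (length(miss))
    stop("taxa with unknown clade: ", paste(miss, collapse = ", "))
  xy <- scores[, axes, drop = FALSE]
  out <- lapply(split(taxa, clades[taxa]), function(tx) {
    p <- xy[tx, , drop = FALSE]
    degen <- nrow(p) < 3L
    area <- 0; hull <- p
    if (!degen) {
      h <- grDevices::chull(p)
      hull <- p[h, , drop = FALSE]
      area <- abs(signed_area(hull))
      degen <- area == 0
    }
    list(row = data.frame(clade = clades[tx[1L]], n_taxa = nrow(p),
                          area = area, degenerate = degen), hull = hull)
  })
  res <- do.call(rbind, lapply(out, `[[`, "row"))
  rownames(res) <- NULL
  attr(res, "hulls") <- lapply(out, `[[`, "hull")
  res
}

# squared Euclidean distances to a set of centres
dist2_to <- function(x, centres) {
  outer(rowSums(x^2), rep(1, nrow(centres))) +
    outer(rep(1, nrow(x)), rowSums(centres^2)) - 2 * x %*% t(centres)
}

kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centres <- matrix(NA_real_, K, ncol(x))
  centres[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centres[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (k in seq_len(K - 1L) + 1L) {
    pr <- pmax(d2, 0)
    i <- if (sum(pr) > 0) sample.int(n, 1L, prob = pr) else sample.int(n, 1L)
    centres[k, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centres[k, ], n, ncol(x), byrow = TRUE))^2))
  }
  centres
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd iterations from `restarts` k-means++ seedings, keeping the
#' solution with the smallest within-cluster sum of squares.  Deterministic
#' under a fixed seed.  A restart that collapses to an empty cluster is
#' repaired by re-seeding.
#'
#' @param x numeric matrix of points (rows).
#' @param K number of clusters, `2 <= K <= nrow(x) - 1`.
#' @param restarts number of seeded initialisations.
#' @param seed integer RNG seed.
#' @return A list with `labels` (named by rownames of `x`), `centroids`,
#'   `wss` (total within-cluster sum of squares) and `K`.
#' @export
kmeans_fit <- function(x, K, restarts = 10L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  K <- as.integer(K)
  if (K < 1L || K > n - 1L)
    stop(sprintf("K must be between 1 and n - 1 = %d", n - 1L))
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- NULL
      for (attempt in 1:5) {
        init <- kmeanspp_init(x, K)
        km <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(km) && all(km$size > 0L)) break
        km <- NULL
      }
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed to produce a valid partition")
    labels <- best$cluster
    names(labels) <- rownames(x)
    list(labels = labels, centroids = best$centers,
         wss = best$tot.withinss, K = K)
  })
}

#' Select the number of clusters by majority rule over validity indices
#'
#' Fits K-means for every K in `[K_min, K_max]` and lets each internal
#' validity index in the battery vote for its best K (each index with its
#' standard optimum direction; the gap statistic uses seeded uniform
#' reference sets).  The chosen K is the modal vote, ties broken toward
#' the smaller K.
#'
#' @param x numeric matrix of points (rows = taxa).
#' @param K_min,K_max candidate range (K_max is clamped to `nrow(x) - 1`
#'   with a warning when necessary).
#' @param indices character vector naming the battery (default: all ten of
#'   `calinski_harabasz`, `silhouette`, `davies_bouldin`, `dunn`,
#'   `c_index`, `gap`, `hartigan`, `krzanowski_lai`, `ball_hall`, `xu`).
#' @param seed integer RNG seed (k-means restarts and gap references).
#' @param restarts k-means restarts per K.
#' @param gap_B number of gap-statistic reference data sets.
#' @return A list of class `"cluster_report"`: `K_min`, `K_max`, `votes`
#'   (index -> best K), `chosen_k`, `vote_margin`, `labels`, `centroids`.
#' @export
select_k_majority <- function(x, K_min = 2L, K_max = 20L,
                              indices = names(validity_indices()),
                              seed = 1L, restarts = 10L, gap_B = 50L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 points")
  K_min <- as.integer(K_min); K_max <- as.integer(K_max)
  if (K_max > n - 1L) {
    warning(sprintf("K_max lowered to %d (n - 1)", n - 1L))
    K_max <- n - 1L
  }
  if (K_min > K_max) stop("K_min exceeds the feasible K_max")
  battery <- validity_indices()
  unknown <- setdiff(indices, names(battery))
  if (length(unknown)) stop("unknown indices: ", paste(unknown, collapse = ", "))
  Ks <- K_min:K_max
  fits <- lapply(Ks, function(K) kmeans_fit(x, K, restarts, seed + K))
  names(fits) <- Ks
  # within-cluster SS for K - 1 and K + 1 neighbours used by some indices
  wss <- vapply(fits, `[[`, numeric(1), "wss")
  wss_lo <- if (K_min == 2L) sum(scale(x, scale = FALSE)^2)
            else kmeans_fit(x, K_min - 1L, restarts, seed)$wss
  wss_hi <- if (K_max + 1L <= n - 1L)
    kmeans_fit(x, K_max + 1L, restarts, seed + K_max + 1L)$wss else NA_real_
  dmat <- as.matrix(stats::dist(x))
  ctx <- list(x = x, fits = fits, Ks = Ks, wss = wss, wss_lo = wss_lo,
              wss_hi = wss_hi, dmat = dmat, seed = seed, gap_B = gap_B)
  votes <- vapply(indices, function(nm) battery[[nm]](ctx), numeric(1))
  tab <- table(factor(votes, levels = Ks))
  chosen <- as.integer(names(tab)[which.max(tab)])  # which.max: first = smaller K
  labels <- fits[[as.character(chosen)]]$labels
  structure(list(K_min = K_min, K_max = K_max,
                 votes = data.frame(index = indices, best_k = unname(votes)),
                 chosen_k = chosen,
                 vote_margin = max(tab) / length(votes),
                 labels = labels,
                 centroids = fits[[as.character(chosen)]]$centroids),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> chosen K = %d (%.0f%% of %d index votes), range %d..%d\n",
              x$chosen_k, 100 * x$vote_margin, nrow(x$votes), x$K_min, x$K_max))
  invisible(x)
}
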
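# Landmark-guided generalised Procrustes alignment.  The similarity
# transform is estimated on the landmark configurations only and then
# applied to the whole outlines, mirroring the landmark-then-Fourier order
# of outline morphometrics workflows.

# optimal 2D rotation matrix turning configuration b onto a (least squares,
# rotation only -- reflections are never introduced by alignment)
fit_rotation <- function(a, b) {
  num <- sum(a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  den <- sum(b[, 1L] * a[, 1L] + b[, 2L] * a[, 2L])
  phi <- atan2(num, den)
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
}

centroid_size <- function(cfg) sqrt(sum(scale(cfg, scale = FALSE)^2))

#' Generalised Procrustes alignment of outlines by their landmarks
#'
#' Full GPA on the landmark configurations (translate to the centroid,
#' scale to unit centroid size, rotate by the 2D orthogonal Procrustes
#' solution against an evolving consensus, iterate until the consensus
#' change drops below `tol`), with each specimen's fitted similarity
#' transform applied to its whole outline.  After convergence the whole
#' set is rigidly rotated so the consensus bilateral axis lies along +x:
#' for front views the top-to-bottom landmark direction, for side views
#' the direction from the tube base to the midpoint of the two lip tips.
#'
#' @param outlines list of >= 2 [outline()] objects of one view, landmarks
#'   attached.
#' @param max_iter maximum GPA iterations.
#' @param tol consensus-change convergence tolerance (root-mean-square).
#' @return A list with `outlines` (aligned), and `result` containing the
#'   per-specimen transforms (`scale`, `angle`, `tx`, `ty`), the consensus
#'   configuration (unit centroid size), `iterations` and `converged`.
#' @export
gpa_align <- function(outlines, max_iter = 100L, tol = 1e-10) {
  if (length(outlines) < 2L) stop("need at least 2 outlines to align")
  views <- vapply(outlines, function(ob) ob$view, character(1))
  if (length(unique(views)) != 1L) stop("all outlines must share one view")
  view <- views[1L]
  for (ob in outlines) validate_outline(ob, require_landmarks = TRUE)
  cfgs <- lapply(outlines, function(ob) ob$points[ob$landmarks, , drop = FALSE])
  k <- nrow(cfgs[[1L]])
  cents <- lapply(cfgs, function(cf) colMeans(cf))
  sizes <- vapply(cfgs, centroid_size, numeric(1))
  if (any(sizes == 0)) stop("degenerate landmark configuration with zero size")
  norm_cfgs <- mapply(function(cf, ct, sz) sweep(cf, 2L, ct) / sz,
                      cfgs, cents, sizes, SIMPLIFY = FALSE)
  for (cf in norm_cfgs) {
    sv <- svd(cf)$d
    if (sv[2L] < 1e-12 * sv[1L])
      stop("degenerate (collinear) landmark configuration")
  }
  rots <- rep(list(diag(2)), length(cfgs))
  consensus <- norm_cfgs[[1L]]
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    rots <- lapply(norm_cfgs, function(cf) fit_rotation(consensus, cf))
    rotated <- mapply(function(cf, R) cf %*% R, norm_cfgs, rots, SIMPLIFY = FALSE)
    new_cons <- Reduce(`+`, rotated) / length(rotated)
    new_cons <- scale(new_cons, scale = FALSE)
    new_cons <- new_cons / centroid_size(new_cons)
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  # re-fit rotations against the final consensus
  rots <- lapply(norm_cfgs, function(cf) fit_rotation(consensus, cf))
  # global rotation putting the bilateral axis on +x
  axis_vec <- if (view == "front") {
    consensus[4L, ] - consensus[3L, ]          # top -> bottom
  } else {
    (consensus[2L, ] + consensus[3L, ]) / 2 - consensus[1L, ]
  }
  phi <- atan2(axis_vec[2L], axis_vec[1L])
  # right-multiplication of row vectors by this matrix rotates by -phi,
  # sending the consensus axis direction onto +x
  Rg <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  consensus <- consensus %*% Rg
  aligned <- vector("list", length(outlines))
  tr <- data.frame(specimen_id = character(length(outlines)),
                   scale = numeric(length(outlines)),
                   angle = numeric(length(outlines)),
                   tx = numeric(length(outlines)),
                   ty = numeric(length(outlines)))
  for (i in seq_along(outlines)) {
    R <- rots[[i]] %*% Rg
    ob <- outlines[[i]]
    pts <- sweep(ob$points, 2L, cents[[i]]) %*% R / sizes[i]
    ob$points <- pts
    aligned[[i]] <- ob
    tr$specimen_id[i] <- ob$specimen_id
    tr$scale[i] <- 1 / sizes[i]
    tr$angle[i] <- atan2(R[1L, 2L], R[1L, 1L])
    tr$tx[i] <- -cents[[i]][1L]; tr$ty[i] <- -cents[[i]][2L]
  }
  list(outlines = aligned,
       result = list(transforms = tr, consensus = consensus,
                     iterations = iter, converged = converged,
                     view = view))
}
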
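# Parametric corolla outline generators.  These emulate the qualitative
# phenotype space of tropical Rhododendron corollas -- pentamerous to
# lateral-doubled front views, tubular side profiles with curved tubes and
# unequal lips -- and give every downstream stage ground-truth inputs.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rot2 <- function(v, phi) {
  c(cos(phi) * v[1L] - sin(phi) * v[2L],
    sin(phi) * v[1L] + cos(phi) * v[2L])
}

#' Parameters of a synthetic flower outline
#'
#' Bundles the knobs of the corolla generators.  Front views are radial
#' functions `r(theta) = 1 + L(theta) * cos(k * theta)` with lobing depth
#' modulated dorsoventrally; side views are a constant-width tube joined to
#' an upper and a lower lip.  Front views ignore the tube fields and side
#' views ignore the petal fields.
#'
#' @param view `"front"` or `"side"`.
#' @param petal_count integer >= 3; number of corolla lobes (front).
#' @param lobe_depth lobing depth as a fraction of the mean radius, in
#'   `[0, 1)` (front).
#' @param dorsoventral_gradient unitless gradient `g`; lobing depth becomes
#'   `lobe_depth * (1 + g * sin(theta))`, so positive values deepen upper
#'   lobes (front). 0 gives radially uniform depth.
#' @param upper_lower_angle_bias radians; angular warp widening the angles
#'   between upper lobes relative to lower ones, left-right symmetric (front).
#' @param lateral_doubling logical; adds two extra lateral lobes, giving a
#'   7-lobed corolla from a pentamerous base (front).
#' @param tube_length tube centreline arc length as a multiple of the
#'   aperture width (side), >= 0.
#' @param tube_curvature signed constant curvature of the tube centreline
#'   (side); positive bends adaxially (up).
#' @param upper_lobe_excess length ratio of the upper to the lower lip
#'   (side); 1 means equal lips.
#' @param reflex_angle radians; how far both lips bend outward from the
#'   tube axis (side).
#' @param asymmetry_sd standard deviation of the radial left-right
#'   perturbation noise, applied anti-symmetrically about the vertical
#'   axis (front).
#' @param n_points number of outline vertices; must be a multiple of 4 and
#'   at least `8 * petal_count` for front views (no lobe aliasing).
#' @param seed integer RNG seed for the noise.
#' @return A list of class `"flower_params"`.
#' @export
flower_params <- function(view = c("front", "side"), petal_count = 5L,
                          lobe_depth = 0.3, dorsoventral_gradient = 0,
                          upper_lower_angle_bias = 0, lateral_doubling = FALSE,
                          tube_length = 2, tube_curvature = 0,
                          upper_lobe_excess = 1, reflex_angle = 0,
                          asymmetry_sd = 0, n_points = 300L, seed = 1L) {
  view <- match.arg(view)
  p <- list(view = view, petal_count = as.integer(petal_count),
            lobe_depth = lobe_depth,
            dorsoventral_gradient = dorsoventral_gradient,
            upper_lower_angle_bias = upper_lower_angle_bias,
            lateral_doubling = isTRUE(lateral_doubling),
            tube_length = tube_length, tube_curvature = tube_curvature,
            upper_lobe_excess = upper_lobe_excess, reflex_angle = reflex_angle,
            asymmetry_sd = asymmetry_sd, n_points = as.integer(n_points),
            seed = as.integer(seed))
  class(p) <- "flower_params"
  if (p$petal_count < 3L) stop("petal_count must be >= 3")
  if (p$lobe_depth < 0 || p$lobe_depth >= 1) stop("lobe_depth must be in [0, 1)")
  if (p$tube_length < 0) stop("tube_length must be >= 0")
  if (p$asymmetry_sd < 0) stop("asymmetry_sd must be >= 0")
  if (p$n_points < 64L) stop("n_points must be >= 64")
  if (p$n_points %% 4L != 0L) stop("n_points must be a multiple of 4")
  p
}

#' Generate a front-view corolla outline
#'
#' Builds the closed counter-clockwise radial outline
#' `r(theta) = 1 + L(theta) * cos(k * psi(theta))` with
#' `L(theta) = lobe_depth * (1 + g * sin(theta))`, a lobe phase placing one
#' lobe at the top, an optional pair of extra lateral lobes
#' (`lateral_doubling`), and per-vertex radial noise of standard deviation
#' `asymmetry_sd` applied anti-symmetrically about the vertical axis, so
#' that noiseless outlines are exactly mirror-symmetric.  Four landmarks
#' are attached: left-middle, right-middle, top, bottom.
#'
#' @param params a [flower_params()] with `view = "front"`.
#' @return An [outline()] starting at the top landmark.
#' @export
gen_front_outline <- function(params) {
  p <- params
  if (!inherits(p, "flower_params")) stop("params must be a flower_params object")
  if (p$view != "front") stop("gen_front_outline requires view = 'front'")
  k <- p$petal_count
  n <- p$n_points
  if (n < 8L * k)
    stop(sprintf("n_points = %d aliases %d lobes; need n_points >= %d", n, k, 8L * k))
  j <- seq_len(n) - 1L
  theta <- pi / 2 + 2 * pi * j / n          # start at top, counter-clockwise
  psi <- theta + p$upper_lower_angle_bias * cos(theta)
  L <- p$lobe_depth * (1 + p$dorsoventral_gradient * sin(theta))
  r <- 1 + L * cos(k * (psi - pi / 2))      # one lobe points up
  if (p$lateral_doubling) {
    # two extra lateral lobes as narrow angular bumps at theta = 0 and pi
    w <- 0.08
    d0 <- pmin(abs(theta %% (2 * pi)), 2 * pi - abs(theta %% (2 * pi)))
    dp <- abs(((theta - pi) + pi) %% (2 * pi) - pi)
    amp <- max(p$lobe_depth, 0.15)
    r <- r + amp * (exp(-d0^2 / (2 * w^2)) + exp(-dp^2 / (2 * w^2)))
  }
  if (p$asymmetry_sd > 0) {
    delta <- with_seed(p$seed, stats::rnorm(n, sd = p$asymmetry_sd))
    mirror <- ((n - j) %% n) + 1L           # index of theta -> pi - theta
    r <- r + (delta - delta[mirror]) / sqrt(2)
  }
  if (any(r <= 0))
    stop("parameters produce a non-positive radius; reduce lobe_depth/gradient/noise")
  pts <- cbind(r * cos(theta), r * sin(theta))
  lms <- c(n / 4L + 1L,       # left-middle  (theta = pi)
           3L * n / 4L + 1L,  # right-middle (theta = 0)
           1L,                # top          (theta = pi/2)
           n / 2L + 1L)       # bottom       (theta = 3pi/2)
  outline(pts, view = "front", landmarks = lms)
}

# one lip lobe: a tapering strip with an elliptic rounded tip.
# s = +1 upper, -1 lower; returns list(points going base-outer -> tip ->
# base-inner, tip point).
lip_points <- function(cm, tau, nu, s, len, flare, width, n_u = 24L) {
  dir <- rot2(tau, s * flare)
  out_vec <- rot2(dir, s * pi / 2)
  h <- 3 * width / 16
  centre_base <- cm + s * (5 * width / 16) * nu
  u <- seq(0, 1, length.out = n_u)
  hw <- h * sqrt(pmax(0, 1 - u^2))
  cx <- centre_base[1L] + u * len * dir[1L]
  cy <- centre_base[2L] + u * len * dir[2L]
  outer <- cbind(cx + hw * out_vec[1L], cy + hw * out_vec[2L])
  inner <- cbind(cx - hw * out_vec[1L], cy - hw * out_vec[2L])
  tip <- c(centre_base + len * dir)
  if (s < 0) list(pts = rbind(outer, inner[rev(seq_len(n_u - 1L)), ]), tip = tip)
  else       list(pts = rbind(inner, outer[rev(seq_len(n_u - 1L)), ]), tip = tip)
}

#' Generate a side-view corolla outline
#'
#' Builds a constant-width tube (centreline of arc length `tube_length`
#' aperture-widths at constant curvature `tube_curvature`) joined to an
#' upper and a lower lip whose lengths differ by `upper_lobe_excess` and
#' which bend outward by `reflex_angle`.  Three landmarks are attached:
#' tube base, upper-lip tip, lower-lip tip.  With zero curvature, equal
#' lips and zero reflex the outline is exactly symmetric about the tube
#' axis.
#'
#' @param params a [flower_params()] with `view = "side"`.
#' @return An [outline()] with `n_points` vertices starting at the tube base.
#' @export
gen_side_outline <- function(params) {
  p <- params
  if (!inherits(p, "flower_params")) stop("params must be a flower_params object")
  if (p$view != "side") stop("gen_side_outline requires view = 'side'")
  w <- 1                                    # aperture width sets the scale
  len <- p$tube_length * w
  kap <- p$tube_curvature
  if (abs(kap) * w / 2 >= 1)
    stop("tube self-intersects: |curvature| must be < 2 / width")
  if (abs(kap) * len >= pi)
    stop("tube self-intersects: |curvature| * length must be < pi")
  m <- max(24L, ceiling(len * 32))
  t <- seq(0, len, length.out = m + 1L)
  if (kap == 0) {
    cx <- t; cy <- rep(0, m + 1L)
    taux <- rep(1, m + 1L); tauy <- rep(0, m + 1L)
  } else {
    cx <- sin(kap * t) / kap; cy <- (1 - cos(kap * t)) / kap
    taux <- cos(kap * t); tauy <- sin(kap * t)
  }
  nux <- -tauy; nuy <- taux
  upper_edge <- cbind(cx + (w / 2) * nux, cy + (w / 2) * nuy)
  lower_edge <- cbind(cx - (w / 2) * nux, cy - (w / 2) * nuy)
  cm <- c(cx[m + 1L], cy[m + 1L])
  tau_end <- c(taux[m + 1L], tauy[m + 1L])
  nu_end <- c(nux[m + 1L], nuy[m + 1L])
  lip_lower_len <- 0.9 * w
  lip_upper_len <- p$upper_lobe_excess * lip_lower_len
  flare <- 0.35 + p$reflex_angle
  lo <- lip_points(cm, tau_end, nu_end, -1, lip_lower_len, flare, w)
  up <- lip_points(cm, tau_end, nu_end, +1, lip_upper_len, flare, w)
  mouth_notch <- cm - 0.15 * w * tau_end
  base_mid <- c(0, 0)
  poly <- rbind(
    lower_edge,                 # base -> mouth along the lower tube wall
    lo$pts,                     # around the lower lip
    mouth_notch,                # aperture indentation
    up$pts,                     # around the upper lip
    upper_edge[rev(seq_len(m + 1L)), ],  # mouth -> base along the upper wall
    base_mid                    # base cap midpoint = tube base
  )
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums((poly[-1L, , drop = FALSE] -
                           poly[-nrow(poly), , drop = FALSE])^2) > 1e-20)
  poly <- poly[keep, , drop = FALSE]
  if (sum((poly[1L, ] - poly[nrow(poly), ])^2) < 1e-20)
    poly <- poly[-nrow(poly), , drop = FALSE]
  ob <- outline(poly, view = "side")
  ob <- canonicalize_orientation_raw(ob)
  ob <- attach_landmarks(ob, rbind(base_mid, up$tip, lo$tip))
  resample_uniform(ob, p$n_points)
}

# orientation fix before landmarks exist
canonicalize_orientation_raw <- function(ob) {
  if (signed_area(ob$points) < 0) {
    n <- nrow(ob$points)
    ob$points <- ob$points[c(1L, n:2L), , drop = FALSE]
  }
  ob
}

#' Mirror an outline across the vertical or horizontal axis
#'
#' Reflects the coordinates (x for `"vertical"`, y for `"horizontal"`),
#' restores counter-clockwise traversal, and swaps the landmark pair whose
#' roles the reflection exchanges (left/right middles for front views
#' mirrored vertically; upper/lower lip tips for side views mirrored
#' horizontally).
#'
#' @param ob an [outline()].
#' @param axis `"vertical"` (x -> -x) or `"horizontal"` (y -> -y).
#' @return The mirrored [outline()].
#' @export
mirror_outline <- function(ob, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  if (axis == "vertical") ob$points[, 1L] <- -ob$points[, 1L]
  else ob$points[, 2L] <- -ob$points[, 2L]
  if (!is.null(ob$landmarks)) {
    if (ob$view == "front" && axis == "vertical")
      ob$landmarks[c(1L, 2L)] <- ob$landmarks[c(2L, 1L)]
    if (ob$view == "side" && axis == "horizontal")
      ob$landmarks[c(2L, 3L)] <- ob$landmarks[c(3L, 2L)]
  }
  canonicalize_orientation(ob)
}

#' Full Procrustes distance between two corresponding point sets
#'
#' Centres both configurations, scales them to unit centroid size, rotates
#' the second onto the first by the 2D orthogonal Procrustes solution
#' (rotation only, no reflection), and returns the root-mean-square
#' distance between corresponding points.
#'
#' @param a,b numeric matrices of identical dimension (rows correspond), or
#'   [outline()] objects with equal vertex counts.
#' @return A non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  if (inherits(a, "outline")) a <- a$points
  if (inherits(b, "outline")) b <- b$points
  if (!all(dim(a) == dim(b))) stop("configurations must have equal dimensions")
  ca <- scale(a, scale = FALSE); cb <- scale(b, scale = FALSE)
  ca <- ca / sqrt(sum(ca^2)); cb <- cb / sqrt(sum(cb^2))
  m <- crossprod(ca, cb)
  phi <- atan2(m[1L, 2L] - m[2L, 1L], m[1L, 1L] + m[2L, 2L])
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  sqrt(mean(rowSums((ca - cb %*% R)^2)))
}
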
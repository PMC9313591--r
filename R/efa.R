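#' Elliptical Fourier coefficients of a closed outline
#'
#' Container for the per-harmonic quadruples `(a_n, b_n, c_n, d_n)` of the
#' chord-length elliptical Fourier decomposition, plus the centroid offset
#' `(A0, C0)` and the outline perimeter `T`.
#'
#' @param an,bn,cn,dn numeric vectors of length `N` (x-cosine, x-sine,
#'   y-cosine, y-sine coefficients).
#' @param A0,C0 offset (centroid) terms.
#' @param T outline perimeter.
#' @param specimen_id,taxon_id,view linkage metadata.
#' @return An object of class `"efa_coefficients"`.
#' @export
efa_coefficients <- function(an, bn, cn, dn, A0 = 0, C0 = 0, T = 1,
                             specimen_id = NA_character_,
                             taxon_id = NA_character_, view = NA_character_) {
  N <- length(an)
  stopifnot(length(bn) == N, length(cn) == N, length(dn) == N, N >= 1L)
  if (!all(is.finite(c(an, bn, cn, dn, A0, C0, T))))
    stop("coefficients must be finite")
  structure(list(an = an, bn = bn, cn = cn, dn = dn, A0 = A0, C0 = C0,
                 T = T, N = N, specimen_id = specimen_id,
                 taxon_id = taxon_id, view = view),
            class = "efa_coefficients")
}

#' @export
print.efa_coefficients <- function(x, ...) {
  cat(sprintf("<efa_coefficients> %d harmonics (%s / %s, %s), perimeter %.4g\n",
              x$N, x$specimen_id, x$taxon_id, x$view, x$T))
  invisible(x)
}

#' Elliptical Fourier decomposition of an outline
#'
#' Chord-length parameterisation: with per-segment increments `dx_p, dy_p,
#' dt_p` and cumulative length `t_p` over the closed polygon of perimeter
#' `T`, the x cosine coefficient of harmonic `n` is
#' `a_n = T / (2 n^2 pi^2) * sum_p (dx_p / dt_p) *
#' (cos(2 pi n t_p / T) - cos(2 pi n t_{p-1} / T))`, and analogously with
#' sines for `b_n` and with `dy` for `c_n, d_n`.  Offsets `A0, C0` are the
#' arc-length averages of x and y (exact for the piecewise-linear outline).
#'
#' @param ob an [outline()] (canonicalised; see [canonicalize_orientation()]).
#' @param N number of harmonics, `1 <= N <= n_points / 2`.
#' @return An [efa_coefficients()].
#' @export
efa_forward <- function(ob, N) {
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  pts <- ob$points
  m <- nrow(pts)
  if (N > m / 2) stop(sprintf("aliasing: N = %d exceeds n_points / 2 = %g", N, m / 2))
  closed <- rbind(pts, pts[1L, , drop = FALSE])
  dx <- diff(closed[, 1L]); dy <- diff(closed[, 2L])
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) stop("outline has a zero-length segment")
  t1 <- cumsum(dt); t0 <- c(0, t1[-m])
  T <- t1[m]
  ns <- seq_len(N)
  argT <- 2 * pi * outer(t1, ns) / T        # m x N
  arg0 <- 2 * pi * outer(t0, ns) / T
  dcos <- cos(argT) - cos(arg0)
  dsin <- sin(argT) - sin(arg0)
  fac <- T / (2 * ns^2 * pi^2)
  an <- fac * colSums((dx / dt) * dcos)
  bn <- fac * colSums((dx / dt) * dsin)
  cn <- fac * colSums((dy / dt) * dcos)
  dn <- fac * colSums((dy / dt) * dsin)
  A0 <- sum(dt * (closed[-1L, 1L] + closed[-(m + 1L), 1L]) / 2) / T
  C0 <- sum(dt * (closed[-1L, 2L] + closed[-(m + 1L), 2L]) / 2) / T
  efa_coefficients(an, bn, cn, dn, A0, C0, T,
                   specimen_id = ob$specimen_id, taxon_id = ob$taxon_id,
                   view = ob$view)
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` uniform values of
#' the arc-length parameter.  The round trip
#' `efa_inverse(efa_forward(x, N))` converges to `x` as `N` grows.
#'
#' @param coef an [efa_coefficients()].
#' @param n_points number of reconstruction vertices.
#' @return An [outline()] (not validated: degenerate coefficient sets may
#'   reconstruct to repeated points).
#' @export
efa_inverse <- function(coef, n_points = 300L) {
  t <- coef$T * (seq_len(n_points) - 1L) / n_points
  ns <- seq_len(coef$N)
  arg <- 2 * pi * outer(t, ns) / coef$T
  x <- coef$A0 + cos(arg) %*% coef$an + sin(arg) %*% coef$bn
  y <- coef$C0 + cos(arg) %*% coef$cn + sin(arg) %*% coef$dn
  vw <- if (coef$view %in% c("front", "side")) coef$view else "front"
  outline(cbind(x, y), specimen_id = coef$specimen_id,
          taxon_id = coef$taxon_id, view = vw, validate = FALSE)
}

#' Cumulative harmonic power fractions
#'
#' Harmonic power is `P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`; the
#' returned sequence is `F_m = sum_{n <= m} P_n / sum_n P_n`, non-decreasing
#' with `F_N = 1`.
#'
#' @param coef an [efa_coefficients()].
#' @return Numeric vector of length `N`.
#' @export
harmonic_power <- function(coef) {
  P <- (coef$an^2 + coef$bn^2 + coef$cn^2 + coef$dn^2) / 2
  tot <- sum(P)
  if (tot == 0) stop("degenerate coefficients with zero total power")
  cumsum(P) / tot
}

#' Choose the harmonic count reaching a target mean power fraction
#'
#' Decomposes every outline at a full reference harmonic count (half the
#' smallest vertex count, so the denominator of the power fractions is the
#' total representable power, not just the first `N_max` harmonics),
#' averages the cumulative power fractions across outlines, and returns
#' the smallest `N <= N_max` whose mean fraction reaches `threshold`.  If
#' the threshold is not reached by `N_max`, `N_max` is returned with
#' attribute `reached = FALSE`.
#'
#' @param outlines list of aligned [outline()] objects.
#' @param threshold target cumulative power fraction in (0, 1).
#' @param N_max largest harmonic count considered.
#' @return Integer with attribute `reached`.
#' @export
calibrate_harmonic_count <- function(outlines, threshold = 0.99, N_max = 64L) {
  if (length(outlines) == 0L) stop("no outlines supplied")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  N_max <- as.integer(N_max)
  nmin <- min(vapply(outlines, function(ob) nrow(ob$points), integer(1)))
  N_ref <- nmin %/% 2L
  N_use <- min(N_max, N_ref)
  fr <- vapply(outlines, function(ob) harmonic_power(efa_forward(ob, N_ref)),
               numeric(N_ref))
  mean_fr <- rowMeans(matrix(fr, nrow = N_ref))
  hit <- which(mean_fr[seq_len(N_use)] >= threshold)
  if (length(hit) == 0L) return(structure(N_use, reached = FALSE))
  structure(hit[1L], reached = TRUE)
}

#' Mirror elliptical Fourier coefficients across the bilateral axis
#'
#' For outlines aligned with the bilateral axis on +x (the [gpa_align()]
#' contract), the mirror image with traversal direction restored has
#' coefficients `(a_n, -b_n, -c_n, d_n)` and offset `(A0, -C0)`.
#' An involution: `mirror_coefficients(mirror_coefficients(x)) = x`.
#'
#' @param coef an [efa_coefficients()].
#' @return The mirrored [efa_coefficients()].
#' @export
mirror_coefficients <- function(coef) {
  coef$bn <- -coef$bn
  coef$cn <- -coef$cn
  coef$C0 <- -coef$C0
  coef
}

#' Remove the asymmetric (or symmetric) coefficient subspace
#'
#' With the bilateral axis on +x, the mirror-antisymmetric subspace of the
#' Fourier decomposition is exactly the `(b_n, c_n, C0)` block.  Removing
#' it (the default) zeroes within-specimen variation between the two
#' opposing halves: the output equals `(x + mirror(x)) / 2` and is exactly
#' mirror-invariant.  `component = "symmetric"` instead zeroes the
#' `(a_n, d_n)` block, keeping only the asymmetric variation.
#'
#' @param coef an [efa_coefficients()].
#' @param component which subspace to remove.
#' @return An [efa_coefficients()].
#' @export
remove_asymmetric_component <- function(coef,
                                        component = c("asymmetric", "symmetric")) {
  component <- match.arg(component)
  if (component == "asymmetric") {
    coef$bn <- coef$bn * 0
    coef$cn <- coef$cn * 0
    coef$C0 <- 0
  } else {
    coef$an <- coef$an * 0
    coef$dn <- coef$dn * 0
  }
  coef
}

#' Per-taxon mean shapes in coefficient space
#'
#' Arithmetic mean of every coefficient (including offsets and perimeter)
#' across the specimens of each taxon.  Single-specimen taxa pass through
#' unchanged.
#'
#' @param coeffs list of [efa_coefficients()], one per specimen.
#' @param table a [specimen_table()] mapping `specimen_id` to `taxon_id`
#'   (and `clade`); every specimen in `coeffs` must appear.
#' @return A named list of [efa_coefficients()], one per taxon, in order of
#'   first appearance in `table`.
#' @export
mean_shape_per_taxon <- function(coeffs, table) {
  ids <- vapply(coeffs, function(cf) cf$specimen_id, character(1))
  miss <- setdiff(ids, table$specimen_id)
  if (length(miss))
    stop("specimens missing from the table: ", paste(miss, collapse = ", "))
  Ns <- vapply(coeffs, function(cf) cf$N, integer(1))
  if (length(unique(Ns)) != 1L)
    stop("all coefficient sets must share the same harmonic count")
  taxa <- table$taxon_id[match(ids, table$specimen_id)]
  out <- lapply(unique(table$taxon_id[table$specimen_id %in% ids]), function(tx) {
    grp <- coeffs[taxa == tx]
    avg <- function(get)
      rowMeans(matrix(vapply(grp, get, numeric(grp[[1L]]$N)),
                      nrow = grp[[1L]]$N))
    avg1 <- function(get) mean(vapply(grp, get, numeric(1)))
    efa_coefficients(avg(function(cf) cf$an), avg(function(cf) cf$bn),
                     avg(function(cf) cf$cn), avg(function(cf) cf$dn),
                     A0 = avg1(function(cf) cf$A0),
                     C0 = avg1(function(cf) cf$C0),
                     T = avg1(function(cf) cf$T),
                     taxon_id = tx, view = grp[[1L]]$view)
  })
  names(out) <- unique(table$taxon_id[table$specimen_id %in% ids])
  out
}

#' Flatten coefficients to a vector (and back)
#'
#' The flat layout is `(a_1..a_N, b_1..b_N, c_1..c_N, d_1..d_N)`; offsets
#' and perimeter are excluded (alignment makes them uninformative).
#'
#' @param coef an [efa_coefficients()].
#' @return `coef_to_vector`: numeric vector of length `4 N`.
#' @export
coef_to_vector <- function(coef) {
  v <- c(coef$an, coef$bn, coef$cn, coef$dn)
  names(v) <- c(paste0("a", seq_len(coef$N)), paste0("b", seq_len(coef$N)),
                paste0("c", seq_len(coef$N)), paste0("d", seq_len(coef$N)))
  v
}

#' @rdname coef_to_vector
#' @param v numeric vector of length `4 N`.
#' @param template optional [efa_coefficients()] supplying offset,
#'   perimeter and metadata.
#' @export
vector_to_coef <- function(v, template = NULL) {
  if (length(v) %% 4L != 0L) stop("length must be a multiple of 4")
  N <- length(v) %/% 4L
  idx <- function(k) v[((k - 1L) * N + 1L):(k * N)]
  if (is.null(template))
    efa_coefficients(idx(1L), idx(2L), idx(3L), idx(4L))
  else
    efa_coefficients(idx(1L), idx(2L), idx(3L), idx(4L),
                     A0 = template$A0, C0 = template$C0, T = template$T,
                     specimen_id = template$specimen_id,
                     taxon_id = template$taxon_id, view = template$view)
}
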
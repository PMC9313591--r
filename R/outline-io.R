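#' Closed 2D outline with landmarks
#'
#' Constructs the basic shape observation used throughout the package: an
#' ordered, implicitly closed, counter-clockwise polyline for one specimen
#' and view, with landmarks stored as vertex indices.  Front views carry 4
#' landmarks (left-middle, right-middle, top, bottom); side views carry 3
#' (tube base, upper-lip tip, lower-lip tip).
#'
#' @param points numeric matrix with two columns (x, y); the last vertex
#'   connects implicitly to the first.
#' @param specimen_id,taxon_id,clade,view character metadata. `view` is
#'   `"front"` or `"side"`.
#' @param landmarks integer vector of vertex indices (may be `NULL` before
#'   [attach_landmarks()] is called).
#' @param validate logical; check invariants (default `TRUE`).
#' @return An object of class `"outline"`.
#' @export
outline <- function(points, specimen_id = "s1", taxon_id = "t1",
                    view = c("front", "side"), clade = NA_character_,
                    landmarks = NULL, validate = TRUE) {
  view <- match.arg(view)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("`points` must have two columns (x, y)")
  colnames(points) <- c("x", "y")
  ob <- structure(
    list(points = points, specimen_id = as.character(specimen_id),
         taxon_id = as.character(taxon_id), view = view,
         clade = as.character(clade),
         landmarks = if (is.null(landmarks)) NULL else as.integer(landmarks)),
    class = "outline")
  if (validate) validate_outline(ob)
  ob
}

validate_outline <- function(ob, require_landmarks = FALSE) {
  pts <- ob$points
  n <- nrow(pts)
  if (n < 3L) stop("outline needs at least 3 vertices")
  if (!all(is.finite(pts))) stop("outline has non-finite coordinates")
  d <- pts - pts[c(2:n, 1L), , drop = FALSE]
  if (any(rowSums(d^2) == 0)) stop("outline has two consecutive identical points")
  if (!is.null(ob$landmarks)) {
    lm <- ob$landmarks
    if (anyDuplicated(lm)) stop("landmark indices must be unique")
    if (any(lm < 1L | lm > n)) stop("landmark index out of range")
    want <- if (ob$view == "front") 4L else 3L
    if (length(lm) != want)
      stop(sprintf("%s view needs %d landmarks, got %d", ob$view, want, length(lm)))
  }
  if (require_landmarks && is.null(ob$landmarks))
    stop("outline has no landmarks attached")
  invisible(ob)
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s / %s [%s] %d vertices, %s landmarks\n",
              x$specimen_id, x$taxon_id, x$view, nrow(x$points),
              if (is.null(x$landmarks)) "no" else length(x$landmarks)))
  invisible(x)
}

#' @export
plot.outline <- function(x, ..., asp = 1) {
  pts <- rbind(x$points, x$points[1L, , drop = FALSE])
  graphics::plot(pts, type = "l", asp = asp, xlab = "x", ylab = "y", ...)
  if (!is.null(x$landmarks))
    graphics::points(x$points[x$landmarks, , drop = FALSE], pch = 19, col = 2)
  invisible(x)
}

binom3_smooth <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  z <- (z[c(1L, 1:(nr - 1L)), ] + 2 * z + z[c(2:nr, nr), ]) / 4
  (z[, c(1L, 1:(nc - 1L))] + 2 * z + z[, c(2:nc, nc)]) / 4
}

# Shoelace signed area; positive for counter-clockwise traversal.
signed_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1L)
  sum(pts[, 1L] * pts[j, 2L] - pts[j, 1L] * pts[, 2L]) / 2
}

outline_perimeter <- function(pts) {
  n <- nrow(pts)
  sum(sqrt(rowSums((pts[c(2:n, 1L), , drop = FALSE] - pts)^2)))
}

#' Trace the boundary of the largest foreground component of a binary mask
#'
#' Runs marching squares (at level 0.5) on a binary raster and returns the
#' boundary of the largest foreground component as a counter-clockwise
#' closed polyline.  The raster y axis (row index increasing downwards) is
#' flipped on ingestion so the mathematical orientation convention holds.
#'
#' @param image either a numeric/logical matrix (1/TRUE = foreground, rows
#'   are raster rows from the top) or the path to a PNG mask with dark
#'   foreground on a light background (grayscale threshold 0.5).
#' @param min_area minimum component area in pixels.
#' @param ... metadata passed on to [outline()] (`specimen_id`, `view`, ...).
#' @return An [outline()] in pixel units.
#' @export
trace_mask <- function(image, min_area = 16, ...) {
  if (is.character(image)) {
    if (!grepl("\\.png$", image, ignore.case = TRUE))
      stop("file input must be a PNG mask; otherwise pass a binary matrix")
    img <- png::readPNG(image)
    if (length(dim(img)) == 3L)
      img <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
    image <- img < 0.5  # dark foreground on white
  }
  m <- matrix(as.numeric(image), nrow = nrow(image))
  if (!all(m %in% c(0, 1))) m <- as.numeric(m > 0.5)
  # pad with background so boundary components still yield closed contours
  zp <- matrix(0, nrow(m) + 4L, ncol(m) + 4L)
  zp[3:(nrow(m) + 2L), 3:(ncol(m) + 2L)] <- m
  # 3x3 binomial smoothing: sub-pixel contour placement without the
  # staircase perimeter bias of a raw binary field
  zp <- binom3_smooth(zp)
  # contourLines expects z[i, j] at (x[i], y[j]); use x = column, y = -row
  z <- t(zp)[, rev(seq_len(nrow(zp))), drop = FALSE]
  xs <- seq_len(nrow(z)) - 1L            # padded column index
  ys <- seq_len(ncol(z))                 # flipped padded row index
  cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  if (length(cl) == 0L) stop("empty input: no foreground component found")
  polys <- lapply(cl, function(cc) {
    p <- cbind(cc$x, cc$y)
    if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    p
  })
  areas <- vapply(polys, function(p) abs(signed_area(p)), numeric(1))
  big <- which.max(areas)
  if (areas[big] < min_area)
    stop(sprintf("empty input: largest component area %.1f px < min_area %.1f",
                 areas[big], min_area))
  if (sum(areas >= areas[big] * (1 - 1e-9)) > 1L)
    stop("ambiguous mask: multiple equal-largest components")
  pts <- polys[[big]]
  if (signed_area(pts) < 0) pts <- pts[c(1L, nrow(pts):2L), , drop = FALSE]
  outline(pts, ...)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Write outlines (and landmarks) to CSV
#'
#' Point rows are `(specimen_id, taxon_id, clade, view, point_index, x, y)`
#' with `point_index` contiguous from 0; landmark rows are
#' `(specimen_id, landmark_index, x, y)` using landmark vertex coordinates.
#' Coordinates are written with 17 significant digits so that
#' `read_outline_table(write_outline_table(x))` is an exact round trip.
#'
#' @param outlines list of [outline()] objects.
#' @param path output CSV path for the points table.
#' @param landmark_path optional CSV path for the landmark table; defaults
#'   to `path` with a `_landmarks.csv` suffix when any outline has landmarks.
#' @return Invisibly, the points path.
#' @export
write_outline_table <- function(outlines, path, landmark_path = NULL) {
  if (inherits(outlines, "outline")) outlines <- list(outlines)
  rows <- lapply(outlines, function(ob) {
    n <- nrow(ob$points)
    data.frame(specimen_id = ob$specimen_id, taxon_id = ob$taxon_id,
               clade = ob$clade, view = ob$view, point_index = seq_len(n) - 1L,
               x = fmt_num(ob$points[, 1L]), y = fmt_num(ob$points[, 2L]),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  has_lm <- vapply(outlines, function(ob) !is.null(ob$landmarks), logical(1))
  if (any(has_lm)) {
    if (is.null(landmark_path))
      landmark_path <- sub("\\.csv$", "_landmarks.csv", path)
    lrows <- lapply(outlines[has_lm], function(ob) {
      data.frame(specimen_id = ob$specimen_id,
                 landmark_index = seq_along(ob$landmarks),
                 x = fmt_num(ob$points[ob$landmarks, 1L]),
                 y = fmt_num(ob$points[ob$landmarks, 2L]),
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, lrows), landmark_path,
                     row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read outlines from CSV
#'
#' Inverse of [write_outline_table()].  Points are re-ordered by
#' `point_index`; a non-contiguous or duplicated index is a format error
#' reporting the offending specimen and index.
#'
#' @param path points CSV path.
#' @param landmark_path optional landmark CSV; when given, landmarks are
#'   attached via [attach_landmarks()].
#' @return A list of [outline()] objects, in order of first appearance.
#' @export
read_outline_table <- function(path, landmark_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("specimen_id", "taxon_id", "clade", "view", "point_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  df$point_index <- as.integer(df$point_index)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  lms <- NULL
  if (!is.null(landmark_path)) {
    lm <- utils::read.csv(landmark_path, stringsAsFactors = FALSE)
    lm <- lm[order(lm$landmark_index), , drop = FALSE]
    lms <- split(lm, lm$specimen_id)
  }
  ids <- unique(df$specimen_id)
  lapply(ids, function(id) {
    sub <- df[df$specimen_id == id, , drop = FALSE]
    sub <- sub[order(sub$point_index), , drop = FALSE]
    idx <- sub$point_index
    if (anyDuplicated(idx)) {
      dup <- idx[duplicated(idx)][1L]
      stop(sprintf("format error: duplicate point_index %d for specimen %s", dup, id))
    }
    expect <- seq_len(nrow(sub)) - 1L
    if (!identical(idx, expect)) {
      gap <- setdiff(seq(0L, max(idx)), idx)[1L]
      stop(sprintf("format error: point_index not contiguous for specimen %s (missing index %d)",
                   id, gap))
    }
    ob <- outline(cbind(sub$x, sub$y), specimen_id = id,
                  taxon_id = sub$taxon_id[1L], view = sub$view[1L],
                  clade = sub$clade[1L])
    if (!is.null(lms) && id %in% names(lms))
      ob <- attach_landmarks(ob, as.matrix(lms[[id]][, c("x", "y")]))
    ob
  })
}

#' Attach landmarks to an outline by nearest-vertex snapping
#'
#' Each landmark coordinate is snapped to the nearest outline vertex
#' (Euclidean distance; ties broken toward the lower vertex index) and
#' stored as a vertex index.  Front views require 4 landmarks in the order
#' left-middle, right-middle, top, bottom; side views 3 in the order tube
#' base, upper-lip tip, lower-lip tip.
#'
#' @param ob an [outline()].
#' @param landmark_coords numeric matrix of landmark coordinates (rows in
#'   the view's canonical order).
#' @return The outline with `landmarks` set.
#' @export
attach_landmarks <- function(ob, landmark_coords) {
  landmark_coords <- as.matrix(landmark_coords)
  want <- if (ob$view == "front") 4L else 3L
  if (nrow(landmark_coords) != want)
    stop(sprintf("%s view needs %d landmarks, got %d",
                 ob$view, want, nrow(landmark_coords)))
  idx <- vapply(seq_len(nrow(landmark_coords)), function(i) {
    d2 <- (ob$points[, 1L] - landmark_coords[i, 1L])^2 +
          (ob$points[, 2L] - landmark_coords[i, 2L])^2
    which(d2 <= min(d2) + 0)[1L]   # lowest index on exact ties
  }, integer(1))
  if (anyDuplicated(idx))
    stop("degenerate landmarks: two landmarks snap to the same vertex")
  ob$landmarks <- idx
  validate_outline(ob)
  ob
}

# start-vertex rule shared by resampling and canonicalisation:
# front outlines start at the top landmark (3rd), side at the tube base (1st)
start_landmark <- function(ob) {
  if (is.null(ob$landmarks)) return(NA_integer_)
  if (ob$view == "front") ob$landmarks[3L] else ob$landmarks[1L]
}

rotate_start <- function(ob, start_index) {
  n <- nrow(ob$points)
  if (is.na(start_index) || start_index == 1L) return(ob)
  ord <- c(start_index:n, seq_len(start_index - 1L))
  ob$points <- ob$points[ord, , drop = FALSE]
  if (!is.null(ob$landmarks))
    ob$landmarks <- match(ob$landmarks, ord)
  ob
}

#' Resample an outline to uniform arc-length spacing
#'
#' Places `n_points` vertices equally spaced along the cumulative arc
#' length of the closed polyline, starting from the canonical start vertex
#' (top landmark for front views, tube base for side views), and re-snaps
#' the landmarks to the new vertices.
#'
#' @param ob an [outline()].
#' @param n_points number of vertices (>= 64).
#' @return A resampled [outline()].
#' @export
resample_uniform <- function(ob, n_points = 300L) {
  n_points <- as.integer(n_points)
  if (n_points < 64L) stop("n_points must be >= 64")
  lm_coords <- if (!is.null(ob$landmarks))
    ob$points[ob$landmarks, , drop = FALSE] else NULL
  ob <- rotate_start(ob, start_landmark(ob))
  pts <- rbind(ob$points, ob$points[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  tt <- c(0, cumsum(seg))
  total <- tt[length(tt)]
  if (total <= 0) stop("degenerate outline with zero perimeter")
  s <- seq(0, total, length.out = n_points + 1L)[seq_len(n_points)]
  new <- cbind(stats::approx(tt, pts[, 1L], xout = s)$y,
               stats::approx(tt, pts[, 2L], xout = s)$y)
  out <- outline(new, specimen_id = ob$specimen_id, taxon_id = ob$taxon_id,
                 view = ob$view, clade = ob$clade)
  if (!is.null(lm_coords)) out <- attach_landmarks(out, lm_coords)
  rotate_start(out, start_landmark(out))
}

#' Canonicalise outline orientation and start vertex
#'
#' Ensures counter-clockwise traversal (reversing the vertex order, start
#' vertex kept, if the signed area is negative) and rotates the vertex
#' order so the canonical start vertex comes first.  Idempotent.
#'
#' @param ob an [outline()].
#' @return The canonical [outline()].
#' @export
canonicalize_orientation <- function(ob) {
  a <- signed_area(ob$points)
  if (a == 0) stop("degenerate outline with zero area")
  if (a < 0) {
    n <- nrow(ob$points)
    ord <- c(1L, n:2L)
    ob$points <- ob$points[ord, , drop = FALSE]
    if (!is.null(ob$landmarks)) ob$landmarks <- match(ob$landmarks, ord)
  }
  rotate_start(ob, start_landmark(ob))
}

#' Specimen inventory table and summary
#'
#' `specimen_table()` builds the inventory (one row per outline);
#' `specimen_summary()` reports, per view, the number of outlines, number
#' of taxa, and the mean and standard deviation of outlines per taxon --
#' the descriptive statistics used to report an outline collection.
#'
#' @param outlines list of [outline()] objects, or a data.frame already in
#'   inventory form with columns `specimen_id`, `taxon_id`, `clade`, `view`.
#' @return `specimen_table()`: the inventory data.frame.
#'   `specimen_summary()`: a data.frame with one row per view and columns
#'   `view`, `n_outlines`, `n_taxa`, `mean_per_taxon`, `sd_per_taxon`.
#' @export
specimen_table <- function(outlines) {
  if (is.data.frame(outlines)) {
    need <- c("specimen_id", "taxon_id", "clade", "view")
    miss <- setdiff(need, names(outlines))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    return(outlines[, need])
  }
  do.call(rbind, lapply(outlines, function(ob)
    data.frame(specimen_id = ob$specimen_id, taxon_id = ob$taxon_id,
               clade = ob$clade, view = ob$view, stringsAsFactors = FALSE)))
}

#' @rdname specimen_table
#' @export
specimen_summary <- function(outlines) {
  st <- specimen_table(outlines)
  out <- lapply(split(st, st$view), function(sub) {
    per_taxon <- table(sub$taxon_id)
    data.frame(view = sub$view[1L], n_outlines = nrow(sub),
               n_taxa = length(per_taxon),
               mean_per_taxon = mean(as.numeric(per_taxon)),
               sd_per_taxon = stats::sd(as.numeric(per_taxon)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
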
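# Trio D-statistics (ABBA-BABA) from population allele frequencies, with
# three trio-arrangement modes, block-jackknife significance and
# Benjamini-Hochberg correction across trios.

pop_frequencies <- function(gt, pops) {
  f <- lapply(pops, function(p) {
    cols <- which(gt$populations == p)
    g <- gt$genotypes[, cols, drop = FALSE]
    rowMeans(g, na.rm = TRUE) / 2
  })
  matrix(unlist(f), nrow = nrow(gt$genotypes), dimnames = list(NULL, pops))
}

#' Site-pattern sums for one trio
#'
#' Per site with derived-allele frequencies `p1, p2, p3, pO`, accumulates
#' `ABBA += (1-p1) p2 p3 (1-pO)`, `BABA += p1 (1-p2) p3 (1-pO)` and
#' `BBAA += p1 p2 (1-p3) (1-pO)`, per jackknife block and in total.  Sites
#' where a whole population is missing are skipped and reported.
#'
#' @param gt a [genotype_table()].
#' @param trio character vector `(P1, P2, P3)` of population labels
#'   (distinct, not the outgroup).
#' @return A list of class `"pattern_sums"`: `abba`, `baba`, `bbaa`,
#'   `blocks` (per-block sums, blocks x 3), `n_sites_used`, `trio`.
#' @export
site_pattern_sums <- function(gt, trio) {
  trio <- as.character(trio)
  if (length(trio) != 3L || anyDuplicated(trio))
    stop("trio must name three distinct populations")
  pops <- c(trio, gt$outgroup)
  absent <- setdiff(pops, gt$populations)
  if (length(absent))
    stop("populations absent from the table: ", paste(absent, collapse = ", "))
  if (nrow(gt$genotypes) == 0L)
    stop("undefined D: genotype table has no sites")
  f <- pop_frequencies(gt, pops)
  usable <- stats::complete.cases(f)
  f <- f[usable, , drop = FALSE]
  bl <- gt$blocks[usable]
  p1 <- f[, 1L]; p2 <- f[, 2L]; p3 <- f[, 3L]; pO <- f[, 4L]
  w_abba <- (1 - p1) * p2 * p3 * (1 - pO)
  w_baba <- p1 * (1 - p2) * p3 * (1 - pO)
  w_bbaa <- p1 * p2 * (1 - p3) * (1 - pO)
  blocks <- cbind(abba = tapply_sum(w_abba, bl),
                  baba = tapply_sum(w_baba, bl),
                  bbaa = tapply_sum(w_bbaa, bl))
  structure(list(abba = sum(w_abba), baba = sum(w_baba), bbaa = sum(w_bbaa),
                 blocks = blocks, n_sites_used = sum(usable), trio = trio),
            class = "pattern_sums")
}

tapply_sum <- function(w, g) {
  out <- tapply(w, factor(g, levels = unique(g)), sum)
  as.numeric(out)
}

#' D-statistic from pattern sums
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`, in `[-1, 1]`; `NA` with an
#' `undefined` attribute when the denominator is zero.
#'
#' @param sums a [site_pattern_sums()] result, or a numeric vector/list
#'   with elements `abba` and `baba`.
#' @return A number (or `NA` flagged `undefined`).
#' @export
d_statistic <- function(sums) {
  abba <- sums[["abba"]]; baba <- sums[["baba"]]
  den <- abba + baba
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  (abba - baba) / den
}

# pattern sums for a fixed labelling (A, B, C) expressed as unordered
# sharing pairs: N[pair sharing the derived allele]
sharing_sums <- function(ps) {
  c(BC = ps$abba, AC = ps$baba, AB = ps$bbaa)
}

arrangements <- function(trio) {
  # (P1, P2, P3) orderings with distinct sister pairs: P3 = excluded taxon
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))
}

arrangement_sums <- function(ps, ord) {
  # for ordering (i, j, k): ABBA = N[{j,k}], BABA = N[{i,k}], BBAA = N[{i,j}]
  pair_name <- function(i, j) paste(sort(c("A", "B", "C")[c(i, j)]), collapse = "")
  N <- sharing_sums(ps)
  blocks <- ps$blocks
  colnames(blocks) <- c("BC", "AC", "AB")
  list(abba = N[[pair_name(ord[2L], ord[3L])]],
       baba = N[[pair_name(ord[1L], ord[3L])]],
       bbaa = N[[pair_name(ord[1L], ord[2L])]],
       blocks = cbind(abba = blocks[, pair_name(ord[2L], ord[3L])],
                      baba = blocks[, pair_name(ord[1L], ord[3L])],
                      bbaa = blocks[, pair_name(ord[1L], ord[2L])]),
       trio = ps$trio[ord])
}

#' Arrange a trio and compute its D-statistic
#'
#' Three conventions: `"BBAA"` treats the pair sharing derived alleles
#' most often as sisters (P1, P2), orienting P1/P2 so that `D >= 0`;
#' `"min"` reports the smallest `|D|` over the three possible sister-pair
#' arrangements; `"tree"` fixes the arrangement from a given species tree.
#'
#' @param ps a [site_pattern_sums()] result for the trio in its input
#'   labelling.
#' @param mode `"BBAA"`, `"min"` or `"tree"`.
#' @param species_tree an [ape::phylo] containing the trio taxa (required
#'   for `mode = "tree"`).
#' @return A list: `trio` (ordered P1, P2, P3), `abba`, `baba`, `bbaa`,
#'   `blocks`, `D`, `mode`, and `tie` (TRUE when the BBAA rule hit a
#'   three-way tie, broken lexicographically).
#' @export
arrange_trio <- function(ps, mode = c("BBAA", "min", "tree"),
                         species_tree = NULL) {
  mode <- match.arg(mode)
  ords <- arrangements(ps$trio)
  tie <- FALSE
  if (mode == "BBAA") {
    bbaa_of <- vapply(ords, function(o) arrangement_sums(ps, o)$bbaa, numeric(1))
    best <- which(bbaa_of >= max(bbaa_of) - 0)
    if (length(best) == 3L) { tie <- TRUE; best <- 1L } else best <- best[1L]
    ar <- arrangement_sums(ps, ords[[best]])
    D <- d_statistic(ar)
    if (!is.na(D) && D < 0) {   # swap P1 and P2 so D >= 0
      o <- ords[[best]][c(2L, 1L, 3L)]
      ar <- arrangement_sums(ps, o)
      D <- d_statistic(ar)
    }
  } else if (mode == "min") {
    ars <- lapply(ords, function(o) arrangement_sums(ps, o))
    Ds <- vapply(ars, function(a) abs(d_statistic(a)), numeric(1))
    best <- which.min(Ds)
    ar <- ars[[best]]
    D <- d_statistic(ar)
  } else {
    if (is.null(species_tree)) stop("tree mode requires a species tree")
    miss <- setdiff(ps$trio, species_tree$tip.label)
    if (length(miss))
      stop("species tree lacks taxa: ", paste(miss, collapse = ", "))
    sub <- ape::keep.tip(species_tree, ps$trio)
    # the excluded taxon (P3) is the tip whose sister is the other pair
    combos <- utils::combn(3L, 2L, simplify = FALSE)
    p3 <- NULL
    for (cb in combos) {
      pair <- ps$trio[cb]
      if (ape::is.monophyletic(sub, pair)) { p3 <- setdiff(1:3, cb); break }
    }
    if (is.null(p3)) stop("could not resolve the trio on the species tree")
    o <- c(setdiff(1:3, p3), p3)
    ar <- arrangement_sums(ps, o)
    D <- d_statistic(ar)
  }
  c(ar, list(D = D, mode = mode, tie = tie))
}

#' Block-jackknife significance of a D-statistic
#'
#' Delete-one-block estimates `D_(-b)` give
#' `SE^2 = (B - 1) / B * sum_b (D_(-b) - mean)^2`, `Z = D / SE` and
#' `p = 2 (1 - Phi(|Z|))`.  Zero jackknife variance with nonzero D yields
#' `p = 0` with a degeneracy flag; with `D = 0`, `Z = 0`.
#'
#' @param arranged an [arrange_trio()] result (per-block sums under the
#'   chosen arrangement).
#' @return A list: `D`, `SE`, `Z`, `p`, `n_blocks`, `degenerate`.
#' @export
jackknife_significance <- function(arranged) {
  bl <- arranged$blocks
  B <- nrow(bl)
  if (B < 2L) stop("insufficient blocks: need at least 2 jackknife blocks")
  tot_abba <- sum(bl[, "abba"]); tot_baba <- sum(bl[, "baba"])
  D <- d_statistic(list(abba = tot_abba, baba = tot_baba))
  Dm <- vapply(seq_len(B), function(b) {
    a <- tot_abba - bl[b, "abba"]; bb <- tot_baba - bl[b, "baba"]
    if (a + bb == 0) NA_real_ else (a - bb) / (a + bb)
  }, numeric(1))
  if (sum(!is.na(Dm)) < 2L) stop("insufficient blocks with a nonzero denominator")
  Dm_ok <- Dm[!is.na(Dm)]
  Bu <- length(Dm_ok)
  SE <- sqrt((Bu - 1) / Bu * sum((Dm_ok - mean(Dm_ok))^2))
  degenerate <- FALSE
  if (SE == 0) {
    if (is.na(D) || D == 0) { Z <- 0; p <- 1 }
    else { Z <- Inf; p <- 0; degenerate <- TRUE }
  } else {
    Z <- D / SE
    p <- 2 * (1 - stats::pnorm(abs(Z)))
  }
  list(D = D, SE = SE, Z = Z, p = p, n_blocks = B, degenerate = degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at
#' 1, input order restored).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' D-statistics for all trios of a genotype table
#'
#' Enumerates every trio of non-outgroup populations, arranges each under
#' the requested mode, attaches block-jackknife significance, and adjusts
#' the p-values across all trios with [bh_adjust()].
#'
#' @param gt a [genotype_table()].
#' @param mode trio arrangement mode (see [arrange_trio()]).
#' @param species_tree species tree for `mode = "tree"`.
#' @return A data.frame of class `"trio_d_table"`: P1, P2, P3, mode, abba,
#'   baba, bbaa, D, SE, Z, p, p_adj, n_blocks.
#' @export
d_scan <- function(gt, mode = c("BBAA", "min", "tree"), species_tree = NULL) {
  mode <- match.arg(mode)
  pops <- setdiff(unique(gt$populations), gt$outgroup)
  if (length(pops) < 3L) stop("need at least three non-outgroup populations")
  trios <- utils::combn(sort(pops), 3L, simplify = FALSE)
  rows <- lapply(trios, function(tr) {
    ps <- site_pattern_sums(gt, tr)
    ar <- arrange_trio(ps, mode, species_tree)
    # a zero pattern denominator makes D undefined for this trio; flag it
    # with NA rather than aborting the scan
    jk <- tryCatch(jackknife_significance(ar), error = function(e)
      list(D = NA_real_, SE = NA_real_, Z = NA_real_, p = NA_real_,
           n_blocks = nrow(ar$blocks)))
    data.frame(P1 = ar$trio[1L], P2 = ar$trio[2L], P3 = ar$trio[3L],
               mode = mode, abba = ar$abba, baba = ar$baba, bbaa = ar$bbaa,
               D = jk$D, SE = jk$SE, Z = jk$Z, p = jk$p,
               n_blocks = jk$n_blocks, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  class(res) <- c("trio_d_table", class(res))
  res
}

#' Heatmap matrices of the most significant D per species pair
#'
#' Cell `(P2, P3)` holds the D of the trio with the largest `|Z|` among all
#' P1 choices placing that pair in the (P2, P3) roles; a companion matrix
#' carries the adjusted p-values.  Pairs never observed in those roles are
#' `NA` (no information).
#'
#' @param results a [d_scan()] result (single mode).
#' @return A list with matrices `D` and `p_adj` (rows = P2 sorted, columns
#'   = P3 sorted).
#' @export
heatmap_matrix <- function(results) {
  if (length(unique(results$mode)) > 1L)
    stop("results mix arrangement modes")
  p2s <- sort(unique(results$P2)); p3s <- sort(unique(results$P3))
  D <- matrix(NA_real_, length(p2s), length(p3s), dimnames = list(p2s, p3s))
  P <- D
  zbest <- D
  for (i in seq_len(nrow(results))) {
    if (is.na(results$Z[i])) next
    r2 <- results$P2[i]; r3 <- results$P3[i]
    if (is.na(zbest[r2, r3]) || abs(results$Z[i]) > abs(zbest[r2, r3])) {
      D[r2, r3] <- results$D[i]
      P[r2, r3] <- results$p_adj[i]
      zbest[r2, r3] <- results$Z[i]
    }
  }
  list(D = D, p_adj = P)
}

#' Plot a D-statistic heatmap
#'
#' Thin display layer over [heatmap_matrix()]: red cells indicate high D,
#' blue low, white missing pairs.
#'
#' @param hm a [heatmap_matrix()] result.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `hm`.
#' @export
plot_d_heatmap <- function(hm, ...) {
  D <- hm$D
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(seq_len(ncol(D)), seq_len(nrow(D)), t(D)[, rev(seq_len(nrow(D))), drop = FALSE],
                  col = pal, zlim = c(-1, 1), axes = FALSE, xlab = "P3", ylab = "P2", ...)
  graphics::axis(1L, seq_len(ncol(D)), colnames(D), las = 2, cex.axis = 0.7)
  graphics::axis(2L, seq_len(nrow(D)), rev(rownames(D)), las = 2, cex.axis = 0.7)
  invisible(hm)
}
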
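# Internal cluster-validity indices.  Each index is a function of a
# context list (data, fitted partitions for every K, within-cluster sums
# of squares, distance matrix) returning the K it votes for.  Standard
# optimum directions: maximise CH, silhouette, Dunn, Krzanowski-Lai;
# minimise Davies-Bouldin, C-index, Xu; elbow rules for Hartigan and
# Ball-Hall; Tibshirani's one-standard-error rule for the gap statistic.

validity_indices <- function() list(
  calinski_harabasz = function(ctx) {
    n <- nrow(ctx$x); tss <- sum(scale(ctx$x, scale = FALSE)^2)
    ch <- vapply(seq_along(ctx$Ks), function(i) {
      K <- ctx$Ks[i]; W <- ctx$wss[i]
      ((tss - W) / (K - 1)) / (W / (n - K))
    }, numeric(1))
    ctx$Ks[which.max(ch)]
  },
  silhouette = function(ctx) {
    sil <- vapply(seq_along(ctx$Ks), function(i)
      mean_silhouette(ctx$fits[[i]]$labels, ctx$dmat), numeric(1))
    ctx$Ks[which.max(sil)]
  },
  davies_bouldin = function(ctx) {
    db <- vapply(seq_along(ctx$Ks), function(i) {
      f <- ctx$fits[[i]]
      S <- vapply(seq_len(f$K), function(k) {
        pts <- ctx$x[f$labels == k, , drop = FALSE]
        mean(sqrt(rowSums(sweep(pts, 2L, f$centroids[k, ])^2)))
      }, numeric(1))
      M <- as.matrix(stats::dist(f$centroids))
      mean(vapply(seq_len(f$K), function(k) {
        r <- (S[k] + S[-k]) / M[k, -k]
        max(r)
      }, numeric(1)))
    }, numeric(1))
    ctx$Ks[which.min(db)]
  },
  dunn = function(ctx) {
    dn <- vapply(seq_along(ctx$Ks), function(i) {
      lab <- ctx$fits[[i]]$labels
      K <- ctx$Ks[i]
      diam <- max(vapply(seq_len(K), function(k) {
        d <- ctx$dmat[lab == k, lab == k, drop = FALSE]
        if (nrow(d) < 2L) 0 else max(d)
      }, numeric(1)))
      sep <- min(vapply(seq_len(K - 1L), function(k) {
        min(vapply((k + 1L):K, function(l)
          min(ctx$dmat[lab == k, lab == l, drop = FALSE]), numeric(1)))
      }, numeric(1)))
      if (diam == 0) Inf else sep / diam
    }, numeric(1))
    ctx$Ks[which.max(dn)]
  },
  c_index = function(ctx) {
    dv <- ctx$dmat[upper.tri(ctx$dmat)]
    dv_sorted <- sort(dv)
    ci <- vapply(seq_along(ctx$Ks), function(i) {
      lab <- ctx$fits[[i]]$labels
      same <- outer(lab, lab, `==`)[upper.tri(ctx$dmat)]
      nw <- sum(same)
      S <- sum(dv[same])
      smin <- sum(dv_sorted[seq_len(nw)])
      smax <- sum(dv_sorted[seq(length(dv_sorted) - nw + 1L, length(dv_sorted))])
      if (smax == smin) 0 else (S - smin) / (smax - smin)
    }, numeric(1))
    ctx$Ks[which.min(ci)]
  },
  gap = function(ctx) {
    # uniform references in the principal-axis bounding box of the data
    pc <- stats::prcomp(ctx$x, center = TRUE, scale. = FALSE)
    z <- pc$x
    lo <- apply(z, 2L, min); hi <- apply(z, 2L, max)
    logW_ref <- with_seed(ctx$seed + 10007L, {
      vapply(seq_len(ctx$gap_B), function(b) {
        zr <- sapply(seq_along(lo), function(j)
          stats::runif(nrow(ctx$x), lo[j], hi[j]))
        xr <- zr %*% t(pc$rotation)
        vapply(ctx$Ks, function(K)
          log(kmeans_fit(xr, K, restarts = 2L, seed = b * 131L + K)$wss),
          numeric(1))
      }, numeric(length(ctx$Ks)))
    })
    logW_ref <- matrix(logW_ref, nrow = length(ctx$Ks))
    gap <- rowMeans(logW_ref) - log(ctx$wss)
    se <- apply(logW_ref, 1L, stats::sd) * sqrt(1 + 1 / ctx$gap_B)
    for (i in seq_len(length(ctx$Ks) - 1L))
      if (gap[i] >= gap[i + 1L] - se[i + 1L]) return(ctx$Ks[i])
    ctx$Ks[length(ctx$Ks)]
  },
  hartigan = function(ctx) {
    n <- nrow(ctx$x)
    W <- c(ctx$wss, ctx$wss_hi)
    for (i in seq_along(ctx$Ks)) {
      if (is.na(W[i + 1L])) break
      H <- (W[i] / W[i + 1L] - 1) * (n - ctx$Ks[i] - 1L)
      if (H <= 10) return(ctx$Ks[i])
    }
    ctx$Ks[length(ctx$Ks)]
  },
  krzanowski_lai = function(ctx) {
    d <- ncol(ctx$x)
    W <- c(ctx$wss_lo, ctx$wss, ctx$wss_hi)     # K_min-1 .. K_max+1
    Kall <- c(ctx$Ks[1L] - 1L, ctx$Ks, ctx$Ks[length(ctx$Ks)] + 1L)
    diff_k <- vapply(seq_len(length(Kall) - 1L), function(i)
      Kall[i]^(2 / d) * W[i] - Kall[i + 1L]^(2 / d) * W[i + 1L], numeric(1))
    kl <- abs(diff_k[-length(diff_k)]) /
      pmax(abs(diff_k[-1L]), .Machine$double.eps)
    kl[is.na(kl)] <- -Inf
    ctx$Ks[which.max(kl)]
  },
  ball_hall = function(ctx) {
    W <- c(ctx$wss_lo, ctx$wss)
    Kall <- c(ctx$Ks[1L] - 1L, ctx$Ks)
    bh <- W / Kall
    drop_ <- bh[-length(bh)] - bh[-1L]          # successive decrease
    ctx$Ks[which.max(drop_)]
  },
  xu = function(ctx) {
    n <- nrow(ctx$x); d <- ncol(ctx$x)
    xu <- d * log2(sqrt(ctx$wss / (d * n^2))) + log(ctx$Ks)
    ctx$Ks[which.min(xu)]
  }
)

mean_silhouette <- function(labels, dmat) {
  n <- length(labels)
  Ks <- sort(unique(labels))
  if (length(Ks) < 2L) return(0)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(dmat[i, own]) / (sum(own) - 1L)
    b <- min(vapply(Ks[Ks != labels[i]], function(k)
      mean(dmat[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
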
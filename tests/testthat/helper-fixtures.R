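# Shared fixtures, built in code.

make_circle_outline <- function(r = 1, n = 256L, centre = c(0, 0),
                                start_angle = 0) {
  th <- start_angle + 2 * pi * (seq_len(n) - 1L) / n
  outline(cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th)),
          view = "front")
}

count_radial_maxima <- function(ob) {
  ctr <- colMeans(ob$points)
  r <- sqrt(rowSums(sweep(ob$points, 2L, ctr)^2))
  n <- length(r)
  sum(r > r[c(n, 1:(n - 1L))] & r > r[c(2:n, 1L)])
}

# three tight, well-separated Gaussian blobs (the clustering testbed)
make_three_blobs <- function(n_per = 50L, sd = 0.1, sep = 10, seed = 1L) {
  centres <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  pts <- petalspectrum:::with_seed(seed, {
    do.call(rbind, lapply(1:3, function(k)
      cbind(stats::rnorm(n_per, centres[k, 1L], sd),
            stats::rnorm(n_per, centres[k, 2L], sd))))
  })
  rownames(pts) <- paste0("p", seq_len(nrow(pts)))
  pts
}

# aligned front-view flower set: generate, canonicalise, resample, GPA
make_aligned_flowers <- function(n = 6L, lobe_depth = 0.3, seed = 1L,
                                 asymmetry_sd = 0, n_points = 240L, ...) {
  obs <- lapply(seq_len(n), function(i) {
    p <- flower_params("front", lobe_depth = lobe_depth,
                       asymmetry_sd = asymmetry_sd,
                       n_points = n_points, seed = seed + i, ...)
    ob <- gen_front_outline(p)
    ob$specimen_id <- paste0("s", i)
    ob$taxon_id <- paste0("t", i)
    ob
  })
  gpa_align(lapply(obs, function(ob)
    resample_uniform(canonicalize_orientation(ob), n_points)))
}

# hand-built pattern_sums object for arrangement tests
make_pattern_sums <- function(abba, baba, bbaa, trio = c("A", "B", "C")) {
  structure(list(abba = abba, baba = baba, bbaa = bbaa,
                 blocks = matrix(c(abba, baba, bbaa), 1L, 3L,
                                 dimnames = list(NULL, c("abba", "baba", "bbaa"))),
                 n_sites_used = abba + baba + bbaa, trio = trio),
            class = "pattern_sums")
}
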
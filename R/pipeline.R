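# Config-driven orchestration: align -> Fourier -> symmetry removal ->
# taxon means -> PCA -> clustering + clade hulls -> optimum shifts, and,
# independently, trio D-statistics -> BH correction -> heatmap matrices.
# All stage outputs are CSV (floats rounded to 12 significant digits) so a
# rerun with the same config and seed is byte-identical.

#' Build a pipeline configuration
#'
#' @param outlines,landmarks paths to the outline and landmark CSVs
#'   ([write_outline_table()] dialect).
#' @param tree optional newick tree with one tip per taxon (enables shift
#'   detection).
#' @param genotypes optional genotype CSV ([write_genotype_csv()] dialect;
#'   enables D-statistics).
#' @param outgroup outgroup population name in the genotype file.
#' @param species_tree optional newick population tree (enables the
#'   `"tree"` D mode).
#' @param views which outline views to process.
#' @param harmonic_threshold,n_max_harmonics harmonic-power calibration.
#' @param remove_asymmetry named logical: zero the asymmetric coefficient
#'   subspace per view (default: front only, where left-right noise is
#'   within-specimen variation).
#' @param n_pcs how many principal components feed clustering and shift
#'   detection.
#' @param k_range candidate cluster-number range.
#' @param s_max maximum number of optimum shifts.
#' @param d_modes trio arrangement modes to compute.
#' @param seed global seed, fanned out to stages as `seed + 100 * stage`.
#' @param out_dir output directory.
#' @return A list of class `"pipeline_config"` (not yet validated).
#' @export
pipeline_config <- function(outlines, landmarks, tree = NULL,
                            genotypes = NULL, outgroup = "OUT",
                            species_tree = NULL,
                            views = c("front", "side"),
                            harmonic_threshold = 0.99,
                            n_max_harmonics = 64L,
                            remove_asymmetry = c(front = TRUE, side = FALSE),
                            n_pcs = 3L, k_range = c(2L, 20L), s_max = 10L,
                            d_modes = c("BBAA", "min"), seed = 1L,
                            out_dir = "petalspectrum-out") {
  structure(list(outlines = outlines, landmarks = landmarks, tree = tree,
                 genotypes = genotypes, outgroup = outgroup,
                 species_tree = species_tree, views = views,
                 harmonic_threshold = harmonic_threshold,
                 n_max_harmonics = as.integer(n_max_harmonics),
                 remove_asymmetry = remove_asymmetry,
                 n_pcs = as.integer(n_pcs),
                 k_range = as.integer(k_range), s_max = as.integer(s_max),
                 d_modes = d_modes, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments; relative paths are resolved against the file's directory.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("outlines", "landmarks", "tree", "genotypes", "species_tree"))
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  if (!is.null(y$remove_asymmetry)) y$remove_asymmetry <- unlist(y$remove_asymmetry)
  if (!is.null(y$out_dir) && !grepl("^/", y$out_dir))
    y$out_dir <- file.path(base, y$out_dir)
  do.call(pipeline_config, y)
}

#' Validate a pipeline configuration
#'
#' Checks every constraint and reports all violations at once rather than
#' failing fast; fills defaults.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return The validated config (class gains `"validated"`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  for (f in c("outlines", "landmarks")) {
    if (is.null(config[[f]])) note(sprintf("missing required path: %s", f))
    else if (!file.exists(config[[f]]))
      note(sprintf("%s file not found: %s", f, config[[f]]))
  }
  for (f in c("tree", "genotypes", "species_tree"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      note(sprintf("%s file not found: %s", f, config[[f]]))
  if (!all(config$views %in% c("front", "side")))
    note("views must be a subset of front, side")
  if (config$harmonic_threshold <= 0 || config$harmonic_threshold >= 1)
    note("harmonic_threshold must be in (0, 1)")
  if (config$n_pcs < 1L) note("n_pcs must be >= 1")
  if (length(config$k_range) != 2L || config$k_range[1L] < 2L ||
      config$k_range[1L] > config$k_range[2L])
    note("k_range must be (K_min >= 2, K_max >= K_min)")
  if (config$s_max < 1L) note("s_max must be >= 1")
  if (!all(config$d_modes %in% c("BBAA", "min", "tree")))
    note("d_modes must be among BBAA, min, tree")
  if ("tree" %in% config$d_modes && is.null(config$species_tree))
    note("d_modes includes 'tree' but no species_tree path is given")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(config) <- c("validated", class(config))
  config
}

round_df <- function(df, digits = 12L) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(round_df(as.data.frame(df)), path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the morphometric stages per view (alignment, harmonic
#' calibration, Fourier decomposition, optional asymmetry removal, taxon
#' means, PCA, majority-rule clustering, clade hulls, optimum-shift
#' detection when a tree is supplied) and, independently, the trio
#' D-statistic scan with BH correction and heatmap matrices when a
#' genotype table is supplied.  Writes stage CSVs plus a JSON manifest
#' (input hashes, seed, per-stage wall time, output hashes) under
#' `config$out_dir`.  Reruns with identical config and seed are
#' byte-identical.
#'
#' @param config a validated [pipeline_config()] (or one to validate, or a
#'   YAML path).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "validated")) config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   inputs = list(), stages = list(), outputs = list())
  for (f in c("outlines", "landmarks", "tree", "genotypes", "species_tree"))
    if (!is.null(config[[f]]))
      manifest$inputs[[f]] <- unname(tools::md5sum(config[[f]]))
  stage <- 0L
  results <- list()
  timed <- function(name, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    manifest$stages[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    out
  }
  outlines <- timed("read_outlines",
                    read_outline_table(config$outlines, config$landmarks))
  st <- specimen_table(outlines)
  for (view in config$views) {
    stage <- stage + 1L
    vs <- outlines[vapply(outlines, function(o) o$view, character(1)) == view]
    if (length(vs) < 2L) stop(sprintf("stage %s: fewer than 2 outlines", view))
    vs <- lapply(vs, function(ob) resample_uniform(canonicalize_orientation(ob)))
    ga <- timed(paste0(view, "_gpa"), gpa_align(vs))
    N <- timed(paste0(view, "_calibrate"),
               calibrate_harmonic_count(ga$outlines, config$harmonic_threshold,
                                        config$n_max_harmonics))
    coefs <- lapply(ga$outlines, efa_forward, N = as.integer(N))
    if (isTRUE(config$remove_asymmetry[[view]]))
      coefs <- lapply(coefs, remove_asymmetric_component)
    means <- mean_shape_per_taxon(coefs, st)
    model <- timed(paste0(view, "_pca"), fit_pca(means))
    npc <- min(config$n_pcs, ncol(model$scores))
    sc <- model$scores[, seq_len(npc), drop = FALSE]
    kmax <- min(config$k_range[2L], nrow(sc) - 1L)
    clus <- timed(paste0(view, "_cluster"),
                  select_k_majority(sc, config$k_range[1L], kmax,
                                    seed = config$seed + 100L * stage))
    clades <- stats::setNames(st$clade, st$taxon_id)
    hulls <- clade_hull_occupancy(model$scores, clades[rownames(model$scores)])
    shifts <- NULL
    if (!is.null(config$tree)) {
      tr <- ape::read.tree(config$tree)
      miss <- setdiff(tr$tip.label, rownames(sc))
      if (length(miss))
        stop("tree tips not matching taxon ids: ", paste(miss, collapse = ", "))
      shifts <- timed(paste0(view, "_shifts"),
                      detect_shifts(tr, sc[tr$tip.label, , drop = FALSE],
                                    s_max = config$s_max,
                                    seed = config$seed + 100L * stage + 1L))
    }
    pre <- function(nm) paste0(view, "_", nm)
    outs <- c(
      write_stage_csv(data.frame(harmonics = as.integer(N),
                                 threshold = config$harmonic_threshold,
                                 reached = isTRUE(attr(N, "reached"))),
                      config$out_dir, pre("harmonics.csv")),
      write_stage_csv(coef_table(means), config$out_dir, pre("mean_coefficients.csv")),
      write_stage_csv(data.frame(taxon_id = rownames(model$scores),
                                 model$scores, check.names = FALSE),
                      config$out_dir, pre("scores.csv")),
      write_stage_csv(data.frame(component = seq_along(model$var_frac),
                                 eigenvalue = model$eigenvalues,
                                 var_frac = model$var_frac),
                      config$out_dir, pre("variance.csv")),
      write_stage_csv(clus$votes, config$out_dir, pre("votes.csv")),
      write_stage_csv(data.frame(taxon_id = names(clus$labels),
                                 cluster = unname(clus$labels),
                                 chosen_k = clus$chosen_k),
                      config$out_dir, pre("clusters.csv")),
      write_stage_csv(hulls, config$out_dir, pre("hull_areas.csv")))
    if (!is.null(shifts)) {
      outs <- c(outs,
        write_stage_csv(shifts$candidates, config$out_dir, pre("shift_candidates.csv")),
        write_stage_csv(data.frame(
          edge = if (length(shifts$edges)) shifts$edges else NA_integer_,
          alpha = shifts$alpha, pbic = shifts$pbic),
          config$out_dir, pre("shift_best.csv")))
    }
    manifest$outputs[basename(outs)] <- NA
    results[[view]] <- list(alignment = ga$result, harmonics = as.integer(N),
                            model = model, clusters = clus, hulls = hulls,
                            shifts = shifts)
  }
  if (!is.null(config$genotypes)) {
    gt <- read_genotype_csv(config$genotypes, outgroup = config$outgroup)
    sp_tree <- if (!is.null(config$species_tree))
      ape::read.tree(config$species_tree) else NULL
    dres <- list()
    for (mode in config$d_modes) {
      dtab <- timed(paste0("dstat_", mode), d_scan(gt, mode, sp_tree))
      hm <- heatmap_matrix(dtab)
      outs <- c(
        write_stage_csv(dtab, config$out_dir, paste0("dstat_", mode, ".csv")),
        write_stage_csv(data.frame(P2 = rownames(hm$D), hm$D, check.names = FALSE),
                        config$out_dir, paste0("dheatmap_", mode, ".csv")))
      manifest$outputs[basename(outs)] <- NA
      dres[[mode]] <- list(table = dtab, heatmap = hm)
    }
    results$dstat <- dres
  }
  for (nm in names(manifest$outputs))
    manifest$outputs[[nm]] <- unname(tools::md5sum(file.path(config$out_dir, nm)))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

coef_table <- function(coef_list) {
  do.call(rbind, lapply(coef_list, function(cf) {
    rbind(data.frame(id = if (!is.na(cf$taxon_id)) cf$taxon_id else cf$specimen_id,
                     view = cf$view, n = seq_len(cf$N),
                     a = cf$an, b = cf$bn, c = cf$cn, d = cf$dn),
          data.frame(id = if (!is.na(cf$taxon_id)) cf$taxon_id else cf$specimen_id,
                     view = cf$view, n = 0L, a = cf$A0, b = 0, c = cf$C0, d = 0))
  }))
}

#' Write a self-contained synthetic demonstration data set and config
#'
#' Generates front and side outlines for a set of taxa in four clades
#' (clades differ in lobing depth, dorsoventral gradient, lateral
#' doubling, tube length and curvature), a unit-height phylogeny over the
#' taxa, trio genotypes with a known admixture excess, a species tree for
#' the trio, and a YAML config pointing at all of them.
#'
#' @param dir directory to create the files in.
#' @param seed integer seed controlling every generated input.
#' @param n_taxa number of taxa (multiple of 4; 6+ for meaningful PCA).
#' @param n_sites genotype sites.
#' @return The path of the written YAML config.
#' @export
demo_config <- function(dir, seed = 1L, n_taxa = 24L, n_sites = 20000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_taxa <- as.integer(n_taxa)
  taxa <- sprintf("tax%02d", seq_len(n_taxa))
  # clades follow the tree so regime shifts and clade hulls are meaningful
  tr <- gen_tree(n_taxa, seed + 17L)
  tr$tip.label <- taxa
  grp <- stats::cutree(stats::hclust(stats::as.dist(stats::cophenetic(tr)),
                                     method = "average"), k = 4L)
  clade <- c("A", "B", "C", "D")[grp[taxa]]
  outs <- list()
  for (i in seq_len(n_taxa)) {
    base <- switch(clade[i],
      A = list(L = 0.15, g = 0.0, dbl = FALSE, tl = 1.0, tc = 0.0),
      B = list(L = 0.35, g = 0.3, dbl = FALSE, tl = 2.0, tc = 0.3),
      C = list(L = 0.25, g = -0.2, dbl = TRUE, tl = 3.0, tc = -0.4),
      D = list(L = 0.45, g = 0.1, dbl = FALSE, tl = 1.5, tc = 0.8))
    jit <- with_seed(seed + 7L * i, stats::runif(4, -0.05, 0.05))
    for (s in 1:2) {
      pf <- flower_params("front", petal_count = 5L,
                          lobe_depth = min(0.6, max(0.05, base$L + jit[1L])),
                          dorsoventral_gradient = base$g + jit[2L],
                          lateral_doubling = base$dbl, asymmetry_sd = 0.015,
                          n_points = 240L, seed = seed + 1000L * i + s)
      ob <- gen_front_outline(pf)
      ob$specimen_id <- sprintf("%s_f%d", taxa[i], s)
      ob$taxon_id <- taxa[i]; ob$clade <- clade[i]
      outs <- c(outs, list(ob))
    }
    psd <- flower_params("side", tube_length = max(0.3, base$tl + 4 * jit[3L]),
                         tube_curvature = base$tc + jit[4L],
                         upper_lobe_excess = 1 + max(-0.5, jit[1L] * 4),
                         reflex_angle = 0.2 + jit[2L], n_points = 240L)
    ob <- gen_side_outline(psd)
    ob$specimen_id <- sprintf("%s_s1", taxa[i])
    ob$taxon_id <- taxa[i]; ob$clade <- clade[i]
    outs <- c(outs, list(ob))
  }
  write_outline_table(outs, file.path(dir, "outlines.csv"),
                      file.path(dir, "landmarks.csv"))
  ape::write.tree(tr, file.path(dir, "tree.nwk"))
  gt <- sim_genotypes(trio_sim_spec(n_sites = n_sites, p_discordance = 0.1,
                                    f_excess = 0.1, seed = seed + 23L))
  write_genotype_csv(gt, file.path(dir, "genotypes.csv"))
  writeLines("(((P1:1,P2:1):1,P3:2):1,OUT:3);", file.path(dir, "species_tree.nwk"))
  cfg <- list(outlines = "outlines.csv", landmarks = "landmarks.csv",
              tree = "tree.nwk", genotypes = "genotypes.csv",
              outgroup = "OUT", species_tree = "species_tree.nwk",
              views = c("front", "side"), n_pcs = 3L,
              k_range = c(2L, 8L), s_max = 6L,
              d_modes = c("BBAA", "min", "tree"),
              seed = seed, out_dir = "results")
  path <- file.path(dir, "demo-synthetic.yaml")
  yaml::write_yaml(cfg, path)
  path
}
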
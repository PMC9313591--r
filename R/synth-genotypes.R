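# Pattern-based trio genotype simulator.  D-statistics depend only on
# site-pattern frequencies, so sites are drawn directly from a mixture over
# {BBAA, ABBA, BABA, other}: a baseline discordance probability feeds ABBA
# and BABA equally (incomplete lineage sorting) and an admixture excess
# adds to ABBA only, giving the closed-form expectation
# D = f_e / (2 p_d + f_e).

#' Specification of a trio genotype simulation
#'
#' @param n_sites number of biallelic sites (>= 0).
#' @param n_individuals individuals per population (recycled over P1, P2,
#'   P3, outgroup).
#' @param p_discordance baseline probability that a site is ABBA-like or
#'   BABA-like under incomplete lineage sorting (each, in `[0, 0.5]`).
#' @param f_excess additional ABBA probability due to admixture
#'   (0 = null; must satisfy `f_excess <= 1 - 2 * p_discordance`).
#' @param p_bbaa probability of a concordant BBAA site.
#' @param block_size sites per contiguous jackknife block.
#' @param freq_noise per-individual allele-sampling noise: with noise `f`,
#'   genotypes are drawn Binomial(2, 1 - f) at derived and Binomial(2, f)
#'   at ancestral individuals of the focal populations (0 = fixed sites).
#' @param seed integer RNG seed.
#' @return A list of class `"trio_sim_spec"`.
#' @export
trio_sim_spec <- function(n_sites = 1e4, n_individuals = 4L,
                          p_discordance = 0.1, f_excess = 0, p_bbaa = 0.2,
                          block_size = NULL, freq_noise = 0, seed = 1L) {
  if (p_discordance < 0 || p_discordance > 0.5)
    stop("p_discordance must be in [0, 0.5]")
  if (f_excess < 0 || f_excess > 1 - 2 * p_discordance)
    stop("f_excess must be in [0, 1 - 2 * p_discordance]")
  if (p_bbaa < 0 || p_bbaa + 2 * p_discordance + f_excess > 1)
    stop("pattern probabilities must lie in [0, 1] and sum to at most 1")
  if (n_sites < 0) stop("n_sites must be >= 0")
  if (freq_noise < 0 || freq_noise >= 0.5) stop("freq_noise must be in [0, 0.5)")
  n_sites <- as.integer(n_sites)
  if (is.null(block_size)) block_size <- max(1L, ceiling(n_sites / 20))
  structure(list(n_sites = n_sites,
                 n_individuals = rep_len(as.integer(n_individuals), 4L),
                 p_discordance = p_discordance, f_excess = f_excess,
                 p_bbaa = p_bbaa, block_size = as.integer(block_size),
                 freq_noise = freq_noise, seed = as.integer(seed)),
            class = "trio_sim_spec")
}

#' Biallelic genotype table
#'
#' Container for derived-allele dosage genotypes (0/1/2) with a population
#' map, a designated outgroup and contiguous jackknife block ids.
#'
#' @param genotypes sites-by-individuals integer matrix of dosages 0/1/2
#'   (`NA` = missing call).
#' @param populations character vector, one population label per column.
#' @param outgroup the population playing the outgroup.
#' @param blocks integer vector of contiguous block ids, one per site.
#' @return A list of class `"genotype_table"`.
#' @export
genotype_table <- function(genotypes, populations, outgroup, blocks = NULL) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != length(populations))
    stop("one population label per genotype column is required")
  if (!outgroup %in% populations) stop("outgroup population not present")
  if (is.null(blocks)) blocks <- rep(1L, nrow(genotypes))
  blocks <- as.integer(blocks)
  if (length(blocks) != nrow(genotypes))
    stop("one block id per site is required")
  if (nrow(genotypes) > 0L && any(diff(blocks) < 0L))
    stop("block ids must be contiguous in site order")
  if (any(table(populations) == 0L)) stop("every population must be non-empty")
  structure(list(genotypes = genotypes, populations = as.character(populations),
                 outgroup = as.character(outgroup), blocks = blocks),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d sites x %d individuals, %d populations (outgroup %s), %d blocks\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$populations)), x$outgroup,
              length(unique(x$blocks))))
  invisible(x)
}

#' Simulate trio genotypes with known admixture excess
#'
#' Each site's pattern class is drawn from `{BBAA, ABBA, BABA, other}` with
#' probabilities `{p_bbaa, p_discordance + f_excess, p_discordance,
#' remainder}`; individuals of the populations carrying the derived allele
#' get dosage 2 (subject to optional `freq_noise`), the rest 0, and the
#' outgroup is fixed ancestral.  Block ids are assigned contiguously.
#'
#' @param spec a [trio_sim_spec()].
#' @return A [genotype_table()] with populations `P1, P2, P3, OUT` and
#'   outgroup `OUT`.
#' @export
sim_genotypes <- function(spec) {
  if (!inherits(spec, "trio_sim_spec")) stop("spec must be a trio_sim_spec")
  ni <- spec$n_individuals
  pops <- rep(c("P1", "P2", "P3", "OUT"), times = ni)
  ns <- spec$n_sites
  probs <- c(bbaa = spec$p_bbaa,
             abba = spec$p_discordance + spec$f_excess,
             baba = spec$p_discordance)
  probs <- c(probs, other = 1 - sum(probs))
  with_seed(spec$seed, {
    cls <- sample.int(4L, ns, replace = TRUE, prob = probs)
    # derived-population indicator per class for (P1, P2, P3); OUT always 0
    derived <- rbind(bbaa = c(1L, 1L, 0L),
                     abba = c(0L, 1L, 1L),
                     baba = c(1L, 0L, 1L),
                     other = c(0L, 0L, 0L))
    G <- matrix(0L, ns, length(pops))
    colnames(G) <- paste0(pops, ".", sequence(ni))
    for (p in 1:3) {
      cols <- which(pops == paste0("P", p))
      target <- derived[cls, p]                 # 0/1 per site
      if (spec$freq_noise > 0) {
        pr <- ifelse(target == 1L, 1 - spec$freq_noise, spec$freq_noise)
        for (cc in cols)
          G[, cc] <- stats::rbinom(ns, 2L, pr)
      } else {
        G[, cols] <- 2L * target
      }
    }
    blocks <- if (ns > 0L) (seq_len(ns) - 1L) %/% spec$block_size + 1L else integer(0)
    genotype_table(G, pops, outgroup = "OUT", blocks = blocks)
  })
}

#' Write / read a genotype table as long CSV
#'
#' Long format with one row per (site, individual):
#' `(site, block, pop, individual, genotype)`.
#'
#' @param gt a [genotype_table()].
#' @param path CSV path.
#' @return `write_genotype_csv`: the path, invisibly.
#' @export
write_genotype_csv <- function(gt, path) {
  ind <- colnames(gt$genotypes)
  if (is.null(ind)) ind <- paste0("ind", seq_len(ncol(gt$genotypes)))
  df <- data.frame(
    site = rep(seq_len(nrow(gt$genotypes)), times = ncol(gt$genotypes)),
    block = rep(gt$blocks, times = ncol(gt$genotypes)),
    pop = rep(gt$populations, each = nrow(gt$genotypes)),
    individual = rep(ind, each = nrow(gt$genotypes)),
    genotype = as.vector(gt$genotypes))
  df <- df[order(df$site, df$individual), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @param outgroup outgroup population label in the file.
#' @export
read_genotype_csv <- function(path, outgroup) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "block", "pop", "individual", "genotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sites <- sort(unique(df$site))
  inds <- unique(df[order(df$individual), c("individual", "pop")])
  G <- matrix(NA_integer_, length(sites), nrow(inds),
              dimnames = list(NULL, inds$individual))
  G[cbind(match(df$site, sites), match(df$individual, inds$individual))] <-
    df$genotype
  blocks <- df$block[match(sites, df$site)]
  genotype_table(G, inds$pop, outgroup = outgroup, blocks = blocks)
}
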
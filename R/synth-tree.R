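# Simulated phylogenies and Ornstein-Uhlenbeck trait evolution with
# optimum shifts.  Shifts are placed at the START of an edge and act on the
# whole edge and all its descendants, the same convention used by the
# shift-detection design matrix, so simulation and inference agree by
# construction.

#' Simulate a pure-birth tree rescaled to unit height
#'
#' Generates a rooted binary pure-birth (Yule) tree with `n_tips` tips,
#' rescales all branch lengths so the root-to-tip height is exactly 1, and
#' labels the tips `t1..tn`.  Deterministic under a fixed seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return An [ape::phylo] object of height 1.
#' @export
gen_tree <- function(n_tips, seed = 1L) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 2L) stop("n_tips must be >= 2")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tr)
  h <- max(depths[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length / h
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

# per-node depth from root and, per edge, depth of its start node
tree_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  list(node_depth = d,
       tip_depth = d[seq_len(ape::Ntip(tree))],
       edge_start = d[tree$edge[, 1L]],
       edge_end = d[tree$edge[, 2L]])
}

# edges (row indices of tree$edge) on the root-to-node path of each node
edge_paths <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent_edge <- integer(nn)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  root <- nt + 1L
  paths <- vector("list", nn)
  # process nodes in increasing depth order so parents are done first
  ord <- order(ape::node.depth.edgelength(tree))
  for (v in ord) {
    if (v == root) { paths[[v]] <- integer(0); next }
    e <- parent_edge[v]
    paths[[v]] <- c(paths[[tree$edge[e, 1L]]], e)
  }
  paths
}

#' Specification of an Ornstein-Uhlenbeck trait simulation
#'
#' @param alpha selection strength per trait (> 0; scalar recycled over traits).
#' @param sigma2 diffusion variance per trait (>= 0; 0 gives the
#'   deterministic optimum-tracking limit).
#' @param theta0 root optimum per trait.
#' @param q number of traits.
#' @param shifts optional data.frame with columns `edge` (row index of
#'   `tree$edge`) and `beta1..betaq` (or a single `beta` recycled over
#'   traits): optimum deltas applied from the start of the edge onward.
#' @param seed integer RNG seed.
#' @return A list of class `"ou_sim_spec"`.
#' @export
ou_sim_spec <- function(alpha = 1, sigma2 = 1, theta0 = 0, q = 1L,
                        shifts = NULL, seed = 1L) {
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1")
  alpha <- rep_len(alpha, q); sigma2 <- rep_len(sigma2, q)
  theta0 <- rep_len(theta0, q)
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0")
  structure(list(alpha = alpha, sigma2 = sigma2, theta0 = theta0, q = q,
                 shifts = shifts, seed = as.integer(seed)),
            class = "ou_sim_spec")
}

shift_beta_matrix <- function(shifts, q) {
  if (is.null(shifts) || nrow(shifts) == 0L)
    return(matrix(0, 0L, q))
  if ("beta" %in% names(shifts)) {
    b <- matrix(rep(shifts$beta, q), ncol = q)
  } else {
    cols <- paste0("beta", seq_len(q))
    miss <- setdiff(cols, names(shifts))
    if (length(miss)) stop("shifts lacks columns: ", paste(miss, collapse = ", "))
    b <- as.matrix(shifts[, cols, drop = FALSE])
  }
  b
}

#' Simulate Ornstein-Uhlenbeck traits on a tree
#'
#' Exact pre-order recursion: the root is drawn from the stationary
#' distribution `Normal(theta0, sigma2 / (2 alpha))` and each child node
#' from `Normal(parent * exp(-alpha l) + theta_edge * (1 - exp(-alpha l)),
#' sigma2 / (2 alpha) * (1 - exp(-2 alpha l)))` where `l` is the branch
#' length and `theta_edge` is the root optimum plus the summed shift deltas
#' of all shift edges on the root-to-edge path (inclusive).
#'
#' @param tree an [ape::phylo] tree.
#' @param spec an [ou_sim_spec()].
#' @return A tips-by-q numeric matrix with rownames `tree$tip.label`.
#' @export
sim_ou_traits <- function(tree, spec) {
  if (!inherits(spec, "ou_sim_spec")) stop("spec must be an ou_sim_spec")
  ne <- nrow(tree$edge)
  if (!is.null(spec$shifts) && nrow(spec$shifts) > 0L) {
    if (any(spec$shifts$edge < 1L | spec$shifts$edge > ne))
      stop("shift edge id outside the tree")
  }
  beta <- shift_beta_matrix(spec$shifts, spec$q)
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  # cumulative optimum per edge
  theta_edge <- matrix(rep(spec$theta0, each = ne), ne, spec$q)
  if (nrow(beta) > 0L) {
    paths <- edge_paths(tree)
    for (i in seq_len(nrow(beta))) {
      e <- spec$shifts$edge[i]
      # edges on or below e: those whose root-to-edge path contains e
      aff <- which(vapply(seq_len(ne), function(f)
        e %in% paths[[tree$edge[f, 2L]]], logical(1)))
      theta_edge[aff, ] <- theta_edge[aff, , drop = FALSE] +
        matrix(rep(beta[i, ], each = length(aff)), length(aff), spec$q)
    }
  }
  with_seed(spec$seed, {
    vals <- matrix(NA_real_, nn, spec$q)
    sv <- spec$sigma2 / (2 * spec$alpha)        # stationary variance
    vals[root, ] <- stats::rnorm(spec$q, spec$theta0, sqrt(sv))
    ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2L]])
    for (e in ord) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      l <- tree$edge.length[e]
      decay <- exp(-spec$alpha * l)
      mu <- vals[par, ] * decay + theta_edge[e, ] * (1 - decay)
      vv <- sv * (1 - exp(-2 * spec$alpha * l))
      vals[child, ] <- stats::rnorm(spec$q, mu, sqrt(vv))
    }
    traits <- vals[seq_len(nt), , drop = FALSE]
    rownames(traits) <- tree$tip.label
    colnames(traits) <- paste0("trait", seq_len(spec$q))
    traits
  })
}

#' Edges subtending disjoint mid-tree clades
#'
#' Picks up to `k` non-root edges whose descendant clades have between
#' `min_tips` and `max_tips` tips and are mutually disjoint (largest
#' first) -- convenient, identifiable places to put simulated optimum
#' shifts.
#'
#' @param tree an [ape::phylo] tree.
#' @param k how many edges to pick.
#' @param min_tips,max_tips clade-size bounds.
#' @return Integer vector of edge ids (row indices of `tree$edge`).
#' @export
pick_clade_edges <- function(tree, k = 3L, min_tips = 6L, max_tips = 16L) {
  nt <- ape::Ntip(tree)
  clade_tips <- function(e) {
    ch <- tree$edge[e, 2L]
    if (ch <= nt) ch
    else match(ape::extract.clade(tree, ch)$tip.label, tree$tip.label)
  }
  cnt <- vapply(seq_len(nrow(tree$edge)), function(e) length(clade_tips(e)),
                integer(1))
  dep <- tree_depths(tree)
  cand <- which(cnt >= min_tips & cnt <= max_tips & dep$edge_start > 1e-6)
  chosen <- integer(0); used <- logical(nt)
  for (e in cand[order(-cnt[cand])]) {
    tt <- clade_tips(e)
    if (!any(used[tt])) { chosen <- c(chosen, e); used[tt] <- TRUE }
    if (length(chosen) == k) break
  }
  chosen
}

#' Edges adjacent to an edge (itself, its parent, its children)
#'
#' @param tree an [ape::phylo] tree.
#' @param e edge id.
#' @return Integer vector of edge ids.
#' @export
adjacent_edges <- function(tree, e) {
  ch <- tree$edge[e, 2L]; pa <- tree$edge[e, 1L]
  unique(c(e, which(tree$edge[, 2L] == pa), which(tree$edge[, 1L] == ch)))
}
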
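# Synthetic tree-cloud generators.
#
# These stand in for the output of real tree inference (MCMC posterior
# samples, most-parsimonious-tree sets, bootstrap replicates) so the whole
# congruence pipeline can be exercised without running any inference.  The
# perturbation kernel is the nearest-neighbour interchange (NNI), the
# smallest topological move, which gives the finest control over expected
# distance from the focal topology; per-tree move counts are Poisson, so
# `dispersion` is the mean number of NNI moves separating a cloud member
# from its centre.  No claim is made that clouds match the geometry of a
# real MCMC posterior.

# Uniform random unrooted binary topology via sequential attachment of each
# new leaf to a uniformly chosen edge (uses the current RNG stream).
random_binary_newick <- function(labels) {
  n <- length(labels)
  edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2L,
                  byrow = TRUE)
  nxt <- n + 2L
  for (leaf in seq_len(n)[-(1:3)]) {
    e <- sample.int(nrow(edges), 1L)
    v <- edges[e, 2L]
    edges[e, 2L] <- nxt
    edges <- rbind(edges, c(nxt, v), c(nxt, leaf))
    nxt <- nxt + 1L
  }
  kids <- split(edges[, 2L], edges[, 1L])
  build <- function(node) {
    if (node <= n) return(labels[node])
    paste0("(", paste(vapply(kids[[as.character(node)]], build, character(1)),
                      collapse = ","), ")")
  }
  paste0(build(n + 1L), ";")
}

#' Uniformly random unrooted binary tree
#'
#' Draws a topology uniformly from the `(2n - 5)!!` unrooted binary trees
#' on the taxon set, by attaching each leaf in turn to a uniformly chosen
#' edge of the growing tree.
#'
#' @param taxa a character vector of labels, or a single integer `n`
#'   (labels `t01 ... tn`); at least 4 taxa.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return an unrooted binary `phylo`.
#' @export
random_binary_tree <- function(taxa, seed) {
  if (is.numeric(taxa) && length(taxa) == 1L) {
    taxa <- sprintf("t%02d", seq_len(taxa))
  }
  taxa <- as.character(taxa)
  if (length(taxa) < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels", call. = FALSE)
  with_local_seed(seed, ape::read.tree(text = random_binary_newick(taxa)))
}

# k successive NNI moves using the current RNG stream; returns the whole
# path (list of k + 1 trees starting at the input).
nni_path_ <- function(tree, k) {
  path <- vector("list", k + 1L)
  path[[1L]] <- tree
  for (i in seq_len(k)) {
    path[[i + 1L]] <- phangorn::rNNI(path[[i]], moves = 1L, n = 1L)
  }
  path
}

#' Random NNI perturbation of a binary tree
#'
#' Applies `k` successive nearest-neighbour interchanges at uniformly
#' chosen internal edges.  A single NNI replaces exactly one split, so
#' `k = 1` always yields RF distance 2 from the input.
#'
#' @param tree an unrooted binary `phylo`.
#' @param k number of moves (`k = 0` returns the tree unchanged).
#' @param seed integer seed.
#' @return the perturbed tree.
#' @export
nni_perturb <- function(tree, k, seed) {
  stopifnot(k >= 0)
  if (!is_fully_resolved(tree)) {
    stop("NNI perturbation requires a fully resolved (binary) tree",
         call. = FALSE)
  }
  if (k == 0L) return(tree)
  with_local_seed(seed, nni_path_(tree, k)[[k + 1L]])
}

cloud_ <- function(center, n, dispersion) {
  ks <- stats::rpois(n, dispersion)
  lapply(ks, function(k) {
    if (k == 0L) center else nni_path_(center, k)[[k + 1L]]
  })
}

#' Simulate a tree cloud around a focal topology
#'
#' Each of the `n` trees is the centre perturbed by `K` NNI moves with
#' `K ~ Poisson(dispersion)`; `dispersion = 0` gives `n` copies of the
#' centre.  The cloud emulates a posterior sample (or MPT/bootstrap set)
#' concentrated around a focal topology.
#'
#' @param center an unrooted binary `phylo`.
#' @param n number of trees.
#' @param dispersion mean NNI moves per tree, `>= 0`.
#' @param seed integer seed.
#' @param source,name passed to [tree_sample()].
#' @return a [tree_sample()].
#' @export
simulate_tree_cloud <- function(center, n, dispersion, seed,
                                source = "synthetic", name = NULL) {
  stopifnot(n >= 1, dispersion >= 0)
  if (!is_fully_resolved(center)) {
    stop("cloud centre must be a fully resolved (binary) tree", call. = FALSE)
  }
  trees <- with_local_seed(seed, cloud_(center, n, dispersion))
  tree_sample(trees, source = source, name = name)
}

#' Simulate a two-partition conflict scenario
#'
#' A synthetic twin of one combined-data study: a molecular truth drawn
#' uniformly at random, a morphological truth `conflict` NNI moves away,
#' and three tree clouds -- molecular, morphological and combined --
#' simulated around their respective centres.  The combined cloud's centre
#' sits on the recorded NNI path between the truths, at a position
#' proportional to the morphological share of parsimony-informative
#' characters (an explicit toy model of signal mixing: the bigger the
#' molecular partition, the closer the combined estimate to the molecular
#' truth).  Character counts are drawn per dataset: morphological
#' informative characters 1.5-5 times the taxon count and molecular ones
#' 10-50 times, echoing typical relative partition sizes of combined
#' datasets.
#'
#' @param n_taxa number of taxa, at least 6.
#' @param conflict number of NNI moves separating the two truths
#'   (`conflict = 0` makes them identical).
#' @param dispersion Poisson mean NNI moves within each cloud.
#' @param n_trees trees per cloud.
#' @param seed integer seed; the whole scenario is deterministic given it.
#' @return a list of class `partition_scenario`: `taxa`,
#'   `molecular_truth`, `morphological_truth`, `combined_center`,
#'   `conflict`, `dispersion`, `clouds` (named list of [tree_sample()]:
#'   `molecular`, `morphological`, `combined`), `n_morph_chars`,
#'   `n_mol_chars`, `p_morph`.
#' @export
simulate_partition_scenario <- function(n_taxa, conflict, dispersion = 1,
                                        n_trees = 100, seed) {
  stopifnot(n_taxa >= 6, conflict >= 0, n_trees >= 1)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  with_local_seed(seed, {
    mol_truth <- ape::read.tree(text = random_binary_newick(taxa))
    path <- nni_path_(mol_truth, conflict)
    morph_truth <- path[[conflict + 1L]]
    n_morph <- round(stats::runif(1, 1.5, 5) * n_taxa)
    n_mol <- round(stats::runif(1, 10, 50) * n_taxa)
    p_morph <- n_morph / (n_morph + n_mol)
    combined_center <- path[[1L + round(conflict * p_morph)]]
    clouds <- list(
      molecular = tree_sample(cloud_(mol_truth, n_trees, dispersion),
                              source = "bayes_posterior", name = "molecular"),
      morphological = tree_sample(cloud_(morph_truth, n_trees, dispersion),
                                  source = "bayes_posterior",
                                  name = "morphological"),
      combined = tree_sample(cloud_(combined_center, n_trees, dispersion),
                             source = "combined_posterior", name = "combined"))
    structure(list(taxa = taxa,
                   molecular_truth = mol_truth,
                   morphological_truth = morph_truth,
                   combined_center = combined_center,
                   conflict = conflict,
                   dispersion = dispersion,
                   clouds = clouds,
                   n_morph_chars = n_morph,
                   n_mol_chars = n_mol,
                   p_morph = p_morph),
              class = "partition_scenario")
  })
}

#' @export
print.partition_scenario <- function(x, ...) {
  cat(sprintf(paste0("<partition_scenario> %d taxa, conflict %d NNI, ",
                     "dispersion %.2g, %d trees/cloud\n"),
              length(x$taxa), x$conflict, x$dispersion,
              length(x$clouds$molecular)))
  cat(sprintf("  characters: %d morphological / %d molecular (p_morph = %.3f)\n",
              x$n_morph_chars, x$n_mol_chars, x$p_morph))
  invisible(x)
}
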
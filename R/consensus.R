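# Consensus construction and support-threshold collapsing.
#
# All consensus methods work from one substrate, the split frequency table
# of the sample.  Splits are admitted in descending frequency with ties
# broken lexicographically on the canonical split key (radix order), and --
# for majority-rule and greedy consensus -- subject to a compatibility check
# against everything already admitted, so the output is always a valid
# tree.  "Clade" support is interpreted throughout as unrooted split
# support, since every tree is unrooted.

#' Split frequencies of a tree sample
#'
#' The (weight-adjusted) fraction of trees in the sample containing each
#' nontrivial split.  This table underlies every consensus method, support
#' annotation, and maximum-clade-credibility scoring.
#'
#' @param sample a [tree_sample()].
#' @return a data frame of class `split_freq_table` with columns `split`
#'   (canonical key) and `frequency`, ordered by descending frequency then
#'   key; attributes `taxa`, `sides` (logical split matrix aligned with the
#'   rows) and `sample_size`.
#' @export
split_frequencies <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  taxa <- sample$taxa
  w <- sample$weights
  total <- sum(w)
  if (total <= 0) stop("sample has zero total weight", call. = FALSE)
  counts <- new.env(parent = emptyenv())
  sides_by_key <- new.env(parent = emptyenv())
  for (i in seq_along(sample$trees)) {
    if (ape::Ntip(sample$trees[[i]]) < 4L) next
    sm <- split_matrix(sample$trees[[i]], taxa)
    keys <- attr(sm, "keys")
    for (j in seq_along(keys)) {
      k <- keys[j]
      prev <- counts[[k]]
      if (is.null(prev)) {
        counts[[k]] <- w[i]
        sides_by_key[[k]] <- sm[j, ]
      } else {
        counts[[k]] <- prev + w[i]
      }
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / total, numeric(1))
  ord <- order(-freq, keys, method = "radix")
  keys <- keys[ord]; freq <- unname(freq[ord])
  sides <- matrix(FALSE, length(keys), length(taxa))
  for (j in seq_along(keys)) sides[j, ] <- sides_by_key[[keys[j]]]
  structure(data.frame(split = keys, frequency = freq,
                       stringsAsFactors = FALSE),
            taxa = taxa, sides = sides,
            sample_size = length(sample$trees),
            class = c("split_freq_table", "data.frame"))
}

# Greedily admit splits (already in admission order) subject to pairwise
# compatibility with everything admitted so far.
admit_compatible <- function(sides) {
  taken <- integer(0)
  for (i in seq_len(nrow(sides))) {
    if (compatible_with_all(sides[i, ], sides[taken, , drop = FALSE])) {
      taken <- c(taken, i)
    }
  }
  taken
}

consensus_from_table <- function(ft, min_freq, check_compat) {
  sides <- attr(ft, "sides")
  taxa <- attr(ft, "taxa")
  keep <- which(ft$frequency >= min_freq - 1e-9)
  sides <- sides[keep, , drop = FALSE]
  freq <- ft$frequency[keep]
  if (check_compat) {
    taken <- admit_compatible(sides)
    sides <- sides[taken, , drop = FALSE]
    freq <- freq[taken]
  }
  out <- tree_from_splits(sides, taxa, support = freq)
  attr(out, "support_scale") <- "posterior"
  out
}

#' Strict consensus tree
#'
#' Tree containing exactly the splits present in every tree of the sample.
#'
#' @param sample a [tree_sample()].
#' @return an unrooted `phylo` with split frequencies (all 1) as supports.
#' @export
strict_consensus <- function(sample) {
  consensus_from_table(split_frequencies(sample), 1, check_compat = FALSE)
}

#' 50% majority-rule consensus tree
#'
#' Splits occurring in at least half the trees, admitted in descending
#' frequency (ties lexicographic on the canonical key) with a compatibility
#' check: frequency-0.5 splits can be mutually incompatible in even-sized
#' samples, and the check guarantees a valid tree while the ordering makes
#' the choice deterministic.  Retained edges carry their frequency as
#' support.
#'
#' @param sample a [tree_sample()].
#' @return an unrooted `phylo` with frequency supports.
#' @export
majority_rule_consensus <- function(sample) {
  consensus_from_table(split_frequencies(sample), 0.5, check_compat = TRUE)
}

#' All-compatible (greedy) consensus tree
#'
#' Splits of any frequency admitted in descending frequency (ties
#' lexicographic) whenever compatible with everything already admitted; the
#' analogue of MrBayes' `sumt Contype = Allcompat` summary.  Always refines
#' or equals the majority-rule tree.
#'
#' @param sample a [tree_sample()].
#' @return an unrooted `phylo` with frequency supports.
#' @export
greedy_consensus <- function(sample) {
  consensus_from_table(split_frequencies(sample), 0, check_compat = TRUE)
}

#' Maximum clade credibility tree
#'
#' The sampled tree maximizing the sum of the sample frequencies of its
#' splits (ties broken by earliest position in the sample, for
#' reproducibility).  Note the score is a *sum* of split frequencies, not a
#' log-product of clade credibilities; the score is attached as attribute
#' `mcc_score`.
#'
#' @param sample a [tree_sample()].
#' @return the winning tree, unrooted, annotated with frequency supports;
#'   attributes `mcc_score` (its score) and `mcc_index` (its position).
#' @export
mcc_tree <- function(sample) {
  ft <- split_frequencies(sample)
  freq <- stats::setNames(ft$frequency, ft$split)
  scores <- vapply(sample$trees, function(t) {
    if (ape::Ntip(t) < 4L) return(0)
    sum(freq[tree_bipartitions(t)], na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)   # first maximum = earliest sample position
  out <- annotate_support(sample$trees[[best]], sample)
  attr(out, "mcc_score") <- scores[[best]]
  attr(out, "mcc_index") <- best
  out
}

#' Annotate a tree's edges with split frequencies from a sample
#'
#' Each internal edge of `tree` receives the frequency of its split in
#' `sample` as support (0 when the split never occurs).  For bootstrap
#' samples the frequency is expressed on the 0-100 percentage scale.
#'
#' @param tree a `phylo` on the sample's taxon set.
#' @param sample a [tree_sample()].
#' @return the unrooted tree with supports in `node.label` and the matching
#'   `support_scale` attribute.
#' @export
annotate_support <- function(tree, sample) {
  stopifnot(inherits(sample, "tree_sample"))
  if (!identical(canonical_taxa(tree$tip.label), sample$taxa)) {
    stop("tree and sample are not on the same taxon set", call. = FALSE)
  }
  ft <- split_frequencies(sample)
  freq <- stats::setNames(ft$frequency, ft$split)
  tr <- ape::unroot(tree)
  sm <- split_matrix(tr, sample$taxa)
  nt <- ape::Ntip(tr)
  lab <- rep("", tr$Nnode)
  f <- unname(freq[attr(sm, "keys")])
  f[is.na(f)] <- 0
  scale <- "posterior"
  if (sample$source == "bootstrap") {
    f <- 100 * f
    scale <- "bootstrap"
  }
  lab[attr(sm, "node") - nt] <- formatC(f, format = "g", digits = 15)
  tr$node.label <- lab
  attr(tr, "support_scale") <- scale
  tr
}

#' Collapse weakly supported edges
#'
#' Contracts every internal edge whose support is strictly less than `x`
#' (support exactly equal to `x` is retained); leaf edges are untouched.
#' `x = 0` is the identity, and collapsing composes:
#' `collapse_below(collapse_below(t, x1), x2) == collapse_below(t, max(x1, x2))`.
#'
#' @param tree a supported `phylo` (every internal edge must carry a
#'   numeric support on one scale).
#' @param x collapse threshold, on the tree's support scale.
#' @return the collapsed unrooted tree, supports retained.
#' @export
collapse_below <- function(tree, x) {
  stopifnot(is.numeric(x), length(x) == 1L)
  tr <- ape::unroot(tree)
  scale <- support_scale(tree)
  sm <- split_matrix(tr)
  sup <- attr(sm, "support")
  if (nrow(sm) > 0L && anyNA(sup)) {
    stop("missing supports on internal edges", call. = FALSE)
  }
  keep <- which(sup >= x)
  out <- tree_from_splits(sm[keep, , drop = FALSE], attr(sm, "taxa"),
                          support = sup[keep])
  attr(out, "support_scale") <- scale
  out
}

#' Iterative support-threshold collapse scan
#'
#' Collapses the tree at each threshold in turn and records the resolution,
#' the mean support of retained edges, and the proportional congruence of
#' the collapsed tree with a fully resolved reference, in both bipartition
#' and quartet flavours.  The default grids are 0, 0.01, ..., 0.99 on the
#' posterior scale and 0, 1, ..., 99 on the bootstrap scale.  Thresholds
#' at which the tree collapses to a star have no comparable relationships;
#' those rows are marked `excluded` and carry `NA` congruence.
#'
#' @param tree a supported `phylo`.
#' @param reference a fully resolved `phylo` on the same taxon set.
#' @param thresholds optional numeric vector of thresholds; defaults to the
#'   grid matching the tree's support scale.
#' @return a data frame of class `collapse_profile` with columns `x`,
#'   `n_internal_edges`, `mean_support`, `P_bip`, `P_quartet`, `excluded`.
#' @export
collapse_scan <- function(tree, reference, thresholds = NULL) {
  taxa <- check_same_taxa(tree, reference)
  if (!is_fully_resolved(reference)) {
    stop("reference must be fully resolved", call. = FALSE)
  }
  scale <- support_scale(tree)
  if (is.null(thresholds)) {
    thresholds <- switch(scale,
                         posterior = seq(0, 0.99, by = 0.01),
                         bootstrap = seq(0, 99, by = 1),
                         stop("tree has no supports to scan over",
                              call. = FALSE))
  }
  sm <- split_matrix(ape::unroot(tree), taxa)
  sup <- attr(sm, "support")
  if (nrow(sm) > 0L && anyNA(sup)) {
    stop("missing supports on internal edges", call. = FALSE)
  }
  keys <- attr(sm, "keys")
  n <- length(taxa)
  combs <- utils::combn(n, 4L)
  ref_keys <- tree_bipartitions(reference)
  ref_status <- quartet_status(split_matrix(reference, taxa), n, combs)
  rows <- lapply(thresholds, function(x) {
    keep <- which(sup >= x)
    m <- length(keep)
    if (m == 0L) {
      return(data.frame(x = x, n_internal_edges = 0L, mean_support = NA_real_,
                        P_bip = NA_real_, P_quartet = NA_real_,
                        excluded = TRUE))
    }
    q_status <- quartet_status(sm[keep, , drop = FALSE], n, combs)
    rq <- sum(q_status > 0L)
    data.frame(x = x,
               n_internal_edges = m,
               mean_support = mean(sup[keep]),
               P_bip = sum(keys[keep] %in% ref_keys) / m,
               P_quartet = sum(q_status > 0L & q_status == ref_status) / rq,
               excluded = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("collapse_profile", "data.frame")
  out
}
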
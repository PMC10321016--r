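# Internal split (bipartition) machinery.
#
# A split is stored as a logical membership vector over the canonical taxon
# order.  The canonical side is the side NOT containing the first taxon in
# canonical order, which makes equality and hashing well defined across trees
# sharing a taxon set.  Keys are the canonical-side labels joined with ",",
# in canonical taxon order; key comparisons use radix (locale-independent)
# ordering throughout.

# Canonical taxon order shared by every split-based computation.
canonical_taxa <- function(labels) {
  if (anyDuplicated(labels)) stop("duplicate taxon labels", call. = FALSE)
  if (length(labels) == 0L) stop("empty taxon set", call. = FALSE)
  sort(as.character(labels), method = "radix")
}

check_same_taxa <- function(t1, t2) {
  a <- canonical_taxa(t1$tip.label)
  b <- canonical_taxa(t2$tip.label)
  if (!identical(a, b)) {
    stop("trees are not on the same taxon set", call. = FALSE)
  }
  a
}

# Extract the nontrivial splits of an unrooted tree as a logical matrix
# (rows = splits, columns = taxa in canonical order), with per-split support
# values harvested from internal node labels (NA when absent) and the id of
# the internal node under each split's edge.
split_matrix <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(taxa)) taxa <- canonical_taxa(tree$tip.label)
  if (!identical(canonical_taxa(tree$tip.label), taxa)) {
    stop("tree labels do not match the taxon set", call. = FALSE)
  }
  n <- length(taxa)
  tr <- ape::unroot(tree)
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  memb <- matrix(FALSE, nt + nn, n)
  memb[cbind(seq_len(nt), match(tr$tip.label, taxa))] <- TRUE
  po <- stats::reorder(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    e <- po$edge[k, ]
    memb[e[1L], ] <- memb[e[1L], ] | memb[e[2L], ]
  }
  inner <- po$edge[, 2L][po$edge[, 2L] > nt]
  sides <- memb[inner, , drop = FALSE]
  sup <- rep(NA_real_, length(inner))
  if (!is.null(tr$node.label)) {
    raw <- tr$node.label[inner - nt]
    raw[!nzchar(raw)] <- NA
    sup <- suppressWarnings(as.numeric(raw))
  }
  # canonical side: must not contain the first canonical taxon
  flip <- sides[, 1L]
  sides[flip, ] <- !sides[flip, , drop = FALSE]
  sz <- rowSums(sides)
  keep <- sz >= 2L & sz <= n - 2L
  sides <- sides[keep, , drop = FALSE]
  structure(sides,
            taxa = taxa,
            support = sup[keep],
            node = inner[keep],
            keys = side_keys(sides, taxa))
}

side_keys <- function(sides, taxa) {
  if (nrow(sides) == 0L) return(character(0))
  apply(sides, 1L, function(s) paste(taxa[s], collapse = ","))
}

# Two splits on the same universe are compatible iff one of the four
# pairwise side intersections is empty.
splits_compatible <- function(s1, s2) {
  !any(s1 & s2) || !any(s1 & !s2) || !any(!s1 & s2) || !any(!s1 & !s2)
}

# TRUE iff `s` is compatible with every row of `sides`.
compatible_with_all <- function(s, sides) {
  for (i in seq_len(nrow(sides))) {
    if (!splits_compatible(s, sides[i, ])) return(FALSE)
  }
  TRUE
}

#' Build a tree from a set of pairwise-compatible splits
#'
#' Reconstructs the (unique) unrooted tree whose nontrivial splits are
#' exactly the given set, attaching `support` values as internal node
#' labels.  The splits must be pairwise compatible; sides are interpreted
#' over `taxa` in canonical (radix-sorted) order.
#'
#' @param sides logical matrix, one row per split, columns in canonical
#'   taxon order; each row is the side not containing the first taxon.
#'   A zero-row matrix yields the star tree.
#' @param taxa character vector of taxon labels (any order; canonicalised
#'   internally).
#' @param support optional numeric vector of per-split supports written as
#'   node labels.
#' @return an unrooted `phylo` object.
#' @export
tree_from_splits <- function(sides, taxa, support = NULL) {
  taxa <- canonical_taxa(taxa)
  n <- length(taxa)
  if (is.null(sides) || nrow(sides) == 0L) {
    return(ape::read.tree(text = paste0("(", paste(taxa, collapse = ","), ");")))
  }
  stopifnot(ncol(sides) == n)
  k <- nrow(sides)
  if (!is.null(support)) stopifnot(length(support) == k)
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      if (!splits_compatible(sides[i, ], sides[j, ])) {
        stop("splits are not pairwise compatible", call. = FALSE)
      }
    }
  }
  # Canonical sides exclude taxon 1, so they form a laminar family of
  # clusters: any two are nested or disjoint.  Parent of a cluster is the
  # smallest strictly-containing cluster (or the root = all taxa).
  sz <- rowSums(sides)
  cl_parent <- rep(0L, k)           # 0 = root
  for (i in seq_len(k)) {
    best <- 0L; best_sz <- n + 1L
    for (j in seq_len(k)) {
      if (j == i) next
      if (sz[j] > sz[i] && all(sides[i, ] <= sides[j, ]) && sz[j] < best_sz) {
        best <- j; best_sz <- sz[j]
      }
    }
    cl_parent[i] <- best
  }
  leaf_parent <- vapply(seq_len(n), function(t) {
    holders <- which(sides[, t])
    if (length(holders) == 0L) return(0L)
    holders[which.min(sz[holders])]
  }, integer(1))
  fmt <- function(x) {
    if (is.null(support) || is.na(x)) "" else formatC(x, format = "g", digits = 15)
  }
  build <- function(id) {
    kids_cl <- which(cl_parent == id)
    kids_leaf <- which(leaf_parent == id)
    parts <- c(vapply(kids_cl, build, character(1)), taxa[kids_leaf])
    lab <- if (id == 0L) "" else fmt(support[id])
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  tree <- ape::read.tree(text = paste0(build(0L), ";"))
  ape::unroot(tree)
}
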
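#' Nontrivial bipartitions of an unrooted tree
#'
#' Every internal edge of an unrooted tree splits the taxon set in two; the
#' nontrivial splits (both sides of size >= 2) are the currency of the
#' Robinson-Foulds metric and of split-based congruence statistics.  Splits
#' are returned as canonical string keys: the labels on the side *not*
#' containing the first taxon in canonical (radix-sorted) order, joined with
#' `","`.  The encoding is invariant to rooting and to the rotation of the
#' input representation.
#'
#' @param tree a `phylo` object (rooted inputs are unrooted first).
#' @return character vector of canonical split keys, one per internal edge;
#'   a fully resolved unrooted tree on `n >= 4` leaves yields `n - 3`.
#' @examples
#' tree_bipartitions(ape::read.tree(text = "((a,b),c,(d,e));"))
#' @export
tree_bipartitions <- function(tree) {
  if (ape::Ntip(tree) < 4L) stop("no nontrivial splits: fewer than 4 leaves",
                                 call. = FALSE)
  sm <- split_matrix(tree)
  unname(attr(sm, "keys"))
}

#' Restrict a tree to a subset of its taxa
#'
#' Induced topology on `subset`: drop all other leaves and suppress the
#' resulting degree-2 nodes.  Branch lengths and support labels are dropped,
#' since the restriction is a purely topological operation.
#'
#' @param tree a `phylo` object.
#' @param subset character vector of taxon labels, all present in `tree`,
#'   length >= 3.
#' @return an unrooted `phylo` on `subset`.
#' @export
restrict_tree <- function(tree, subset) {
  subset <- unique(as.character(subset))
  if (length(subset) < 3L) stop("subset must contain at least 3 taxa",
                                call. = FALSE)
  missing <- setdiff(subset, tree$tip.label)
  if (length(missing)) {
    stop("unknown taxa in subset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- ape::keep.tip(tree, subset)
  out$edge.length <- NULL
  out$node.label <- NULL
  ape::unroot(out)
}

#' Is a tree fully resolved (unrooted binary)?
#'
#' @param tree a `phylo` object; rooted inputs are judged after unrooting.
#' @return `TRUE` iff every internal node of the unrooted tree has degree
#'   exactly 3.
#' @export
is_fully_resolved <- function(tree) {
  tr <- ape::unroot(tree)
  n <- ape::Ntip(tr)
  if (n < 4L) return(TRUE)
  tr$Nnode == n - 2L
}
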
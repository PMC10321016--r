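# Tree distances, normalised by the maximum attainable distance: the sum of
# resolved bipartitions (RF) or resolved quartets across both trees.  The
# normalisation makes distances comparable across trees of different
# resolution, and reduces to the familiar RF/(2(n-3)) and classic quartet
# distance when both trees are binary.

#' Robinson-Foulds distance
#'
#' Number of bipartitions present in exactly one of the two trees,
#' `|B1 \ B2| + |B2 \ B1|`.
#'
#' @param t1,t2 `phylo` objects on the same taxon set.
#' @return a non-negative integer count.
#' @export
rf_distance <- function(t1, t2) {
  check_same_taxa(t1, t2)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Normalized Robinson-Foulds distance
#'
#' RF distance divided by its maximum attainable value for this pair,
#' `|B1| + |B2|` (the value reached when the trees share no split).  Two
#' star trees have no resolved splits at all; the distance is then reported
#' as 0 with attribute `degenerate = TRUE`.
#'
#' @inheritParams rf_distance
#' @return a value in `[0, 1]`; attribute `degenerate` flags the 0/0 case.
#' @examples
#' t1 <- parse_newick("((a,b),c,(d,e));")
#' t2 <- parse_newick("((a,c),b,(d,e));")
#' normalized_rf(t1, t2)   # 2/4
#' @export
normalized_rf <- function(t1, t2) {
  check_same_taxa(t1, t2)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  denom <- length(b1) + length(b2)
  if (denom == 0L) {
    return(structure(0, degenerate = TRUE))
  }
  d <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  structure(d / denom, degenerate = FALSE)
}

# Per-quartet resolution status of a tree: an integer vector over the
# columns of combn(n, 4) on the canonical taxon order; 0 = unresolved,
# 1 = {q1,q2}|{q3,q4}, 2 = {q1,q3}|{q2,q4}, 3 = {q1,q4}|{q2,q3}.
# A quartet is resolved iff some split separates it 2-2, and all splits of
# one tree that do so induce the same pairing.
quartet_status <- function(sides, n, combs = utils::combn(n, 4L)) {
  q <- ncol(combs)
  status <- integer(q)
  for (i in seq_len(nrow(sides))) {
    s <- sides[i, ]
    a <- s[combs[1L, ]]; b <- s[combs[2L, ]]
    c_ <- s[combs[3L, ]]; d <- s[combs[4L, ]]
    two <- (a + b + c_ + d) == 2L & status == 0L
    if (!any(two)) next
    pair <- ifelse(a == b, 1L, ifelse(a == c_, 2L, 3L))
    status[two] <- pair[two]
  }
  status
}

#' Quartet agreement tallies for a pair of trees
#'
#' For every 4-taxon subset, each tree induces one of the three resolved
#' quartet topologies or leaves the quartet unresolved.  The tallies drive
#' both the normalized quartet distance and quartet-flavoured proportional
#' congruence.
#'
#' @inheritParams rf_distance
#' @return a list of class `quartet_counts` with elements `r1`, `r2`
#'   (quartets resolved in each tree), `s` (resolved identically in both)
#'   and `q_total` (`choose(n, 4)`).
#' @export
quartet_counts <- function(t1, t2) {
  taxa <- check_same_taxa(t1, t2)
  n <- length(taxa)
  if (n < 4L) stop("quartet tallies require at least 4 taxa", call. = FALSE)
  combs <- utils::combn(n, 4L)
  s1 <- quartet_status(split_matrix(t1, taxa), n, combs)
  s2 <- quartet_status(split_matrix(t2, taxa), n, combs)
  structure(list(r1 = sum(s1 > 0L),
                 r2 = sum(s2 > 0L),
                 s = sum(s1 > 0L & s1 == s2),
                 q_total = ncol(combs)),
            class = "quartet_counts")
}

#' @export
print.quartet_counts <- function(x, ...) {
  cat(sprintf("<quartet_counts> r1=%d r2=%d shared=%d of %d quartets\n",
              x$r1, x$r2, x$s, x$q_total))
  invisible(x)
}

#' Normalized quartet distance
#'
#' `(r1 + r2 - 2s) / (r1 + r2)`: the number of quartet statements made by
#' exactly one tree or resolved differently by the two, divided by the
#' total number of resolved quartet statements across both trees (the
#' maximum attainable disagreement).  On two binary trees this equals the
#' classic quartet distance over `choose(n, 4)`.  Two star trees resolve
#' nothing; the distance is 0 with attribute `degenerate = TRUE`.
#'
#' @inheritParams rf_distance
#' @return a value in `[0, 1]` with attribute `degenerate`.
#' @export
normalized_quartet_distance <- function(t1, t2) {
  qc <- quartet_counts(t1, t2)
  denom <- qc$r1 + qc$r2
  if (denom == 0L) {
    return(structure(0, degenerate = TRUE))
  }
  structure((qc$r1 + qc$r2 - 2L * qc$s) / denom, degenerate = FALSE)
}
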
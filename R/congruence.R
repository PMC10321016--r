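# Proportional congruence: an asymmetric statistic comparing a (possibly
# partially resolved) query tree against a fully resolved reference tree.
# Because the reference resolves every relationship, every relationship the
# query asserts is comparable; the statistic is the fraction of the query's
# assertions that the reference agrees with.  It is comparable across
# datasets with different taxon counts and across consensus trees of
# different resolution, which symmetric distances are not.

check_congruence_pair <- function(query, reference) {
  taxa <- check_same_taxa(query, reference)
  if (!is_fully_resolved(reference)) {
    stop("reference must be fully resolved", call. = FALSE)
  }
  taxa
}

#' Proportional congruence over bipartitions
#'
#' The fraction of the query tree's bipartitions that also occur in the
#' fully resolved reference tree:
#' `|bipartitions(query) intersect bipartitions(reference)| / |bipartitions(query)|`.
#' A query with 5 bipartitions of which 4 occur in the reference scores
#' 0.8, regardless of how many additional splits the reference resolves.
#'
#' @param query a `phylo`, possibly partially resolved; must have at least
#'   one nontrivial bipartition (a star query is an error, not a zero).
#' @param reference a fully resolved `phylo` on the same taxon set.
#' @return a proportion in `[0, 1]`.
#' @export
proportional_congruence_bipartitions <- function(query, reference) {
  check_congruence_pair(query, reference)
  bq <- tree_bipartitions(query)
  if (length(bq) == 0L) {
    stop("no comparable bipartitions: query tree is a star", call. = FALSE)
  }
  br <- tree_bipartitions(reference)
  length(intersect(bq, br)) / length(bq)
}

#' Proportional congruence over quartet statements
#'
#' The fraction of the quartets resolved by the query whose resolution
#' matches the reference.  Since the reference is binary it resolves every
#' quartet, so every query-resolved quartet is comparable.
#'
#' @inheritParams proportional_congruence_bipartitions
#' @return a proportion in `[0, 1]`.
#' @export
proportional_congruence_quartets <- function(query, reference) {
  taxa <- check_congruence_pair(query, reference)
  n <- length(taxa)
  combs <- utils::combn(n, 4L)
  sq <- quartet_status(split_matrix(query, taxa), n, combs)
  r_query <- sum(sq > 0L)
  if (r_query == 0L) {
    stop("no comparable quartet statements: query tree is a star",
         call. = FALSE)
  }
  sr <- quartet_status(split_matrix(reference, taxa), n, combs)
  sum(sq > 0L & sq == sr) / r_query
}

#' Mean proportional congruence of a tree sample
#'
#' Arithmetic mean of the per-tree proportional congruence of every tree in
#' the sample against a fully resolved reference.  Star queries carry no
#' comparable relationships and are excluded from the mean rather than
#' coerced to 0 or 1; the exclusion count is always reported.
#'
#' @param queries a [tree_sample()].
#' @param reference a fully resolved `phylo` on the sample's taxon set.
#' @param flavor `"bipartition"` or `"quartet"`.
#' @return the mean congruence (numeric scalar) with attributes `n_used`,
#'   `n_excluded` and `values` (per-tree results, `NA` where excluded).
#' @export
mean_proportional_congruence <- function(queries, reference,
                                         flavor = c("bipartition", "quartet")) {
  stopifnot(inherits(queries, "tree_sample"))
  flavor <- match.arg(flavor)
  f <- switch(flavor,
              bipartition = proportional_congruence_bipartitions,
              quartet = proportional_congruence_quartets)
  vals <- vapply(queries$trees, function(t) {
    tryCatch(f(t, reference), error = function(e) {
      if (grepl("no comparable", conditionMessage(e))) NA_real_ else stop(e)
    })
  }, numeric(1))
  used <- !is.na(vals)
  if (!any(used)) {
    stop("every query tree was excluded (no comparable relationships)",
         call. = FALSE)
  }
  structure(mean(vals[used]),
            n_used = sum(used),
            n_excluded = sum(!used),
            values = vals)
}
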
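SAMPLE_SOURCES <- c("bayes_posterior", "mpt_equal_weights",
                    "mpt_implied_weights", "bootstrap",
                    "combined_posterior", "synthetic")

#' An ordered collection of trees on a shared taxon set
#'
#' Groups a set of trees (a Bayesian posterior sample, a set of most
#' parsimonious trees, bootstrap replicates, or a synthetic cloud) with a
#' source tag and optional per-tree multiplicities.  All trees must share
#' one taxon set; this is checked at construction.
#'
#' @param trees a `multiPhylo` object or list of `phylo` objects; non-empty.
#' @param source one of `"bayes_posterior"`, `"mpt_equal_weights"`,
#'   `"mpt_implied_weights"`, `"bootstrap"`, `"combined_posterior"`,
#'   `"synthetic"`.
#' @param weights optional non-negative per-tree multiplicities (default:
#'   all 1).
#' @param name optional display label used e.g. in pooled distance
#'   matrices; defaults to `source`.
#' @return an object of class `tree_sample`.
#' @export
tree_sample <- function(trees, source = "synthetic", weights = NULL,
                        name = NULL) {
  source <- match.arg(source, SAMPLE_SOURCES)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("a tree sample must be non-empty", call. = FALSE)
  taxa <- canonical_taxa(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!identical(canonical_taxa(t$tip.label), taxa)) {
      stop("all trees in a sample must share one taxon set", call. = FALSE)
    }
  }
  if (is.null(weights)) {
    weights <- rep(1, length(trees))
  } else {
    stopifnot(length(weights) == length(trees), all(weights >= 0))
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, source = source, weights = weights,
                 taxa = taxa, name = if (is.null(name)) source else name),
            class = "tree_sample")
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("<tree_sample> %d trees on %d taxa (source: %s, name: %s)\n",
              length(x$trees), length(x$taxa), x$source, x$name))
  invisible(x)
}
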
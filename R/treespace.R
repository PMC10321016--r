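# Treespace ordination: pooled pairwise distance matrices over labelled
# tree samples and their classical multidimensional scaling (principal
# coordinates) into 2 axes.

#' Random subsample of a tree sample
#'
#' Draws `n` trees uniformly without replacement (original order kept);
#' when the sample holds `n` trees or fewer the whole sample is returned
#' unchanged, the conventional treatment of e.g. a most-parsimonious-tree
#' set smaller than the subsampling target.
#'
#' @param sample a [tree_sample()].
#' @param n target size (default 1000, the customary treespace subsample).
#' @param seed integer seed; the draw is deterministic given the seed and
#'   does not disturb the caller's RNG state.
#' @return a [tree_sample()].
#' @export
subsample_trees <- function(sample, n = 1000, seed) {
  stopifnot(inherits(sample, "tree_sample"), n >= 1)
  if (length(sample) <= n) return(sample)
  idx <- sort(with_local_seed(seed, sample.int(length(sample), n)))
  tree_sample(sample$trees[idx], source = sample$source,
              weights = sample$weights[idx], name = sample$name)
}

#' Pooled pairwise tree distance matrix
#'
#' Normalized RF or quartet distances between every pair of trees pooled
#' across one or more labelled samples (all on one taxon set).  Sample
#' names and within-sample indices are kept, so downstream ordination can
#' colour points by their source.  Quartet distances over pools larger
#' than 500 trees are refused unless `allow_large = TRUE`, as the cost
#' grows with `choose(n, 4)` statuses per tree and the square of the pool.
#'
#' @param samples a [tree_sample()] or list of them.
#' @param metric `"rf"` or `"quartet"` (normalized in both cases).
#' @param allow_large override the 500-tree guard for the quartet metric.
#' @return a symmetric matrix of class `tree_distance_matrix` with zero
#'   diagonal, attributes `labels` (data frame: `sample`, `index`) and
#'   `metric`.
#' @export
pooled_distance_matrix <- function(samples, metric = c("rf", "quartet"),
                                   allow_large = FALSE) {
  metric <- match.arg(metric)
  if (inherits(samples, "tree_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  taxa <- samples[[1L]]$taxa
  for (s in samples) {
    stopifnot(inherits(s, "tree_sample"))
    if (!identical(s$taxa, taxa)) {
      stop("all samples must share one taxon set", call. = FALSE)
    }
  }
  trees <- do.call(c, lapply(samples, function(s) unclass(s$trees)))
  labels <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = rep(s$name, length(s)), index = seq_len(length(s)),
               stringsAsFactors = FALSE)
  }))
  m <- length(trees)
  if (metric == "quartet" && m > 500L && !allow_large) {
    stop("quartet metric on a pool of ", m,
         " trees; pass allow_large = TRUE to override", call. = FALSE)
  }
  n <- length(taxa)
  D <- matrix(0, m, m)
  if (metric == "rf") {
    keysets <- lapply(trees, function(t) attr(split_matrix(t, taxa), "keys"))
    sizes <- lengths(keysets)
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        denom <- sizes[i] + sizes[j]
        if (denom == 0L) next
        shared <- sum(keysets[[i]] %in% keysets[[j]])
        D[i, j] <- D[j, i] <- (denom - 2 * shared) / denom
      }
    }
  } else {
    combs <- utils::combn(n, 4L)
    stat <- lapply(trees, function(t) {
      quartet_status(split_matrix(t, taxa), n, combs)
    })
    res <- lapply(stat, function(s) s > 0L)
    r <- vapply(res, sum, numeric(1))
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        denom <- r[i] + r[j]
        if (denom == 0) next
        s <- sum(res[[i]] & stat[[i]] == stat[[j]])
        D[i, j] <- D[j, i] <- (denom - 2 * s) / denom
      }
    }
  }
  structure(D, labels = labels, metric = paste0(metric, "_normalized"),
            class = c("tree_distance_matrix", "matrix", "array"))
}

#' Classical multidimensional scaling of a tree distance matrix
#'
#' Principal-coordinates embedding: the squared-distance matrix is double
#' centered and eigendecomposed; coordinates are the top-`k` eigenvectors
#' scaled by the square roots of their eigenvalues.  Tree distances are
#' generally non-Euclidean, so negative eigenvalues can occur; they are
#' clamped to zero for coordinates, the clamp count is reported, and
#' variance explained is taken over the positive part of the spectrum
#' only.
#'
#' @param D a `tree_distance_matrix`, plain symmetric matrix, or `dist`,
#'   over at least 3 points.
#' @param k number of retained axes (default 2).
#' @return a list of class `tree_mds`: `points` (n x k), `eigenvalues`
#'   (full spectrum), `variance_explained` (per retained axis),
#'   `n_negative` (clamped eigenvalues), `degenerate` (no positive
#'   eigenvalue at all, e.g. an all-zero matrix), `labels`.
#' @export
classical_mds <- function(D, k = 2) {
  labels <- attr(D, "labels")
  d <- stats::as.dist(D)
  npt <- attr(d, "Size")
  if (npt < 3L) stop("classical MDS needs at least 3 trees", call. = FALSE)
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- fit$eig
  pos <- eig[eig > 1e-12]
  degenerate <- length(pos) == 0L
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {     # non-positive axes were dropped
    pad <- matrix(0, npt, k - if (is.null(pts)) 0L else ncol(pts))
    pts <- cbind(pts, pad)
  }
  ve <- if (degenerate) rep(NA_real_, k) else pmax(eig[seq_len(k)], 0) / sum(pos)
  structure(list(points = pts,
                 eigenvalues = eig,
                 variance_explained = ve,
                 n_negative = sum(eig < -1e-12),
                 degenerate = degenerate,
                 labels = labels),
            class = "tree_mds")
}

#' @export
print.tree_mds <- function(x, ...) {
  cat(sprintf("<tree_mds> %d trees, %d axes", nrow(x$points), ncol(x$points)))
  if (x$degenerate) {
    cat(" (degenerate: no positive eigenvalue)\n")
  } else {
    cat(sprintf("; variance explained %s\n",
                paste(sprintf("%.1f%%", 100 * x$variance_explained),
                      collapse = " + ")))
  }
  invisible(x)
}
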
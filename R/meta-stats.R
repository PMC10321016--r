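#' Correlation between morphological partition share and tree distance
#'
#' Across datasets, correlates the proportion of parsimony-informative
#' characters that are morphological with the distance between the
#' combined-data and molecular-only consensus trees.  The primary
#' statistic is the Pearson product-moment correlation with the usual
#' two-sided t-test on `n - 2` degrees of freedom; a Spearman rank option
#' is provided since rank correlation is the customary robustness
#' companion for such cross-dataset comparisons.
#'
#' @param p_morph numeric vector in `(0, 1)`: per-dataset morphological
#'   character proportions.
#' @param distance numeric vector in `[0, 1]`: per-dataset tree distances
#'   (same length).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a list with `r` (correlation), `p_value` (two-sided), `n`,
#'   `method`.
#' @export
partition_size_correlation <- function(p_morph, distance,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(p_morph) == length(distance))
  ok <- is.finite(p_morph) & is.finite(distance)
  if (!all(ok)) stop("non-finite values in input", call. = FALSE)
  n <- length(p_morph)
  if (n < 3L) stop("need at least 3 records", call. = FALSE)
  if (stats::sd(p_morph) == 0 || stats::sd(distance) == 0) {
    stop("correlation undefined: zero variance in an input variable",
         call. = FALSE)
  }
  ct <- stats::cor.test(p_morph, distance, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n, method = method)
}
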
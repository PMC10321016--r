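# Bayes-factor combinability verdicts.
#
# Two models of a combined (e.g. molecular + morphological) dataset are
# compared by marginal likelihood: M1 gives each partition its own topology
# and branch lengths; M2 links the topology and gives partitions only
# independent branch lengths.  M1 has more free parameters and is expected
# to fit better; only a *decisive* advantage for the unlinked model is
# evidence that the partitions conflict too much to combine.

#' Per-model marginal-likelihood estimates
#'
#' @param runs numeric vector of log marginal likelihoods, one per
#'   independent estimation run (e.g. stepping-stone analyses); all finite.
#' @param model `"M1_unlinked"` (partition-specific topologies) or
#'   `"M2_linked"` (one shared topology).
#' @return an object of class `marginal_likelihood_set`.
#' @export
marginal_likelihood_set <- function(runs, model = c("M1_unlinked", "M2_linked")) {
  model <- match.arg(model)
  runs <- as.numeric(runs)
  if (length(runs) == 0L) stop("at least one run estimate is required",
                               call. = FALSE)
  if (!all(is.finite(runs))) stop("non-finite marginal likelihood estimate",
                                  call. = FALSE)
  structure(list(model = model, run_estimates = runs),
            class = "marginal_likelihood_set")
}

#' Read marginal-likelihood runs from a TSV file
#'
#' Expects columns `model` (values `M1`/`M1_unlinked` and
#' `M2`/`M2_linked`), `run`, and `log_marginal_likelihood`.
#'
#' @param path TSV file path.
#' @return a list with elements `m1` and `m2`, each a
#'   [marginal_likelihood_set()].
#' @export
read_marginal_likelihoods <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("model", "run", "log_marginal_likelihood")
  if (!all(need %in% names(tab))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  pick <- function(tag, full) tab$model %in% c(tag, full)
  m1 <- tab$log_marginal_likelihood[pick("M1", "M1_unlinked")]
  m2 <- tab$log_marginal_likelihood[pick("M2", "M2_linked")]
  list(m1 = marginal_likelihood_set(m1, "M1_unlinked"),
       m2 = marginal_likelihood_set(m2, "M2_linked"))
}

#' Convergence check for repeated marginal-likelihood runs
#'
#' Independent runs of a converged estimator should agree closely; the
#' rule used here is that the sample standard deviation of the run
#' estimates is at most `sd_threshold` log units (default 5).  A single
#' run cannot be assessed and returns `FALSE` with a warning.
#'
#' @param x a [marginal_likelihood_set()] or numeric vector of run
#'   estimates.
#' @param sd_threshold maximum acceptable standard deviation, log units.
#' @return `TRUE`/`FALSE`.
#' @export
convergence_check <- function(x, sd_threshold = 5) {
  runs <- if (inherits(x, "marginal_likelihood_set")) x$run_estimates else
    as.numeric(x)
  if (length(runs) == 0L) stop("empty marginal likelihood set", call. = FALSE)
  if (length(runs) == 1L) {
    warning("single run: convergence not assessable", call. = FALSE)
    return(FALSE)
  }
  stats::sd(runs) <= sd_threshold
}

#' Bayes-factor combinability verdict
#'
#' The Bayes factor is `mean(M1 runs) - mean(M2 runs)` in log units.  By
#' default (`direction = "unlinked_wins"`) a large advantage for the
#' unlinked model M1 is evidence of incongruence: `bf >= 5` is very strong
#' (`very_strong_incongruence`), `3 <= bf < 5` strong
#' (`strong_incongruence`), and `bf < 3` leaves little evidence against
#' linking, so the combined model with fewest free parameters (M2) is
#' favoured (`combinable`).  `direction = "linked_wins"` applies the same
#' thresholds to the sign-flipped statistic, for sensitivity analysis.  A
#' verdict computed from non-converged runs is flagged `reliable = FALSE`.
#'
#' @param m1,m2 [marginal_likelihood_set()] objects (or numeric run
#'   vectors) for the unlinked and linked models.
#' @param direction which model's advantage counts as incongruence
#'   evidence; default `"unlinked_wins"`.
#' @param sd_threshold convergence rule passed to [convergence_check()].
#' @return a list of class `combinability_verdict`: `bf`, `category`,
#'   `converged_m1`, `converged_m2`, `reliable`, `direction`.
#' @export
bayes_factor_verdict <- function(m1, m2,
                                 direction = c("unlinked_wins", "linked_wins"),
                                 sd_threshold = 5) {
  direction <- match.arg(direction)
  if (!inherits(m1, "marginal_likelihood_set")) {
    m1 <- marginal_likelihood_set(m1, "M1_unlinked")
  }
  if (!inherits(m2, "marginal_likelihood_set")) {
    m2 <- marginal_likelihood_set(m2, "M2_linked")
  }
  bf <- mean(m1$run_estimates) - mean(m2$run_estimates)
  d <- if (direction == "unlinked_wins") bf else -bf
  category <- if (d >= 5) "very_strong_incongruence"
              else if (d >= 3) "strong_incongruence"
              else "combinable"
  c1 <- length(m1$run_estimates) >= 2L &&
    stats::sd(m1$run_estimates) <= sd_threshold
  c2 <- length(m2$run_estimates) >= 2L &&
    stats::sd(m2$run_estimates) <= sd_threshold
  structure(list(bf = bf, category = category,
                 converged_m1 = c1, converged_m2 = c2,
                 reliable = c1 && c2, direction = direction),
            class = "combinability_verdict")
}

#' @export
print.combinability_verdict <- function(x, ...) {
  cat(sprintf("<combinability_verdict> bf = %.3f log units -> %s%s\n",
              x$bf, x$category,
              if (x$reliable) "" else "  [unreliable: non-converged runs]"))
  invisible(x)
}
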
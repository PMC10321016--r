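# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library calls never perturb a user's simulation stream.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Write a result table as tab-separated values
#'
#' All tabular results in the package (collapse profiles, distance summaries,
#' correlation tables) serialise through this writer: one header row, UTF-8,
#' `"."` as the decimal separator, no row names and no quoting.
#'
#' @param x a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, dec = ".",
                     fileEncoding = "UTF-8")
  invisible(path)
}
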
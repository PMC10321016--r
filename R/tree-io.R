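# Newick / NEXUS input-output.
#
# Dialect notes:
# * Support values are harvested with fixed precedence: a MrBayes-style
#   comment annotation after a closing parenthesis ("[&prob=0.98]" or a bare
#   "[0.98]") wins over a numeric internal-node label; a conflict raises a
#   warning and the comment value is kept.
# * Underscores inside unquoted labels are preserved verbatim (no space
#   substitution).
# * All trees are unrooted on input: a degree-2 root is suppressed
#   mechanically, and downstream computations are split-based.

#' Parse a Newick string into an unrooted tree with supports
#'
#' Internal-edge supports are read from (in precedence order) MrBayes-style
#' square-bracket comment annotations after closing parentheses, then
#' numeric internal node labels.  The support scale is inferred from the
#' values: all within `[0, 1]` is a posterior-probability scale, values in
#' `(1, 100]` a bootstrap-percentage scale.  The inferred scale is attached
#' as attribute `"support_scale"` (`"posterior"`, `"bootstrap"` or
#' `"none"`) and can be re-derived at any time with [support_scale()].
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @return an unrooted `phylo`; supports, if any, are in `node.label`.
#' @examples
#' tr <- parse_newick("((a,b)0.95,c,(d,e)0.40);")
#' support_scale(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_balanced(text)
  txt <- harvest_comment_supports(text)
  txt <- gsub("\\[[^]]*\\]", "", txt)   # drop remaining comments
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse error", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate taxon labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree <- ape::unroot(tree)
  attr(tree, "support_scale") <- infer_support_scale(tree)
  tree
}

check_balanced <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parenthesis at position ", i,
                           call. = FALSE)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth,
                        " unclosed at end of input", call. = FALSE)
  invisible(TRUE)
}

# Rewrite ")[&prob=0.98]lab" as ")0.98", warning when a numeric label
# disagrees with the comment annotation.
harvest_comment_supports <- function(text) {
  m <- gregexpr("\\)\\s*\\[([^]]*)\\]([^,();:\\[]*)", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(text)
  pieces <- regmatches(text, gregexpr("\\)\\s*\\[([^]]*)\\]([^,();:\\[]*)",
                                      text, perl = TRUE))[[1L]]
  for (p in pieces) {
    comment <- sub("^\\)\\s*\\[([^]]*)\\].*$", "\\1", p)
    label <- sub("^\\)\\s*\\[[^]]*\\]", "", p)
    val <- comment_support_value(comment)
    if (is.na(val)) next
    lab_num <- suppressWarnings(as.numeric(label))
    if (nzchar(label) && !is.na(lab_num) && lab_num != val) {
      warning("support annotation conflict (comment ", val, " vs label ",
              lab_num, "); comment wins", call. = FALSE)
    }
    text <- sub(p, paste0(")", formatC(val, format = "g", digits = 15)),
                text, fixed = TRUE)
  }
  text
}

comment_support_value <- function(comment) {
  for (field in c("prob", "posterior", "support")) {
    pat <- paste0("(^|[,&])", field, "=([0-9.eE+-]+)")
    if (grepl(pat, comment)) {
      return(suppressWarnings(
        as.numeric(sub(paste0(".*", pat, ".*"), "\\2", comment))))
    }
  }
  bare <- sub("^&?\\s*([0-9.eE+-]+)\\s*$", "\\1", comment)
  suppressWarnings(as.numeric(bare))
}

infer_support_scale <- function(tree) {
  if (is.null(tree$node.label)) return("none")
  v <- suppressWarnings(as.numeric(tree$node.label))
  v <- v[!is.na(v)]
  if (length(v) == 0L) return("none")
  if (all(v >= 0 & v <= 1)) return("posterior")
  if (all(v >= 0 & v <= 100)) return("bootstrap")
  warning("support values outside [0, 100]; scale set to none", call. = FALSE)
  "none"
}

#' Support scale of a tree
#'
#' @param tree a `phylo`.
#' @return `"posterior"`, `"bootstrap"` or `"none"`, from the cached
#'   attribute if present, otherwise re-inferred from the node labels.
#' @export
support_scale <- function(tree) {
  sc <- attr(tree, "support_scale")
  if (!is.null(sc)) return(sc)
  infer_support_scale(tree)
}

#' Read a NEXUS trees block as a tree sample with burnin
#'
#' Reads the `trees` block of a NEXUS file (translate tables are resolved to
#' labels; order is preserved) and discards the first
#' `floor(burnin_fraction * N)` trees, the conventional treatment of an
#' MCMC sample whose opening fraction has not reached stationarity.
#'
#' @param x path to a NEXUS file, or the file content as a character string.
#' @param burnin_fraction fraction in `[0, 1)` of leading trees to discard.
#' @param source source tag for the resulting [tree_sample()].
#' @param name optional sample label.
#' @return a [tree_sample()] of the post-burnin trees, each unrooted.
#' @export
parse_nexus_trees <- function(x, burnin_fraction = 0,
                              source = "bayes_posterior", name = NULL) {
  stopifnot(is.numeric(burnin_fraction), length(burnin_fraction) == 1L,
            burnin_fraction >= 0, burnin_fraction < 1)
  path <- x
  if (length(x) > 1L || grepl("\n", x) || grepl("^\\s*#NEXUS", x[1L])) {
    path <- tempfile(fileext = ".nex")
    writeLines(x, path)
    on.exit(unlink(path))
  }
  content <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("begin\\s+trees", content, ignore.case = TRUE)) {
    stop("no trees block in NEXUS input", call. = FALSE)
  }
  trees <- ape::read.nexus(path, force.multi = TRUE)
  n <- length(trees)
  drop <- floor(burnin_fraction * n)
  if (drop >= n) stop("burnin discards every tree", call. = FALSE)
  kept <- lapply(seq.int(drop + 1L, n), function(i) ape::unroot(trees[[i]]))
  tree_sample(kept, source = source, name = name)
}

#' Serialize a tree to Newick
#'
#' Round-trip guarantee: `parse_newick(write_newick(t))` has the same split
#' set and the same split-to-support mapping as `t`.
#'
#' @param tree a `phylo`.
#' @param include_support keep internal node labels (supports) in the
#'   output?
#' @return a Newick string.
#' @export
write_newick <- function(tree, include_support = TRUE) {
  if (!include_support) tree$node.label <- NULL
  ape::write.tree(tree)
}
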
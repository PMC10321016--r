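# Shared fixtures and independent oracles, all built in code.

nwk <- function(text) parse_newick(text)

# Canonical 5-taxon pair used across the distance/congruence tests:
# shares only the split de|abc.
pair5 <- function() {
  list(t1 = nwk("((a,b),c,(d,e));"),
       t2 = nwk("((a,c),b,(d,e));"))
}

# A supported sample {T1, T1, T2}: split frequencies de|abc = 1,
# ab|cde = 2/3, ac|bde = 1/3.
sample_t1t1t2 <- function() {
  p <- pair5()
  tree_sample(list(p$t1, p$t1, p$t2), source = "bayes_posterior")
}

random_tree <- function(n, seed) random_binary_tree(n, seed = seed)

# Independent split-set oracle built on ape::prop.part (clade-based, a
# different route than the package's edge-membership accumulation).
oracle_split_keys <- function(tree) {
  tr <- ape::unroot(tree)
  n <- ape::Ntip(tr)
  taxa <- sort(tr$tip.label, method = "radix")
  pp <- ape::prop.part(tr)
  keys <- vapply(pp, function(idx) {
    side <- sort(tr$tip.label[idx], method = "radix")
    if (taxa[1L] %in% side) side <- setdiff(taxa, side)
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(side, collapse = ",")
  }, character(1))
  sort(unique(keys[!is.na(keys)]), method = "radix")
}

# Brute-force quartet oracle: restrict the tree to each 4-subset with
# ape::keep.tip and read the cherry structure directly.
# Returns 0 (unresolved) or the pairing code of the sorted quartet
# (1 = q1q2|q3q4, 2 = q1q3|q2q4, 3 = q1q4|q2q3).
oracle_quartet_one <- function(tree, quartet) {
  labs <- sort(quartet, method = "radix")
  tr4 <- ape::unroot(ape::keep.tip(tree, labs))
  if (tr4$Nnode < 2L) return(0L)
  tip_parent <- tr4$edge[match(seq_len(4L), tr4$edge[, 2L]), 1L]
  names(tip_parent) <- tr4$tip.label
  partner <- names(tip_parent)[names(tip_parent) != labs[1L] &
                               tip_parent == tip_parent[labs[1L]]]
  match(partner, labs) - 1L
}

oracle_quartet_counts <- function(t1, t2) {
  taxa <- sort(t1$tip.label, method = "radix")
  quartets <- utils::combn(taxa, 4L)
  s1 <- apply(quartets, 2L, function(q) oracle_quartet_one(t1, q))
  s2 <- apply(quartets, 2L, function(q) oracle_quartet_one(t2, q))
  list(r1 = sum(s1 > 0L), r2 = sum(s2 > 0L),
       s = sum(s1 > 0L & s1 == s2), q_total = ncol(quartets))
}

# Concrete realisation of the textbook proportional-congruence example:
# a fully resolved 13-taxon reference (10 bipartitions) and a partially
# resolved query with 5 bipartitions, 4 of which occur in the reference.
worked_example_trees <- function() {
  ref <- parse_newick(paste0(
    "(((((((((((t01,t02),t03),t04),t05),t06),t07),t08),t09),t10),t11),",
    "t12,t13);"))
  query <- parse_newick(paste0(
    "(((((t01,t02),t03),t04),t05),(t06,t08),t07,t09,t10,t11,t12,t13);"))
  list(query = query, reference = ref)
}
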
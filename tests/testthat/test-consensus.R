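test_that("split frequencies match the hand count for {T1, T1, T2}", {
  ft <- split_frequencies(sample_t1t1t2())
  freq <- stats::setNames(ft$frequency, ft$split)
  expect_equal(unname(freq["c,d,e"]), 2 / 3)  # ab|cde
  expect_equal(unname(freq["d,e"]), 1)        # de|abc
  expect_equal(unname(freq["b,d,e"]), 1 / 3)  # ac|bde
  expect_identical(attr(ft, "sample_size"), 3L)

  single <- split_frequencies(tree_sample(nwk("((a,b),c,(d,e));")))
  expect_true(all(single$frequency == 1))

  stars <- split_frequencies(tree_sample(list(nwk("(a,b,c,d,e);"))))
  expect_identical(nrow(stars), 0L)
})

test_that("consensus methods reproduce the hand-checked examples", {
  s <- sample_t1t1t2()
  expect_setequal(tree_bipartitions(strict_consensus(s)), "d,e")

  maj <- majority_rule_consensus(s)
  expect_setequal(tree_bipartitions(maj), c("d,e", "c,d,e"))
  sm <- treecord:::split_matrix(maj)
  sup <- stats::setNames(attr(sm, "support"), attr(sm, "keys"))
  expect_equal(unname(sup["d,e"]), 1)
  expect_equal(unname(sup["c,d,e"]), 2 / 3, tolerance = 1e-12)

  greedy <- greedy_consensus(s)  # ac|bde rejected as incompatible with ab|cde
  expect_setequal(tree_bipartitions(greedy), c("d,e", "c,d,e"))

  # identical binary trees: every method returns that tree, supports 1
  t <- nwk("((a,b),c,(d,e));")
  rep_s <- tree_sample(list(t, t, t))
  for (f in list(strict_consensus, majority_rule_consensus, greedy_consensus)) {
    expect_setequal(tree_bipartitions(f(rep_s)), tree_bipartitions(t))
  }
  expect_setequal(tree_bipartitions(strict_consensus(
    tree_sample(list(nwk("((a,b),(c,d),e);"), nwk("((a,c),(b,d),e);"))))),
    character(0))
})

test_that("exact-0.5 incompatible splits are resolved by the deterministic tie-break", {
  s <- tree_sample(list(nwk("((a,b),(c,d),e);"), nwk("((a,c),(b,d),e);")))
  maj <- majority_rule_consensus(s)
  got <- tree_bipartitions(maj)
  # admission order is lexicographic on canonical keys: b,d first, then the
  # compatible b,d,e; the cross-tree conflicts c,d and c,d,e are rejected
  expect_setequal(got, c("b,d", "b,d,e"))
  # determinism and validity regardless of input order
  maj2 <- majority_rule_consensus(
    tree_sample(list(nwk("((a,c),(b,d),e);"), nwk("((a,b),(c,d),e);"))))
  expect_setequal(tree_bipartitions(maj2), got)
})

test_that("strict, majority and greedy split sets are nested", {
  set.seed(405)
  for (rep in 1:30) {
    center <- random_tree(sample(6:12, 1), seed = rep)
    s <- simulate_tree_cloud(center, sample(4:12, 1),
                             dispersion = sample(c(0.5, 1, 3), 1),
                             seed = rep + 1000)
    st <- tree_bipartitions(strict_consensus(s))
    mj <- tree_bipartitions(majority_rule_consensus(s))
    gr <- tree_bipartitions(greedy_consensus(s))
    expect_true(all(st %in% mj))
    expect_true(all(mj %in% gr))
    # outputs are valid trees: splits pairwise compatible by reconstruction
    expect_s3_class(majority_rule_consensus(s), "phylo")
  }
})

test_that("the MCC tree maximizes the frequency-sum score", {
  s <- sample_t1t1t2()
  m <- mcc_tree(s)
  expect_identical(attr(m, "mcc_index"), 1L)  # T1: 5/3 beats T2: 4/3
  expect_equal(attr(m, "mcc_score"), 5 / 3)
  expect_setequal(tree_bipartitions(m), c("c,d,e", "d,e"))

  ident <- tree_sample(list(pair5()$t2, pair5()$t2))
  expect_identical(attr(mcc_tree(ident), "mcc_index"), 1L)

  # brute-force rescan oracle on a random cloud
  center <- random_tree(8, seed = 77)
  cloud <- simulate_tree_cloud(center, 50, dispersion = 2, seed = 78)
  m2 <- mcc_tree(cloud)
  keysets <- lapply(cloud$trees, oracle_split_keys)
  all_keys <- unlist(keysets)
  scores <- vapply(keysets, function(ks) {
    sum(vapply(ks, function(k) sum(all_keys == k), numeric(1))) / 50
  }, numeric(1))
  expect_equal(attr(m2, "mcc_score"), max(scores), tolerance = 1e-12)
  expect_identical(attr(m2, "mcc_index"), which.max(scores))
})

test_that("support annotation maps sample frequencies onto edges", {
  s <- sample_t1t1t2()
  strict <- strict_consensus(tree_sample(list(pair5()$t1, pair5()$t2)))
  ann <- annotate_support(strict, s)
  sup <- stats::setNames(attr(treecord:::split_matrix(ann), "support"),
                         attr(treecord:::split_matrix(ann), "keys"))
  expect_equal(unname(sup["d,e"]), 1)

  t <- nwk("((a,b),c,(d,e));")
  self <- annotate_support(t, tree_sample(list(t, t)))
  expect_true(all(attr(treecord:::split_matrix(self), "support") == 1))

  # an edge absent from every sampled tree gets 0; bootstrap scale is x100
  boot <- tree_sample(list(pair5()$t2, pair5()$t2), source = "bootstrap")
  annb <- annotate_support(t, boot)
  supb <- stats::setNames(attr(treecord:::split_matrix(annb), "support"),
                          attr(treecord:::split_matrix(annb), "keys"))
  expect_equal(unname(supb["c,d,e"]), 0)     # ab|cde never sampled
  expect_equal(unname(supb["d,e"]), 100)
  expect_identical(support_scale(annb), "bootstrap")
})

test_that("collapsing is strict and composes as a max of thresholds", {
  t <- parse_newick("((a,b)0.95,c,(d,e)0.40);")
  expect_setequal(tree_bipartitions(collapse_below(t, 0.5)), "c,d,e")
  # support exactly equal to the threshold is retained
  expect_setequal(tree_bipartitions(collapse_below(t, 0.40)),
                  c("c,d,e", "d,e"))
  expect_setequal(tree_bipartitions(collapse_below(t, 0)),
                  tree_bipartitions(t))
  expect_length(tree_bipartitions(collapse_below(t, 0.96)), 0L)
  expect_error(collapse_below(nwk("((a,b),c,(d,e));"), 0.5),
               "missing supports")

  set.seed(406)
  for (rep in 1:10) {
    center <- random_tree(8, seed = rep + 300)
    cloud <- simulate_tree_cloud(center, 10, dispersion = 1,
                                 seed = rep + 400)
    ann <- annotate_support(center, cloud)
    x1 <- runif(1); x2 <- runif(1)
    composed <- collapse_below(collapse_below(ann, x1), x2)
    direct <- collapse_below(ann, max(x1, x2))
    expect_setequal(tree_bipartitions(composed), tree_bipartitions(direct))
  }
})

test_that("the collapse scan profiles resolution, support and congruence", {
  s <- sample_t1t1t2()
  maj <- annotate_support(majority_rule_consensus(s), s)
  ref <- pair5()$t1
  prof <- collapse_scan(maj, ref, thresholds = c(0, 0.5, 0.7, 0.95))
  expect_s3_class(prof, "data.frame")
  # row at x = 0 equals the uncollapsed statistics
  expect_identical(prof$n_internal_edges[1], 2L)
  expect_equal(prof$P_bip[1],
               proportional_congruence_bipartitions(maj, ref))
  expect_equal(prof$P_quartet[1],
               proportional_congruence_quartets(maj, ref))
  # at x = 0.7 only de|abc (frequency 1) survives: P_bip = 1/1
  row7 <- prof[prof$x == 0.7, ]
  expect_identical(row7$n_internal_edges, 1L)
  expect_equal(row7$P_bip, 1)
  # resolution is non-increasing across the scan
  expect_true(all(diff(prof$n_internal_edges) <= 0))

  # the default grids follow the support scale
  full_prof <- collapse_scan(maj, ref)
  expect_equal(full_prof$x, seq(0, 0.99, by = 0.01))
  boot <- annotate_support(pair5()$t1,
                           tree_sample(list(pair5()$t1), source = "bootstrap"))
  boot_prof <- collapse_scan(boot, ref)
  expect_equal(boot_prof$x, 0:99)

  # a scan that collapses to a star marks the rows excluded
  high <- collapse_scan(maj, ref, thresholds = c(0, 1.01))
  expect_true(high$excluded[2])
  expect_true(is.na(high$P_bip[2]))
})
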
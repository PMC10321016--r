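test_that("random binary trees are binary, deterministic and uniform", {
  t5 <- random_binary_tree(5, seed = 1)
  expect_length(tree_bipartitions(t5), 2L)
  expect_identical(ape::write.tree(random_binary_tree(10, seed = 9)),
                   ape::write.tree(random_binary_tree(10, seed = 9)))
  expect_false(identical(ape::write.tree(random_binary_tree(10, seed = 9)),
                         ape::write.tree(random_binary_tree(10, seed = 10))))
  expect_error(random_binary_tree(3, seed = 1), "at least 4")

  # all 105 unrooted binary topologies on 6 taxa, frequencies consistent
  # with uniformity (chi-square not rejected at alpha = 0.01)
  ids <- vapply(1:2000, function(i) {
    paste(sort(tree_bipartitions(random_binary_tree(6, seed = 20000 + i)),
               method = "radix"), collapse = ";")
  }, character(1))
  counts <- table(ids)
  expect_identical(length(counts), 105L)
  chi <- stats::chisq.test(as.vector(counts),
                           p = rep(1 / 105, 105))
  expect_gt(chi$p.value, 0.01)
})

test_that("NNI perturbation takes minimal steps and demands binary input", {
  tr <- random_binary_tree(8, seed = 3)
  expect_identical(ape::write.tree(nni_perturb(tr, 0, seed = 4)),
                   ape::write.tree(tr))
  for (seed in 1:10) {
    one <- nni_perturb(pair5()$t1, 1, seed = seed)
    expect_identical(rf_distance(pair5()$t1, one), 2L)
  }
  expect_error(nni_perturb(nwk("(a,b,c,d,e);"), 1, seed = 1),
               "fully resolved")

  # expected distance is non-decreasing in the number of moves
  means <- vapply(c(0, 1, 2, 4, 8), function(k) {
    mean(vapply(1:100, function(r) {
      as.numeric(normalized_rf(tr, nni_perturb(tr, k, seed = 1000 * k + r)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("tree clouds concentrate around their centre", {
  center <- random_binary_tree(10, seed = 41)
  frozen <- simulate_tree_cloud(center, 30, dispersion = 0, seed = 42)
  expect_true(all(vapply(frozen$trees, function(t) {
    rf_distance(t, center) == 0L
  }, logical(1))))

  # mean distance to the centre rises along a dispersion ladder
  ladder <- vapply(c(0.5, 2, 8), function(d) {
    cl <- simulate_tree_cloud(center, 100, dispersion = d, seed = 50 + d)
    mean(vapply(cl$trees, function(t) as.numeric(normalized_rf(t, center)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ladder) > 0))

  # a tight cloud's majority-rule consensus recovers the centre's splits
  tight <- simulate_tree_cloud(center, 500, dispersion = 0.5, seed = 60)
  maj <- majority_rule_consensus(tight)
  expect_true(all(tree_bipartitions(maj) %in% tree_bipartitions(center)))
  expect_gte(length(tree_bipartitions(maj)), 5L)
})

test_that("generators are byte-identical under a fixed seed", {
  a <- simulate_tree_cloud(random_binary_tree(8, 7), 20, 1.5, seed = 71)
  b <- simulate_tree_cloud(random_binary_tree(8, 7), 20, 1.5, seed = 71)
  expect_identical(vapply(a$trees, ape::write.tree, character(1)),
                   vapply(b$trees, ape::write.tree, character(1)))

  s1 <- simulate_partition_scenario(8, conflict = 4, dispersion = 1,
                                    n_trees = 10, seed = 72)
  s2 <- simulate_partition_scenario(8, conflict = 4, dispersion = 1,
                                    n_trees = 10, seed = 72)
  expect_identical(ape::write.tree(s1$molecular_truth),
                   ape::write.tree(s2$molecular_truth))
  expect_identical(vapply(s1$clouds$combined$trees, ape::write.tree,
                          character(1)),
                   vapply(s2$clouds$combined$trees, ape::write.tree,
                          character(1)))
  expect_identical(s1$n_morph_chars, s2$n_morph_chars)
})

test_that("partition scenarios encode the requested conflict level", {
  s0 <- simulate_partition_scenario(10, conflict = 0, dispersion = 1,
                                    n_trees = 20, seed = 81)
  expect_identical(rf_distance(s0$molecular_truth, s0$morphological_truth), 0L)
  # conflict 0: the two clouds share a generator, so between-cloud mean
  # distance resembles within-cloud mean distance
  between <- mean(vapply(seq_len(20), function(i) {
    as.numeric(normalized_rf(s0$clouds$molecular$trees[[i]],
                             s0$clouds$morphological$trees[[i]]))
  }, numeric(1)))
  within <- mean(vapply(seq_len(19), function(i) {
    as.numeric(normalized_rf(s0$clouds$molecular$trees[[i]],
                             s0$clouds$molecular$trees[[i + 1]]))
  }, numeric(1)))
  expect_lt(abs(between - within), 0.15)

  s5 <- simulate_partition_scenario(10, conflict = 5, dispersion = 1,
                                    n_trees = 20, seed = 82)
  expect_gt(rf_distance(s5$molecular_truth, s5$morphological_truth), 0L)
  expect_true(s5$p_morph > 0 && s5$p_morph < 1)
  # the combined centre interpolates: no farther from the molecular truth
  # than the morphological truth is
  expect_lte(rf_distance(s5$molecular_truth, s5$combined_center),
             rf_distance(s5$molecular_truth, s5$morphological_truth))
})
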
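balanced4 <- function() read_newick(text = "((A:1,B:1):1,(C:1,D:1):1):0;")

test_that("observed_changes matches hand recursion on small cases", {
  tr <- balanced4()
  expect_equal(observed_changes(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(observed_changes(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_equal(observed_changes(tr, c(A = 0, B = 0, C = 0, D = 0)), 0)
  expect_equal(observed_changes(tr, c(A = 1, B = 1, C = 1, D = 1)), 0)
  expect_error(observed_changes(tr, c(A = 1, B = 0, C = 1)), "missing")
  poly <- read_newick(text = "(A:1,B:1,C:1):0;")
  expect_error(observed_changes(poly, c(A = 1, B = 0, C = 0)), "polytomies")
})

test_that("observed_changes is invariant to state inversion and rotation", {
  set.seed(11)
  for (i in 1:15) {
    tree <- ape::rcoal(10)
    states <- random_states(tree, sample(2:8, 1))
    s <- observed_changes(tree, states)
    expect_equal(observed_changes(tree, 1 - states), s)
    rotated <- ape::rotate(tree, sample((11):(10 + tree$Nnode), 1))
    expect_equal(observed_changes(rotated, states), s)
  }
})

test_that("observed_changes equals the brute-force oracle on random trees", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n)
    states <- random_states(tree, sample(1:(n - 1), 1))
    expect_identical(observed_changes(tree, states),
                     oracle_changes(tree, states))
  }
})

test_that("permutation_null preserves prevalence and is seed-deterministic", {
  tr <- balanced4()
  expect_equal(permutation_null(tr, c(A = 1, B = 1, C = 1, D = 1), 50, seed = 1),
               rep(0, 50))
  sr1 <- permutation_null(tr, c(A = 1, B = 1, C = 0, D = 0), 200, seed = 9)
  sr2 <- permutation_null(tr, c(A = 1, B = 1, C = 0, D = 0), 200, seed = 9)
  expect_identical(sr1, sr2)
  # on the 4-tip balanced tree with k = 2 only change sums 1 and 2 occur
  expect_true(all(sr1 %in% c(1, 2)))
})

test_that("brownian_null reduces to the permutation null on a star tree", {
  # On a star, BM tip values are i.i.d., so the top-k set is uniform and the
  # two nulls draw from the same change-sum distribution.
  star <- resolve_polytomies(
    read_newick(text = paste0("(", paste0("t", 1:8, ":1", collapse = ","), ");")),
    seed = 4)
  states <- c(rep(1, 4), rep(0, 4))
  names(states) <- paste0("t", 1:8)
  sr <- permutation_null(star, states, 1000, seed = 21)
  sb <- brownian_null(star, k = 4, 1000, seed = 22)
  expect_gt(suppressWarnings(stats::wilcox.test(sr, sb)$p.value), 0.01)
})

test_that("brownian_null clumps states on an imbalanced tree", {
  cat16 <- ape::compute.brlen(ape::stree(16, "left"), 1)
  states <- random_states(cat16, 8)
  sr <- permutation_null(cat16, states, 1000, seed = 31)
  sb <- brownian_null(cat16, k = 8, 1000, seed = 32)
  expect_lt(mean(sb), mean(sr))
})

test_that("brownian_null validates its inputs", {
  tr <- balanced4()
  expect_error(brownian_null(tr, k = 0), "0 < k")
  expect_error(brownian_null(tr, k = 4), "0 < k")
  zero <- read_newick(text = "((A:0,B:0):0,(C:0,D:0):0):0;")
  expect_error(brownian_null(zero, k = 2), "zero total depth")
})

test_that("compute_d implements the standardization and both p-values", {
  res <- compute_d(5, sr_values = c(6, 7, 8), sb_values = c(2, 3, 4))
  expect_equal(res$D, 0.5)
  expect_equal(res$p_random, 0)
  expect_equal(res$p_brownian, 0)

  sr <- c(4, 5, 6)
  sb <- c(1, 2, 3)
  expect_equal(compute_d(mean(sr), sr, sb)$D, 1)
  expect_equal(compute_d(mean(sb), sr, sb)$D, 0)

  res2 <- compute_d(2.5, sr_values = 1:4, sb_values = c(0, 1, 2, 3))
  expect_equal(res2$p_random, 2 / 4)    # fraction of s_r <= s_obs
  expect_equal(res2$p_brownian, 1 / 4)  # fraction of s_b >= s_obs
  res3 <- compute_d(2.5, 1:4, c(0, 1, 2, 3), correct = TRUE)
  expect_equal(res3$p_random, 3 / 5)
  expect_equal(res3$p_brownian, 2 / 5)

  expect_error(compute_d(1, c(2, 2), c(2, 2)), "indistinguishable")
  expect_error(compute_d(1, numeric(0), c(1, 2)), "nonempty")
})

test_that("phylo_d flags a perfect clade marker as strongly clumped", {
  tree <- ape::compute.brlen(ape::stree(64, "balanced"), 1)
  half <- ape::extract.clade(tree, 66)$tip.label  # one daughter of the root
  states <- setNames(as.numeric(tree$tip.label %in% half), tree$tip.label)
  res <- phylo_d(tree, states, "clade_marker", seed = 5)
  expect_equal(res$s_obs, 1)
  expect_lt(res$D, 0)
  expect_lt(res$p_random, 0.05)
})

test_that("phylo_d is deterministic and order-independent via trait substreams", {
  tree <- simulate_yule_tree(32, seed = 3)
  states <- simulate_binary_trait(tree, "random", 0.4, seed = 8)
  a <- phylo_d(tree, states, "tr_a", 300, 300, seed = 77)
  b <- phylo_d(tree, states, "tr_a", 300, 300, seed = 77)
  expect_identical(a[c("s_obs", "sr_values", "sb_values", "D")],
                   b[c("s_obs", "sr_values", "sb_values", "D")])
  # a different trait name draws a different substream from the same master
  c_ <- phylo_d(tree, states, "tr_b", 300, 300, seed = 77)
  expect_false(identical(a$sr_values, c_$sr_values))
})

test_that("phylo_d agrees under state inversion within Monte-Carlo error", {
  tree <- simulate_yule_tree(64, seed = 6)
  states <- simulate_binary_trait(tree, "brownian_threshold", 0.3, seed = 13)
  d1 <- phylo_d(tree, states, "x", seed = 19)
  d2 <- phylo_d(tree, 1 - states, "x", seed = 19)
  expect_identical(d1$sr_values, d2$sr_values)  # same seed, same shuffles
  expect_equal(d1$s_obs, d2$s_obs)
  expect_lt(abs(d1$D - d2$D), 0.15)
})

test_that("phylo_d refuses invariant traits and unscored tips", {
  tree <- simulate_yule_tree(8, seed = 1)
  const <- setNames(rep(1, 8), tree$tip.label)
  expect_error(phylo_d(tree, const, "fixed", seed = 1), "no variation")
  part <- setNames(c(1, 0, 1), tree$tip.label[1:3])
  expect_error(phylo_d(tree, part, "partial", seed = 1), "no value for tips")
})
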
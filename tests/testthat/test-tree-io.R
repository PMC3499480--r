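test_that("read_newick parses minimal trees and validates input", {
  tr <- read_newick(text = "(A:1,B:1):0;")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))

  tr3 <- read_newick(text = "((A:1,B:1):1,C:2):0;")
  depths <- ape::node.depth.edgelength(tr3)[1:3]
  expect_equal(depths, c(2, 2, 2))

  expect_error(read_newick(text = "((A:1,B"), "parse error at character")
  expect_error(read_newick(text = "(A:1,B:1));"), "parse error at character")
  expect_error(read_newick(text = "(A:1,A:1);"), "duplicate tip labels")
  # branch lengths defaulted to 1 when absent
  nb <- read_newick(text = "(A,(B,C));")
  expect_true(all(nb$edge.length == 1))
})

test_that("is_ultrametric applies a relative tolerance on tip depths", {
  expect_true(is_ultrametric(read_newick(text = "((A:1,B:1):1,C:2):0;")))
  expect_false(is_ultrametric(read_newick(text = "((A:1,B:1):1,C:5):0;")))
  expect_true(is_ultrametric(
    read_newick(text = "((A:1,B:1.0000001):1,C:2):0;"), rel_tol = 1e-3))
  expect_false(is_ultrametric(
    read_newick(text = "((A:1,B:1.01):1,C:2):0;"), rel_tol = 1e-6))
})

test_that("patristic_matrix sums path lengths and matches the path oracle", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2):0;")
  m <- patristic_matrix(tr)
  expect_equal(m["A", "B"], 2)
  expect_equal(m["A", "C"], 4)
  expect_equal(m["B", "C"], 4)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))

  set.seed(41)
  for (i in 1:20) {
    tree <- ape::rtree(10)
    expect_equal(patristic_matrix(tree),
                 oracle_patristic(tree)[tree$tip.label, tree$tip.label])
  }
})

test_that("patristic distances satisfy the triangle inequality", {
  set.seed(42)
  for (i in 1:10) {
    m <- patristic_matrix(ape::rtree(12))
    n <- nrow(m)
    for (a in 1:n) for (b in 1:n) for (c in 1:n) {
      expect_lte(m[a, b], m[a, c] + m[c, b] + 1e-12)
    }
  }
})

test_that("prune_to_tips preserves patristic distances among kept tips", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2):0;")
  expect_equal(patristic_matrix(prune_to_tips(tr, tr$tip.label)),
               patristic_matrix(tr))
  two <- prune_to_tips(tr, c("A", "C"))
  expect_equal(patristic_matrix(two)["A", "C"], 4)

  set.seed(7)
  for (i in 1:15) {
    tree <- ape::rcoal(12)
    keep <- sample(tree$tip.label, 6)
    sub <- patristic_matrix(prune_to_tips(tree, keep))
    full <- patristic_matrix(tree)[rownames(sub), colnames(sub)]
    expect_equal(sub, full)
  }

  expect_error(prune_to_tips(tr, c("A", "Z")), "unknown tip")
  expect_error(prune_to_tips(tr, "A"), "at least 2")
})

test_that("resolve_polytomies bifurcates deterministically without moving distances", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2):0;")
  expect_identical(resolve_polytomies(tr, seed = 1), tr)

  poly <- read_newick(text = "(A:1,B:1,C:1):0;")
  res <- resolve_polytomies(poly, seed = 5)
  expect_true(ape::is.binary(res))
  expect_equal(res$Nnode, 2)
  expect_equal(sum(res$edge.length == 0), 1)
  m <- patristic_matrix(res)
  expect_true(all(m[upper.tri(m)] == 2))
  expect_equal(ape::write.tree(resolve_polytomies(poly, seed = 5)),
               ape::write.tree(res))

  # larger polytomy: all pairwise distances preserved
  big <- read_newick(text = "((A:1,B:1,C:1,D:1,E:1):1,F:2):0;")
  res2 <- resolve_polytomies(big, seed = 3)
  expect_true(ape::is.binary(res2))
  expect_equal(patristic_matrix(res2)[big$tip.label, big$tip.label],
               patristic_matrix(big))
})

test_that("genus_clades splits tips into maximal pure clades", {
  gmap <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  tr <- read_newick(text = "((A1:1,A2:1):1,(B1:1,B2:1):1):0;")
  cl <- genus_clades(tr, gmap)
  expect_setequal(names(cl), c("A", "B"))
  expect_setequal(cl$A, c("A1", "A2"))
  expect_setequal(cl$B, c("B1", "B2"))

  inter <- read_newick(text = "((A1:1,B1:1):1,(A2:1,B2:1):1):0;")
  cl2 <- genus_clades(inter, gmap)
  expect_setequal(names(cl2), c("A-1", "A-2", "B-1", "B-2"))
  expect_true(all(lengths(cl2) == 1))
  # no same-genus pair has a pure MRCA here, hence four singleton clades
  expect_false(is.null(ape::getMRCA(inter, c("A1", "A2"))))

  one <- read_newick(text = "((A1:1,A2:1):1,A3:2):0;")
  cl3 <- genus_clades(one, c(A1 = "A", A2 = "A", A3 = "A"))
  expect_equal(names(cl3), "A")
  expect_setequal(cl3$A, one$tip.label)

  expect_error(genus_clades(tr, c(A1 = "A")), "missing from genus map")
})

test_that("genus_clades partitions the tip set exactly once", {
  for (seed in 1:8) {
    tree <- simulate_yule_tree(40, seed = seed, polyphyly_fraction = 0.3)
    cl <- genus_clades(tree, genus_map_from_labels(tree$tip.label))
    expect_setequal(unlist(cl, use.names = FALSE), tree$tip.label)
    expect_equal(sum(lengths(cl)), ape::Ntip(tree))
    # every clade is pure and its MRCA subtends only its own tips
    gmap <- genus_map_from_labels(tree$tip.label)
    for (i in seq_along(cl)) {
      expect_length(unique(gmap[cl[[i]]]), 1)
      if (length(cl[[i]]) > 1) {
        node <- ape::getMRCA(tree, cl[[i]])
        expect_setequal(ape::extract.clade(tree, node)$tip.label, cl[[i]])
      }
    }
  }
})

test_that("genus maps come from labels or CSV", {
  gm <- genus_map_from_labels(c("Narcissus_poeticus", "Galanthus_nivalis", "solo"))
  expect_equal(unname(gm), c("Narcissus", "Galanthus", "solo"))
  f <- write_temp_csv(c("tip,genus", "x1,A", "x2,B"))
  gm2 <- read_genus_map(f)
  expect_equal(gm2, c(x1 = "A", x2 = "B"))
})
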
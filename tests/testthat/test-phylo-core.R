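test_that("newick parsing recovers toy topologies and path lengths", {
  tr2 <- read_phylogeny(text = "(A:1,B:2);")
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(patristic_matrix(tr2)["A", "B"], 3)

  tr <- tree3()
  expect_equal(ape::Ntip(tr), 3)
  root <- ape::Ntip(tr) + 1L
  expect_length(tr$edge[tr$edge[, 1] == root, 2], 2)  # two root children
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(2, 3))  # balanced: equal root-to-tip depths

  st <- star3()
  expect_equal(st$Nnode, 1L)  # polytomy preserved, not resolved
})

test_that("parse errors are raised with position information", {
  expect_error(read_phylogeny(text = "((A:1,B:2);"), "unbalanced")
  expect_error(read_phylogeny(text = "(A:1,B:2));"), "position")
  expect_error(read_phylogeny(text = "(A:1,B:2)"), ";")
  expect_error(read_phylogeny(text = "  "), "empty")
  expect_error(read_phylogeny(text = "(A:1,A:2);"), "duplicate")
  expect_error(read_phylogeny(text = "(onlytip:1);"), "2 tips")
})

test_that("missing branch lengths error unless the unit-length fallback is on", {
  expect_error(read_phylogeny(text = "(A,B);"), "unit_lengths")
  tr <- read_phylogeny(text = "((A,B),C);", unit_lengths = TRUE)
  expect_equal(patristic_matrix(tr)["A", "B"], 2)
  expect_warning(read_phylogeny(text = "((A:0,B:0):1,C:1);"), "zero-length")
})

test_that("write/parse round-trips preserve topology, labels and lengths", {
  for (seed in 1:4) {
    tr <- simulate_yule_tree(10, seed = seed)
    s <- write_newick(tr)
    tr2 <- read_phylogeny(text = s)
    expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE,
                                     tolerance = 1e-8))
    expect_identical(write_newick(tr2), s)
  }
  # node labels with metacharacters are quoted, not rejected
  tr <- tree3()
  out <- write_newick(tr, node_labels = c("5" = "MORE:Skin|Pain"))
  expect_match(out, "'MORE:Skin|Pain'", fixed = TRUE)
  expect_silent(read_phylogeny(text = out))
})

test_that("patristic distances match hand sums and a naive path oracle", {
  d <- patristic_matrix(tree3())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(isSymmetric(d))

  ds <- patristic_matrix(star3())
  expect_equal(unname(ds[upper.tri(ds)]), rep(2, 3))

  for (seed in 1:5) {
    tr <- simulate_yule_tree(10, seed = 100 + seed)
    d <- patristic_matrix(tr)
    expect_equal(d, naive_patristic(tr), tolerance = 1e-10)
    # tree metric: triangle inequality for every triple
    for (i in 1:8) for (j in (i + 1):9) for (k in (j + 1):10)
      expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-12)
    # ultrametric input: equal root-to-tip depths
    depths <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
    expect_lt(diff(range(depths)) / max(depths), 1e-9)
  }
})

test_that("MRCA and descendant queries behave on rooted trees", {
  tr <- tree3()
  ab <- mrca_node(tr, c("A", "B"))
  expect_identical(sort(descendant_tips(tr, ab)), c("A", "B"))
  expect_identical(mrca_node(tr, c("A", "C")), ape::Ntip(tr) + 1L)  # root
  expect_identical(mrca_node(tr, tr$tip.label), ape::Ntip(tr) + 1L)
  expect_identical(descendant_tips(tr, ape::Ntip(tr) + 1L), tr$tip.label)
  expect_identical(descendant_tips(tr, 1L), "A")
  expect_error(mrca_node(tr, c("A", "Zz")), "Zz")
  # whitespace-normalized matching
  expect_identical(mrca_node(tr, c(" A ", "B")), ab)
})

test_that("node report labels follow the MRCA(first,last) convention", {
  tr <- tree3()
  ab <- mrca_node(tr, c("A", "B"))
  expect_identical(node_report_label(tr, ab), "MRCA(A,B)")
  expect_identical(node_report_label(tr, ape::Ntip(tr) + 1L), "MRCA(A,C)")
  expect_identical(node_report_label(tr, ab), node_report_label(tr, ab))
  expect_error(node_report_label(tr, 1L), "tip")
})
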
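test_that("closed-form topology frequencies", {
  expect_equal(unname(expected_topology_freqs(0)), rep(1 / 3, 3))
  e <- expected_topology_freqs(log(2))
  expect_equal(unname(e), c(2 / 3, 1 / 6, 1 / 6))
  big <- expected_topology_freqs(50)
  expect_equal(big[["q1"]], 1, tolerance = 1e-12)
  expect_error(expected_topology_freqs(-0.1), "negative")
})

test_that("two-taxon trees coalesce into the only possible topology", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  gts <- simulate_gene_trees(tr, 50, seed = 1)
  expect_equal(gts$n, 50)
  for (m in gts$merges) {
    expect_equal(nrow(m), 1)
    expect_setequal(m[1, 1:2], c(1, 2))
  }
})

test_that("a zero-length focal branch gives three equal resolutions", {
  tr <- caterpillar5(0)
  gts <- simulate_gene_trees(tr, 20000, seed = 2)
  tf <- topology_freqs(gts, tr, c("A", "B"))
  expect_true(all(abs(tf$freqs - 1 / 3) < 0.01))
})

test_that("a long focal branch is almost never discordant", {
  tr <- caterpillar5(10)
  gts <- simulate_gene_trees(tr, 5000, seed = 3)
  tf <- topology_freqs(gts, tr, c("A", "B"))
  expect_gte(tf$freqs[["q1"]], 0.999)
})

test_that("hand-built gene trees are classified by direct count", {
  tr <- caterpillar5(1)
  lab <- tr$tip.label
  mk <- function(...) {
    prs <- list(...)
    m <- matrix(0, length(prs), 3)
    for (k in seq_along(prs)) {
      m[k, ] <- c(match(prs[[k]][1], lab), match(prs[[k]][2], lab), k)
    }
    m
  }
  # ((A,B),(C,(D,E))): species-tree arrangement around the (A,B) branch
  t_q1 <- mk(c("A", "B"), c("D", "E"), c("C", "D"), c("A", "C"))
  # ((B,(A,C)),(D,E)): A groups with C (the sibling side)
  t_q2 <- mk(c("A", "C"), c("A", "B"), c("D", "E"), c("A", "D"))
  # ((A,(D,E)),(B,C)): A groups with the distal D/E side
  t_q3 <- mk(c("D", "E"), c("A", "D"), c("B", "C"), c("A", "B"))
  gts <- structure(list(tip_labels = lab, n = 6,
                        merges = list(t_q1, t_q1, t_q1, t_q2, t_q2, t_q3)),
                   class = "gene_tree_set")
  tf <- topology_freqs(gts, tr, c("A", "B"))
  expect_equal(unname(tf$freqs),
               c(0.5, 2 / 6, 1 / 6), tolerance = 1e-9)
})

test_that("simulated frequencies match the coalescent expectation", {
  tr <- caterpillar5(0.5)
  gts <- simulate_gene_trees(tr, 20000, seed = 4)
  tf <- topology_freqs(gts, tr, c("A", "B"))
  want <- expected_topology_freqs(0.5)
  expect_true(all(abs(tf$freqs - want) < 0.01))
  # counts are exact proportions
  expect_equal(sum(tf$freqs), 1, tolerance = 1e-12)
  expect_equal(sum(tf$counts), tf$n_quartets)
  # the two alternates are symmetric
  expect_lte(abs(tf$freqs[["q2"]] - tf$freqs[["q3"]]), 0.015)
})

test_that("gene-tree simulation is deterministic per seed", {
  tr <- angiosperm14_tree(ana_branch = 0.3)
  g1 <- simulate_gene_trees(tr, 200, seed = 11)
  g2 <- simulate_gene_trees(tr, 200, seed = 11)
  g3 <- simulate_gene_trees(tr, 200, seed = 12)
  expect_identical(g1$merges, g2$merges)
  expect_false(identical(g1$merges, g3$merges))
})

test_that("nonbinary species trees are rejected", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_error(simulate_gene_trees(tr, 10), "binary")
})

test_that("newick output round-trips through ape", {
  tr <- caterpillar5(0.7)
  gts <- simulate_gene_trees(tr, 20, seed = 5)
  nwk <- gene_trees_newick(gts)
  expect_length(nwk, 20)
  trees <- ape::read.tree(text = nwk)
  for (t in trees) {
    expect_setequal(t$tip.label, tr$tip.label)
    expect_true(ape::is.binary(t))
  }
})

test_that("Spearman concordance handles the textbook cases", {
  expect_equal(concordance(1:5 / 10, 1:5 / 10)$rho, 1)
  expect_equal(concordance(1:5 / 10, 5:1 / 10)$rho, -1)
  expect_equal(concordance(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  expect_error(concordance(1:3, 1:4), "mismatch")
  expect_error(concordance(1:2, 1:2), "at least 3")
})

test_that("focal-branch group identification", {
  tr <- angiosperm14_tree()
  cl <- angiosperm14_clades()
  gr <- wgdils:::branch_groups(tr, cl$ana)
  expect_setequal(gr$B, "Euryale")
  expect_setequal(gr$C, "Amborella")
  expect_setequal(gr$D, "Ginkgo")
  expect_length(gr$A, 11)
  gr2 <- wgdils:::branch_groups(tr, cl$cerato)
  expect_setequal(gr2$B, "Ceratophyllum")
  expect_setequal(gr2$C, c("Cinnamomum", "Persea", "Liriodendron"))
  expect_error(wgdils:::branch_groups(tr, c("Ginkgo", "Amborella")),
               "node")
})
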
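test_that("a clean diagonal chains into one block, below-threshold ones vanish", {
  ga <- toy_genome("A", c(c1 = 50))
  gb <- toy_genome("B", c(c1 = 50))
  a12 <- diagonal_anchors(ga, gb, "c1", "c1", 0, 0, 12)
  blocks <- chain_anchors(a12, ga, gb)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 12)
  expect_equal(blocks[[1]]$orientation, "+")

  a9 <- diagonal_anchors(ga, gb, "c1", "c1", 0, 0, 9)
  expect_length(chain_anchors(a9, ga, gb), 0)
})

test_that("a rank gap beyond max_gap splits chains", {
  ga <- toy_genome("A", c(c1 = 1200))
  gb <- toy_genome("B", c(c1 = 1200))
  anchors <- rbind(diagonal_anchors(ga, gb, "c1", "c1", 0, 0, 15),
                   diagonal_anchors(ga, gb, "c1", "c1", 515, 515, 15))
  blocks <- chain_anchors(anchors, ga, gb, chain_params(max_gap = 25))
  expect_length(blocks, 2)
  expect_equal(sort(vapply(blocks, function(b) nrow(b$anchors),
                           integer(1))), c(15L, 15L))
})

test_that("antiparallel (inverted) runs are chained when allowed", {
  ga <- toy_genome("A", c(c1 = 40))
  gb <- toy_genome("B", c(c1 = 40))
  inv <- data.frame(gene_a = sprintf("A_c1_%d", 0:11),
                    gene_b = sprintf("B_c1_%d", 30 - (0:11)),
                    score = 1)
  blocks <- chain_anchors(inv, ga, gb)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$orientation, "-")
  expect_length(chain_anchors(inv, ga, gb,
                              chain_params(allow_inversions = FALSE)), 0)
})

test_that("unknown anchor genes raise a named error", {
  ga <- toy_genome("A", c(c1 = 10))
  gb <- toy_genome("B", c(c1 = 10))
  bad <- data.frame(gene_a = "A_c1_3", gene_b = "B_c9_99", score = 1)
  expect_error(chain_anchors(bad, ga, gb, chain_params(min_block = 2)),
               "B_c9_99")
})

test_that("chaining equals exhaustive search on small anchor sets", {
  ga <- toy_genome("A", c(c1 = 60))
  gb <- toy_genome("B", c(c1 = 60))
  params <- chain_params(min_block = 2, max_gap = 10)
  for (sd in 1:12) {
    set.seed(sd)
    n <- sample(8:15, 1)
    ra <- sample(0:40, n)
    rb <- sample(0:40, n)
    anchors <- data.frame(gene_a = sprintf("A_c1_%d", ra),
                          gene_b = sprintf("B_c1_%d", rb), score = 1)
    blocks <- chain_anchors(anchors, ga, gb, params)
    want <- oracle_best_chain(ra, rb, params$max_gap, params$gap_penalty)
    if (length(blocks) == 0) {
      expect_lt(want$score, 2)  # no chain of >= 2 anchors scores higher
    } else {
      scores <- vapply(blocks, `[[`, numeric(1), "score")
      expect_equal(max(scores), want$score, tolerance = 1e-9)
      best <- blocks[[which.max(scores)]]
      expect_equal(nrow(best$anchors), length(want$idx))
    }
  }
})

test_that("stricter min_block yields a subset of blocks", {
  ga <- toy_genome("A", c(c1 = 400))
  gb <- toy_genome("B", c(c1 = 400))
  anchors <- rbind(diagonal_anchors(ga, gb, "c1", "c1", 0, 0, 12),
                   diagonal_anchors(ga, gb, "c1", "c1", 100, 100, 25),
                   diagonal_anchors(ga, gb, "c1", "c1", 200, 200, 15))
  loose <- chain_anchors(anchors, ga, gb, chain_params(min_block = 10))
  strict <- chain_anchors(anchors, ga, gb, chain_params(min_block = 14))
  keyset <- function(bl) vapply(bl, function(b)
    paste(b$anchors$gene_a, collapse = ","), character(1))
  expect_true(all(keyset(strict) %in% keyset(loose)))
  expect_lt(length(strict), length(loose))
})

test_that("planted blocks are recalled on noise-free fixtures", {
  ga <- toy_genome("A", c(c1 = 500, c2 = 500))
  gb <- toy_genome("B", c(c1 = 500, c2 = 500))
  planted <- list()
  anchors <- NULL
  for (i in 0:9) {
    for (chs in list(c("c1", "c1"), c("c2", "c2"))) {
      d <- diagonal_anchors(ga, gb, chs[1], chs[2], i * 50, i * 50, 16)
      planted[[length(planted) + 1L]] <- d
      anchors <- rbind(anchors, d)
    }
  }
  blocks <- chain_anchors(anchors, ga, gb)
  found <- vapply(blocks, function(b)
    paste(sort(b$anchors$gene_a), collapse = ","), character(1))
  hits <- vapply(planted, function(d)
    paste(sort(d$gene_a), collapse = ",") %in% found, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("syntenic depth ratios reflect ploidy history", {
  # identical genomes, no WGD: 1:1
  ga <- toy_genome("A", c(c1 = 100))
  gb <- toy_genome("B", c(c1 = 100))
  blocks <- chain_anchors(diagonal_anchors(ga, gb, "c1", "c1", 0, 0, 100),
                          ga, gb)
  d <- syntenic_depth(blocks, "B")
  expect_equal(unname(d$ratio), c(1, 1))

  # A duplicated once relative to B: 2:1
  ga2 <- toy_genome("A", c(c1 = 100, c1d = 100))
  an <- rbind(diagonal_anchors(ga2, gb, "c1", "c1", 0, 0, 100),
              diagonal_anchors(ga2, gb, "c1d", "c1", 0, 0, 100))
  b2 <- chain_anchors(an, ga2, gb)
  d2 <- syntenic_depth(b2, "B")
  expect_equal(unname(d2$ratio), c(2, 1))
  expect_equal(names(d2$ratio), c("A", "B"))

  # two rounds in A: 4:1
  ga4 <- toy_genome("A", c(c1 = 100, c2 = 100, c3 = 100, c4 = 100))
  an4 <- do.call(rbind, lapply(c("c1", "c2", "c3", "c4"), function(ch)
    diagonal_anchors(ga4, gb, ch, "c1", 0, 0, 100)))
  b4 <- chain_anchors(an4, ga4, gb)
  expect_equal(unname(syntenic_depth(b4, "B")$ratio), c(4, 1))

  expect_error(syntenic_depth(structure(list(),
                                        class = "syntenic_blocks"), "B"),
               "empty")
})

test_that("within-genome comparisons drop self-pairs and dedupe", {
  ga <- toy_genome("A", c(c1 = 60, c2 = 60))
  fwd <- data.frame(gene_a = sprintf("A_c1_%d", 0:14),
                    gene_b = sprintf("A_c2_%d", 0:14), score = 1)
  rev <- data.frame(gene_a = fwd$gene_b, gene_b = fwd$gene_a, score = 1)
  selfp <- data.frame(gene_a = "A_c1_0", gene_b = "A_c1_0", score = 1)
  blocks <- chain_anchors(rbind(fwd, rev, selfp), ga, ga)
  expect_length(blocks, 1)
  expect_equal(nrow(blocks[[1]]$anchors), 15)
})
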
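test_that("full retention duplicates every gene exactly once", {
  sc <- evolution_scenario(
    list(event_speciation(60, "anc", c("A", "B")),
         event_wgd(30, "A", ploidy = 2, retention = 1)),
    chromosomes = 2, genes_per_chromosome = 30, cds_codons = 30,
    seed = 5)
  sim <- simulate_history(sc)
  wgd <- sim$truth[sim$truth$event_type == "wgd", ]
  expect_equal(nrow(wgd), 60)  # one duplicate per pre-WGD gene
  expect_equal(length(sim$genomes$A$cds), 120)
  expect_equal(length(sim$genomes$B$cds), 60)
  # every planted pair appears exactly once
  key <- apply(sim$truth[, c("gene_a", "gene_b")], 1,
               function(r) paste(sort(r), collapse = "|"))
  expect_false(any(duplicated(key)))
})

test_that("zero elapsed time after a WGD leaves duplicates identical", {
  # most recent event essentially at the present
  sc <- evolution_scenario(
    list(event_speciation(50, "anc", c("A", "B")),
         event_wgd(1e-9, "A", ploidy = 2, retention = 1)),
    chromosomes = 1, genes_per_chromosome = 20, cds_codons = 40,
    seed = 6)
  sim <- simulate_history(sc)
  wgd <- sim$truth[sim$truth$event_type == "wgd", ]
  for (i in seq_len(nrow(wgd))) {
    a <- sim$genomes$A$cds[[wgd$gene_a[i]]]
    b <- sim$genomes$A$cds[[wgd$gene_b[i]]]
    expect_identical(a, b)
    expect_equal(ks_pair(a, b)$ks, 0)
  }
})

test_that("planted WGD Ks is recovered by the NG86 estimator", {
  sim <- wgd_recovery_fixture()
  wgd <- sim$truth[sim$truth$event_type == "wgd", ]
  expect_gte(nrow(wgd), 300)
  expect_equal(unique(wgd$expected_ks), 0.5, tolerance = 1e-9)
  cds <- sim$genomes$A$cds
  ks <- mapply(function(a, b) ks_pair(cds[[a]], cds[[b]])$ks,
               wgd$gene_a, wgd$gene_b)
  expect_lt(abs(mean(ks) - 0.5), 0.05)
})

test_that("gene retention follows the stated loss probability", {
  p <- 0.6
  n0 <- 500
  sc <- evolution_scenario(
    list(event_speciation(40, "anc", c("A", "B")),
         event_wgd(20, "A", ploidy = 2, retention = p)),
    chromosomes = 2, genes_per_chromosome = n0 / 2, cds_codons = 9,
    seed = 7)
  sim <- simulate_history(sc)
  extra <- length(sim$genomes$A$cds) - n0
  expect_lt(abs(extra - p * n0), 3 * sqrt(n0 * p * (1 - p)))
})

test_that("genome invariants: consecutive ranks, unique ids, CDS for all", {
  sim <- rate_fixture()$sim
  for (g in sim$genomes) {
    ids <- unlist(lapply(g$loci, function(d) d$gene), use.names = FALSE)
    expect_false(any(duplicated(ids)))
    expect_setequal(ids, names(g$cds))
    for (d in g$loci) expect_equal(sort(d$rank), seq_len(nrow(d)) - 1L)
    expect_true(all(nchar(g$cds) %% 3 == 0))
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  sc <- evolution_scenario(
    list(event_speciation(30, "anc", c("A", "B")),
         event_wgd(10, "B", ploidy = 3, retention = 0.5)),
    chromosomes = 1, genes_per_chromosome = 25, cds_codons = 20,
    seed = 99)
  expect_identical(simulate_history(sc), simulate_history(sc))
})

test_that("invalid schedules are rejected", {
  expect_error(evolution_scenario(
    list(event_speciation(10, "anc", c("A", "B")),
         event_wgd(20, "A"))), "strictly decreasing")
  sc <- evolution_scenario(
    list(event_speciation(30, "anc", c("A", "B")),
         event_wgd(10, "nosuch")),
    chromosomes = 1, genes_per_chromosome = 5, cds_codons = 10)
  expect_error(simulate_history(sc), "unknown or extinct")
})

test_that("anchor emission adds the requested noise and nothing else", {
  sim <- wgd_recovery_fixture()
  a0 <- emit_anchor_pairs(sim$truth, 0)
  expect_equal(nrow(a0), nrow(sim$truth))
  expect_setequal(paste(a0$gene_a, a0$gene_b),
                  paste(sim$truth$gene_a, sim$truth$gene_b))
  a2 <- emit_anchor_pairs(sim$truth, 0.2, seed = 8)
  expect_equal(nrow(a2), round(1.2 * nrow(sim$truth)))
  expect_identical(emit_anchor_pairs(sim$truth, 0.2, seed = 8), a2)
})

test_that("uniform spurious anchors never chain into reportable blocks", {
  ga <- toy_genome("A", c(c1 = 1000))
  gb <- toy_genome("B", c(c1 = 1000))
  for (sd in 1:20) {
    set.seed(sd)
    anchors <- data.frame(
      gene_a = sprintf("A_c1_%d", sample(0:999, 100, replace = TRUE)),
      gene_b = sprintf("B_c1_%d", sample(0:999, 100, replace = TRUE)),
      score = 1)
    blocks <- chain_anchors(anchors, ga, gb, chain_params(min_block = 10))
    expect_length(blocks, 0)
  }
})
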
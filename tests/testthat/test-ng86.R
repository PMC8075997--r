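test_that("site and difference counting matches hand enumeration", {
  id <- ng86_counts("TTTGGG", "TTTGGG")
  expect_equal(id$Sd, 0)
  expect_equal(id$Nd, 0)
  expect_equal(id$S + id$N, 3 * id$codons_used)

  one <- ng86_counts("TTTGGG", "TTCGGG")
  expect_equal(one$S, 4 / 3)
  expect_equal(one$N, 14 / 3)
  expect_equal(one$Sd, 1)
  expect_equal(one$Nd, 0)
})

test_that("counting is symmetric and rejects bad input", {
  set.seed(11)
  cods <- sense_codons()
  for (i in 1:20) {
    a <- paste(sample(cods, 10, replace = TRUE), collapse = "")
    b <- paste(sample(cods, 10, replace = TRUE), collapse = "")
    ab <- ng86_counts(a, b)
    ba <- ng86_counts(b, a)
    expect_equal(ab$Sd, ba$Sd)
    expect_equal(ab$Nd, ba$Nd)
    expect_equal(ab$S, ba$S)
  }
  expect_error(ng86_counts("ATG", "ATGATG"), "length")
  expect_error(ng86_counts("TAA", "TAA"), "usable")
})

test_that("gap and ambiguous codons are skipped", {
  cnt <- ng86_counts("ATG---GGG", "ATGAAANGG")
  expect_equal(cnt$codons_used, 1L)  # only ATG/ATG
  full <- ng86_counts("ATGGGG", "ATGGGA")
  expect_equal(full$codons_used, 2L)
  expect_equal(full$Sd, 1)
})

test_that("random codon pairs agree exactly with the pathway oracle", {
  set.seed(42)
  cods <- sense_codons()
  for (i in 1:500) {
    c1 <- sample(cods, 1)
    c2 <- sample(cods, 1)
    got <- ng86_counts(c1, c2)
    want <- oracle_ng86_codon(c1, c2)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, unname(want$Sd), tolerance = 1e-12)
    expect_equal(got$Nd, unname(want$Nd), tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction and saturation flagging", {
  expect_equal(ks_jc(list(S = 2, Sd = 0))$ks, 0)
  k <- ks_jc(list(S = 2, Sd = 1))  # p_s = 0.5
  expect_equal(k$ks, 0.8240, tolerance = 1e-4)
  expect_false(k$saturated)
  expect_true(ks_jc(list(S = 4, Sd = 3))$saturated)  # p_s = 3/4
  expect_true(ks_jc(list(S = 4, Sd = 2.95))$saturated)  # finite ks > 3
  expect_error(ks_jc(list(S = 0, Sd = 0)), "S = 0")
})

test_that("block median uses unsaturated values only", {
  blk <- structure(list(anchors = NULL), class = "syntenic_block")
  expect_equal(block_median_ks(blk, c(0.1, 0.2, 0.3))$median_ks, 0.2)
  expect_equal(block_median_ks(blk, c(0.1, 0.3))$median_ks, 0.2)
  b <- block_median_ks(blk, c(0.1, 0.3, NA))
  expect_equal(b$median_ks, 0.2)
  expect_equal(b$n_saturated, 1)
  expect_true(is.na(block_median_ks(blk, c(NA, NA))$median_ks))
})

test_that("measured Ks increases with the mutation target", {
  set.seed(7)
  s <- wgdils:::random_cds(3000)
  targets <- c(0.05, 0.2, 0.5, 1, 2)
  ks <- vapply(seq_along(targets), function(i)
    ks_pair(s, mutate_cds(s, targets[i], seed = i))$ks, numeric(1))
  expect_true(all(diff(ks) > 0))
})
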
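# Shared fixtures, built in code. The heavier simulated fixtures are
# cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

# A positions-only genome for synteny tests: chrom_sizes is a named
# integer vector, gene ids are <species>_<chrom>_<rank>.
toy_genome <- function(species, chrom_sizes) {
  rows <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]]
    data.frame(gene = sprintf("%s_%s_%d", species, ch, seq_len(n) - 1L),
               chrom = ch, rank = seq_len(n) - 1L, strand = "+",
               stringsAsFactors = FALSE)
  }))
  cds <- stats::setNames(rep("ATG", nrow(rows)), rows$gene)
  structure(list(species = species,
                 loci = split(rows[, c("gene", "rank", "strand")],
                              rows$chrom),
                 cds = cds),
            class = "annotated_genome")
}

# anchors forming a diagonal between two toy genomes
diagonal_anchors <- function(ga, gb, chrom_a, chrom_b, start_a, start_b,
                             n, step = 1) {
  data.frame(
    gene_a = sprintf("%s_%s_%d", ga$species, chrom_a,
                     start_a + step * (seq_len(n) - 1L)),
    gene_b = sprintf("%s_%s_%d", gb$species, chrom_b,
                     start_b + step * (seq_len(n) - 1L)),
    score = 1, stringsAsFactors = FALSE)
}

# Equal-rate three-genome fixture: simultaneous basal split of the slow
# anchor (At), second anchor (Ef) and baseline (Vv), all at rate 1, plus
# one WGD in the baseline lineage. Used for the identity property of the
# rate correction (lambda == 1, corrected == raw).
equal_rate_fixture <- function() {
  cached("equal_rate", {
    sc <- evolution_scenario(
      list(event_speciation(100, "anc", c("At", "Ef", "Vv")),
           event_wgd(50, "Vv", ploidy = 2, retention = 1)),
      chromosomes = 5, genes_per_chromosome = 50, cds_codons = 150,
      ks_per_myr = 0.003, seed = 101)
    sim <- simulate_history(sc)
    anchors <- emit_anchor_pairs(sim$truth)
    list(scenario = sc, sim = sim, anchors = anchors)
  })
}

# Unequal-rate fixture: basal star split of At, Ef, Vv (rate 1) and X
# (rate 2) 150 Ma; the baseline lineage Vv carries the reference WGD at
# 122.5 Ma (the midpoint of the 115-130 Ma calibration window) and a
# second, younger WGD at 40 Ma used as the dated test event.
rate_fixture <- function() {
  cached("rate_fixture", {
    sc <- evolution_scenario(
      list(event_speciation(150, "anc", c("At", "Ef", "Vv", "X"),
                            rates = c(1, 1, 1, 2)),
           event_wgd(122.5, "Vv", ploidy = 2, retention = 1),
           event_wgd(40, "Vv", ploidy = 2, retention = 1)),
      chromosomes = 6, genes_per_chromosome = 50, cds_codons = 150,
      ks_per_myr = 0.003, seed = 202)
    sim <- simulate_history(sc)
    anchors <- emit_anchor_pairs(sim$truth)
    fits <- wgd_ks_fits(sim$genomes, anchors)
    list(scenario = sc, sim = sim, anchors = anchors, fits = fits)
  })
}

# WGD-recovery fixture: one planted WGD with expected paralog Ks 0.5
# over >= 300 retained pairs.
wgd_recovery_fixture <- function() {
  cached("wgd_recovery", {
    sc <- evolution_scenario(
      list(event_speciation(120, "anc", c("A", "B")),
           event_wgd(250 / 3, "A", ploidy = 2, retention = 1)),
      chromosomes = 2, genes_per_chromosome = 160, cds_codons = 300,
      ks_per_myr = 0.003, seed = 303)
    simulate_history(sc)
  })
}

# five-taxon caterpillar with a focal internal branch of length t above
# the (A,B) cherry; every other internal branch long enough to suppress
# ILS elsewhere
caterpillar5 <- function(t, other = 5) {
  ape::read.tree(text = sprintf(
    "((((A:1,B:1):%.10g,C:1):%g,D:1):%g,E:1);", t, other, other))
}
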
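Package: wgdils
Title: Ks-Based Polyploidy Dating and Multispecies-Coalescent Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and dating whole-genome duplications from
    synonymous-substitution (Ks) distributions, and for testing whether
    gene-tree discordance is consistent with incomplete lineage sorting
    under the multispecies coalescent. Includes a synthetic genome-evolution
    simulator (planted speciations, rate multipliers and polyploidy events),
    collinear-block detection by gap-constrained anchor chaining, Nei-Gojobori
    Ks estimation with Jukes-Cantor correction, kernel-density peak fitting by
    Gaussian mixtures, evolutionary-rate correction of Ks peaks anchored on a
    slowly evolving reference lineage, calibration-based event dating, and
    coalescent gene-tree simulation with per-branch topology (quartet)
    frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
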
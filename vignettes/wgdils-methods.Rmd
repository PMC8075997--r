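---
title: "Methods: Ks-based polyploidy dating and coalescent concordance"
author: "wgdils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ks-based polyploidy dating and coalescent concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `wgdils`, the
parameters that matter, the numerical decisions taken where the
procedures left latitude, and what the synthetic fixtures can and
cannot demonstrate.

## 1. Synonymous divergence (Ks)

Per anchor pair, synonymous and nonsynonymous sites and differences are
counted with the Nei–Gojobori method: each codon position contributes
the fraction of its three possible changes that are synonymous (changes
to stop codons count as nonsynonymous), site counts are averaged over
the two sequences, and codons differing at several positions are
averaged over all substitution orderings, excluding pathways through
stop codons and renormalizing over the remainder. Codons containing
gaps, ambiguous bases, or stops in either sequence are skipped. The
proportion of synonymous differences per synonymous site is then
Jukes–Cantor corrected, `ks = -(3/4) log(1 - (4/3) p_s)`.

**Saturation policy.** `p_s >= 3/4` makes the correction undefined;
such values, and finite Ks above 3.0, are flagged saturated and
excluded from block medians (with a count kept) rather than clipped.
Median-of-block summaries make this robust; a block whose anchors are
all saturated is dropped with a message. The 3.0 cap is standard
practice for Ks-age plots; whether any range filter was applied before
peak fitting in comparable published workflows is usually unstated, so
the cap is an explicit, configurable decision here.

## 2. Syntenic block detection

Anchors are chained in gene-rank space (0-based ranks per chromosome,
not base pairs) with a DAGchainer-style sparse dynamic program: each
anchor scores 1, gaps are penalized at 0.01 per skipped rank, and
consecutive anchors may be at most `max_gap = 25` ranks apart on either
genome. Chains must be strictly monotonic (antiparallel chains model
inversions and are allowed by default). Highest-scoring chains are
extracted greedily without anchor reuse — ties broken by longer chain,
then lexicographic chromosome order — and chains below
`min_block = 10` anchors are discarded at the end (so a stricter
threshold always yields a subset). The dynamic program is verified
against exhaustive enumeration on small inputs in the test suite.

Syntenic depth tiles a target genome in windows of 20 gene ranks and
reports the modal nonzero number of covering blocks in each direction,
e.g. 2:1 after one unshared WGD.

## 3. Peak fitting

Block-median Ks values are smoothed with a Gaussian kernel
(`bandwidth = 0.025` Ks units — the kernel standard deviation — on a
512-point even grid spanning `[0, max + 4*bandwidth]`). A sum of
Gaussians is then fit to the smoothed curve by Levenberg–Marquardt
least squares, adding components (up to 5) until the coefficient of
determination reaches `r2_min = 0.95`; if it never does, the best fit
is returned flagged below-threshold. Components are initialized at the
prominence-ranked local maxima of the curve (ties to the leftmost), or
incrementally from the previous fit plus a component at the residual
maximum; the incremental start guarantees the fit quality is
monotone in the component count. Fitting the smoothed curve (rather
than running EM on the raw values) mirrors the curve-fitting workflow
this procedure reproduces; it trades statistical orthodoxy for fidelity
to that workflow.

## 4. Evolutionary-rate correction and dating

Lineages differ in molecular clock rate; a peak between genomes *i* and
*j* is rescaled by `lambda_i * lambda_j` (standard deviations scale
linearly, variances by the square). Because the two basal anchor
species diverged from every ingroup species at essentially the same
time, the ratio of an anchor's peak against the baseline genome to its
peak against species *i* estimates `a_i = lambda_i / lambda_base`; the
two anchor-derived ratios are averaged, the slow anchor is pinned at
`lambda = 1`, and the slowest ingroup species pins
`max{lambda_i} = 1`, giving `lambda_base = 1 / max{a_i}`. The
normalization is applied over the corrected species set excluding the
slow anchor, exactly following the estimator's algebra; any conflict
between the two pins would be reported, not silently resolved.

Ages scale linearly from the corrected reference peak calibrated at
115–130 Ma. Reported intervals propagate only the calibration range
(endpoints rounded to integer Ma, raw values retained); the corrected
sigma is carried as a diagnostic but deliberately not folded into the
interval, matching how such ranges are conventionally printed.

**Peak selection.** Which mixture component is "the" divergence peak of
a between-genome comparison is not derivable from the data alone; the
default is the largest-weight component, overridable per comparison.

**A caution on within-genome dating of fast lineages.** Under an
additive clock the between-genome peak is proportional to
`r_i + r_j`, while the multiplicative correction `lambda_i lambda_j`
is exact only for ratios against a shared anchor. Anchor-versus-ingroup
peaks are therefore corrected essentially exactly (this is what the
consistency check verifies), but within-genome paralog peaks of a
lineage with rate far from the baseline retain a bias (about +11% in
dated age for a rate ratio of 2). Events dated against a reference on
the same lineage clock — the supported use — do not suffer from this.

## 5. The synthetic genome simulator

`simulate_history` plays an event schedule (speciations with
per-lineage rate multipliers; WGDs with ploidy 2 or 3) over an
ancestral genome, and logs every planted homologous pair with its
expected Ks (`2 * ks_per_myr * rate-scaled time`). Defaults:
`ks_per_myr = 0.003` per lineage (a typical angiosperm nuclear rate:
a 100 Ma split yields Ks 0.6), 2 chromosomes of 200 genes, 200 codons
per gene. WGD is modelled as chromosome-set duplication (duplicates
appended as new chromosomes, ranks recompacted) followed by independent
per-gene loss at the stated retention probability — colinear blocks
therefore exist by construction. No finer fractionation model is
implied by the procedures being emulated, so none is used.

**Codon model.** Sequences are built from the 20 pure
fourfold-degenerate codons (Gly, Ala, Pro, Thr, Val). For these, every
third-position change is synonymous and every other change is not, so
the synonymous substitution process is an exact four-state
Jukes–Cantor chain and expected NG86/JC Ks accumulates exactly
linearly in time — planted divergences are additive at any depth below
saturation. With codons drawn over all 61 sense codons (the obvious
alternative) the pooled NG86 `p_s` saturates above 3/4 — two-fold
degenerate positions contribute a third of a site but whole
differences — which makes expected Ks convex in time and planted pair
divergences non-additive by up to ~20%; that alternative was
implemented, measured, and rejected. `mutate_cds` still accepts
arbitrary sense-codon sequences: the expected Ks between its input and
output is calibrated numerically through the 61-state synonymous chain
(via its eigendecomposition), and an optional small nonsynonymous
fraction can be added; stop codons are never introduced. Targets above
3.0 are rejected (the correction is undefined as `p_s` approaches
3/4). Within `simulate_history`, chain time is tracked cumulatively
per lineage and calibrated at the pair level, so basal pairs hit their
expected Ks exactly even for non-fourfold input.

**What the fixtures do not emulate:** indels and alignment error
(pairs are generated gapless), transposable elements, realistic codon
usage and GC content, gene-order rearrangement beyond WGD
(inversions/translocations), tandem duplication, and fractionation
biases between subgenomes. Passing tests show the pipeline's inference
is correct when its modelling assumptions hold; on real genomes,
alignment quality and assembly contiguity add error sources the
fixtures cannot represent.

## 6. Multispecies-coalescent simulation and quartet frequencies

One lineage enters per species tip; within each species-tree branch of
length *t* coalescent units, *k* lineages coalesce with exponential
waiting times at rate `k(k-1)/2`; survivors pass upward, and lineages
reaching the root coalesce in an unbounded ancestral branch. Terminal
branch lengths default to 1 (one allele per species, where they are
irrelevant to topology frequencies). Gene trees are stored as merge
tables, from which both newick output and topology classification
derive; the simulation is deterministic given a seed.

Around a focal internal branch the four neighbor groups are the two
child clades (A, B), the sibling clade (C) and the remainder (D); when
the branch is incident to the root, the sibling's child clades stand in
for C and D, and classification is then around the single unrooted
internal edge. Every quartet with one leaf per group is classified by
its earliest-coalescing pair, and counts are pooled across quartets and
gene trees — the per-branch quartet-support convention of
coalescent species-tree methods. `q1` is the species-tree arrangement;
the closed form `q1 = 1 - (2/3) e^{-t}` serves as the validation
oracle. Branches are identified by their sorted leaf-set bipartition
so empirical tables align unambiguously.

The default number of simulated gene trees is 20,000; the figure
200,000 also appears in comparable workflows, and both are supported
through `n` — at 20,000 the binomial standard error on a frequency is
already ~0.35 points. Reported coalescent branch lengths in empirical
species trees attribute all gene-tree heterogeneity to ILS and may
therefore be overestimates; the simulation reproduces the stated
procedure without attempting to debias. Spearman concordance between
empirical and simulated frequencies uses the standard rank-correlation
test, two-sided.

## 7. Interfaces

All interchange formats are plain text: BED-like gene-position TSVs
(0-based ranks), 3-column anchor TSVs, per-pair Ks TSVs, peak tables,
topology-frequency TSVs, CDS FASTA, and newick with coalescent-unit
branch lengths (10 significant digits on write). The package's
interface is its functions — the two pipeline drivers
`run_wgd_pipeline` and `run_ils_pipeline` chain the stages end to
end — plus `scripts/acceptance.R` for the headline reproduction; a
separate shell-level subcommand wrapper would add surface without
capability for an analysis library and was deliberately not built.
Configuration is a named list (`run_config`), optionally read from
YAML, with defaults matching the conventional values (bandwidth 0.025,
R² 0.95, min block 10, max gap 25, calibration 115–130 Ma, 20,000 gene
trees).

## 8. Test problem sizes

The suite exercises deliberately compact problem sizes chosen to give
each statistical check comfortable power: genome fixtures of 2–6
chromosomes × 25–160 genes (150–300 codons per gene), 300+ pairs for
Ks-recovery checks, 600-value two-peak mixtures over 20 seeds, 20,000
gene trees for the headline frequencies and 6,000–8,000 for the
property sweeps. These sizes are the package's own choices; every
tolerance used is stated next to the corresponding check.
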
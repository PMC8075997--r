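#' A 14-taxon angiosperm species tree in coalescent units
#'
#' Genus-level species tree of 13 angiosperms plus a gymnosperm outgroup
#' (Ginkgo), with Amborella and Euryale (Nymphaeales) successively
#' sister to all other angiosperms, and monocots and magnoliids
#' successively sister to (Ceratophyllum, eudicots). Internal branch
#' lengths are in coalescent units; two focal internal branches, the one
#' subtending (Euryale + mesangiosperms) and the one subtending
#' (Ceratophyllum + eudicots), can be set individually to study
#' incomplete lineage sorting around the contentious splits.
#'
#' @param ana_branch Length of the internal branch separating Amborella
#'   from (Euryale + mesangiosperms).
#' @param cerato_branch Length of the internal branch subtending
#'   (Ceratophyllum, eudicots).
#' @param other_internal Length of every other internal branch
#'   (default 5 coalescent units, effectively no ILS there).
#' @param terminal Terminal branch length (default 1, one allele per
#'   species).
#' @return An \code{ape::phylo} rooted binary tree.
#' @export
angiosperm14_tree <- function(ana_branch = 5, cerato_branch = 5,
                              other_internal = 5, terminal = 1) {
  o <- other_internal
  nwk <- sprintf(paste0(
    "(Ginkgo:%1$g,(Amborella:%1$g,(Euryale:%1$g,",
    "((Phalaenopsis:%1$g,(Musa:%1$g,Oryza:%1$g):%2$g):%2$g,",
    "(((Cinnamomum:%1$g,Persea:%1$g):%2$g,Liriodendron:%1$g):%2$g,",
    "(Ceratophyllum:%1$g,",
    "(Aquilegia:%1$g,(Vitis:%1$g,(Arabidopsis:%1$g,Prunus:%1$g",
    "):%2$g):%2$g):%2$g):%4$g):%2$g):%2$g):%3$g):%2$g);"),
    terminal, o, ana_branch, cerato_branch)
  ape::read.tree(text = nwk)
}

#' Leaf sets of the two focal clades of the 14-taxon tree
#'
#' @return List with \code{ana} (the clade below the branch separating
#'   Amborella from the rest: Euryale plus all mesangiosperms) and
#'   \code{cerato} (Ceratophyllum plus the eudicots).
#' @export
angiosperm14_clades <- function() {
  meso <- c("Phalaenopsis", "Musa", "Oryza", "Cinnamomum", "Persea",
            "Liriodendron", "Ceratophyllum", "Aquilegia", "Vitis",
            "Arabidopsis", "Prunus")
  list(ana = c("Euryale", meso),
       cerato = c("Ceratophyllum", "Aquilegia", "Vitis", "Arabidopsis",
                  "Prunus"))
}
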
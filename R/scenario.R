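#' Speciation event for an evolution scenario
#'
#' @param time_ma Event age in Ma (million years before present).
#' @param lineage Name of the lineage that splits.
#' @param children Character vector (length >= 2) of child lineage names.
#'   Multifurcations are allowed and model simultaneous splits.
#' @param rates Numeric vector of per-child evolutionary-rate multipliers
#'   r_i (>= 0, relative to the baseline clock); recycled if length 1.
#' @return A speciation event (list), for use in
#'   \code{\link{evolution_scenario}}.
#' @export
event_speciation <- function(time_ma, lineage, children, rates = 1) {
  stopifnot(time_ma > 0, length(children) >= 2, all(rates >= 0))
  rates <- rep_len(rates, length(children))
  if (anyDuplicated(children)) stop("duplicate child lineage names")
  structure(list(type = "speciation", time_ma = time_ma, lineage = lineage,
                 children = children, rates = rates),
            class = "evo_event")
}

#' Whole-genome duplication event for an evolution scenario
#'
#' @param time_ma Event age in Ma.
#' @param lineage Lineage in which the polyploidization occurs.
#' @param ploidy Ploidy multiplier, 2 (duplication) or 3 (triplication).
#' @param retention Probability in [0, 1] that each duplicated gene copy
#'   is retained (independent per-gene loss; original copies are kept).
#' @return A WGD event (list).
#' @export
event_wgd <- function(time_ma, lineage, ploidy = 2, retention = 1) {
  stopifnot(time_ma > 0, ploidy %in% c(2, 3),
            retention >= 0, retention <= 1)
  structure(list(type = "wgd", time_ma = time_ma, lineage = lineage,
                 ploidy = as.integer(ploidy), retention = retention),
            class = "evo_event")
}

#' Define a genome-evolution scenario
#'
#' A scenario is an ordered schedule of speciation and polyploidization
#' (WGD) events on a set of lineages, plus the shape of the ancestral
#' genome and the baseline molecular clock. Event times must be strictly
#' decreasing toward the present; the first event acts on the root
#' lineage.
#'
#' @param events List of events built with \code{\link{event_speciation}}
#'   and \code{\link{event_wgd}}, ordered from oldest to most recent.
#' @param chromosomes Number of chromosomes in the ancestral genome.
#' @param genes_per_chromosome Genes per ancestral chromosome.
#' @param cds_codons Codons per gene.
#' @param ks_per_myr Baseline synonymous-divergence accumulation rate, in
#'   Ks units per lineage per Myr for a lineage with rate multiplier 1
#'   (default 0.003, a typical angiosperm nuclear rate: a pair split T Ma
#'   ago accumulates an expected Ks of 2 x 0.003 x T).
#' @param seed Integer seed; the whole simulation is deterministic given
#'   the scenario.
#' @return An object of class \code{evolution_scenario}.
#' @export
evolution_scenario <- function(events, chromosomes = 2,
                               genes_per_chromosome = 200,
                               cds_codons = 200, ks_per_myr = 0.003,
                               seed = 1) {
  stopifnot(length(events) >= 1, chromosomes >= 1,
            genes_per_chromosome >= 1, cds_codons >= 1, ks_per_myr > 0)
  if (!all(vapply(events, inherits, logical(1), "evo_event"))) {
    stop("all events must be built with event_speciation()/event_wgd()")
  }
  times <- vapply(events, `[[`, numeric(1), "time_ma")
  if (any(diff(times) >= 0)) {
    stop("event times must be strictly decreasing toward the present")
  }
  structure(
    list(events = events, chromosomes = as.integer(chromosomes),
         genes_per_chromosome = as.integer(genes_per_chromosome),
         cds_codons = as.integer(cds_codons), ks_per_myr = ks_per_myr,
         seed = as.integer(seed)),
    class = "evolution_scenario"
  )
}

#' @export
print.evolution_scenario <- function(x, ...) {
  cat("Evolution scenario:", length(x$events), "events,",
      x$chromosomes, "x", x$genes_per_chromosome, "ancestral genes,",
      "ks_per_myr =", x$ks_per_myr, "\n")
  for (e in x$events) {
    if (e$type == "speciation") {
      cat(sprintf("  %6.1f Ma  speciation  %s -> %s (rates %s)\n",
                  e$time_ma, e$lineage, paste(e$children, collapse = ", "),
                  paste(e$rates, collapse = ", ")))
    } else {
      cat(sprintf("  %6.1f Ma  WGD x%d     %s (retention %.2f)\n",
                  e$time_ma, e$ploidy, e$lineage, e$retention))
    }
  }
  invisible(x)
}
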
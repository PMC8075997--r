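# End-to-end drivers chaining the analysis stages: the Ks/WGD pipeline
# (synteny -> per-anchor Ks -> block medians -> density peaks ->
# rate correction -> dating) and the ILS pipeline (coalescent
# simulation -> per-branch topology frequencies -> concordance test).

gene_species_map <- function(genomes) {
  sp <- rep(names(genomes), vapply(genomes, function(g)
    length(g$cds), integer(1)))
  stats::setNames(sp, unlist(lapply(genomes, function(g) names(g$cds)),
                             use.names = FALSE))
}

#' Ks mixture fits for every genome comparison
#'
#' Splits an anchor table by species pair (including within-genome
#' self-comparisons), chains each into syntenic blocks, estimates
#' per-anchor Ks, and fits a Gaussian mixture to the kernel density of
#' the block median Ks values. Comparisons yielding fewer than 5 blocks
#' are skipped with a message.
#'
#' @param genomes Named list of \code{annotated_genome} objects.
#' @param anchors Anchor table covering any subset of the genomes.
#' @param config Parameters from \code{\link{run_config}}.
#' @return List keyed "i-j" of lists with \code{blocks}, \code{medians}
#'   and \code{fit} (a \code{mixture_fit}).
#' @export
wgd_ks_fits <- function(genomes, anchors, config = run_config()) {
  smap <- gene_species_map(genomes)
  unknown <- setdiff(c(anchors$gene_a, anchors$gene_b), names(smap))
  if (length(unknown) > 0) {
    stop("anchor gene(s) not in any genome: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  sa <- smap[anchors$gene_a]
  sb <- smap[anchors$gene_b]
  flip <- sa > sb
  key <- paste(ifelse(flip, sb, sa), ifelse(flip, sa, sb), sep = "-")
  params <- chain_params(min_block = config$min_block,
                         max_gap = config$max_gap)
  out <- list()
  for (k in sort(unique(key))) {
    sub <- anchors[key == k, , drop = FALSE]
    sp <- strsplit(k, "-", fixed = TRUE)[[1]]
    blocks <- chain_anchors(sub, genomes[[sp[1]]], genomes[[sp[2]]],
                            params)
    if (length(blocks) == 0) {
      message("comparison ", k, ": no syntenic blocks, skipped")
      next
    }
    cds <- c(genomes[[sp[1]]]$cds, genomes[[sp[2]]]$cds)
    blocks <- blocks_ks(blocks, cds)
    med <- block_medians(blocks)
    if (length(med) < 5) {
      message("comparison ", k, ": only ", length(med),
              " blocks, too few for a density estimate; skipped")
      next
    }
    curve <- ks_kde(med, bandwidth = config$bandwidth)
    fit <- fit_mixture(curve, r2_min = config$r2_min)
    out[[k]] <- list(blocks = blocks, medians = med, fit = fit)
  }
  out
}

#' Run the full Ks/WGD dating pipeline
#'
#' Chains \code{\link{wgd_ks_fits}}, peak selection, rate correction and
#' calibration-based dating.
#'
#' @inheritParams wgd_ks_fits
#' @param anchors_roles Named character vector (\code{slow},
#'   \code{second}, \code{baseline}) naming which genomes play the
#'   rate-correction anchor roles; NULL skips correction and dating.
#' @param reference_key Peak-table key of the calibration event (for
#'   example the baseline genome's within-genome WGD peak, "Vv-Vv");
#'   required for dating.
#' @param component Optional per-comparison component overrides for
#'   \code{\link{peaks_from_fits}}.
#' @return List with \code{fits}, \code{peaks}, and when roles are
#'   given: \code{model} (\code{rate_model}), \code{consistency},
#'   \code{corrected} (per comparison) and \code{dated} (data.frame of
#'   event ages in Ma).
#' @export
run_wgd_pipeline <- function(genomes, anchors, config = run_config(),
                             anchors_roles = NULL, reference_key = NULL,
                             component = NULL) {
  fits <- wgd_ks_fits(genomes, anchors, config)
  peaks <- peaks_from_fits(lapply(fits, `[[`, "fit"), component)
  out <- list(fits = fits, peaks = peaks)
  if (is.null(anchors_roles)) return(out)
  model <- fit_rate_model(peaks, anchors = anchors_roles)
  out$model <- model
  out$consistency <- consistency_check(peaks, model, anchors_roles)
  lam <- function(sp) {
    if (sp %in% names(model$lambda)) model$lambda[[sp]] else 1
  }
  corr <- lapply(names(peaks), function(kk) {
    sp <- strsplit(kk, "-", fixed = TRUE)[[1]]
    correct_distribution(peaks[[kk]], lam(sp[1]), lam(sp[2]))
  })
  names(corr) <- names(peaks)
  out$corrected <- corr
  if (!is.null(reference_key)) {
    if (is.null(corr[[reference_key]])) {
      stop("reference comparison ", reference_key, " not among peaks")
    }
    cal <- ks_calibration(corr[[reference_key]]$mu_corrected,
                          config$age_low, config$age_high)
    dated <- do.call(rbind, lapply(names(corr), function(kk) {
      d <- date_event(corr[[kk]], cal)
      data.frame(event = kk, mu_raw = peaks[[kk]]$mu,
                 mu_corrected = corr[[kk]]$mu_corrected,
                 age_low = d$age_low, age_high = d$age_high)
    }))
    out$calibration <- cal
    out$dated <- dated
  }
  out
}

#' Run the ILS concordance pipeline
#'
#' Simulates gene trees under the multispecies coalescent on a species
#' tree, computes topology frequencies around each requested focal
#' branch, and (optionally) tests rank concordance against empirical
#' frequencies.
#'
#' @param tree Species tree (\code{ape::phylo}, coalescent units).
#' @param clades List of focal clades (character vectors of tip
#'   labels), one per focal internal branch.
#' @param empirical Optional numeric vector of empirical proportions,
#'   in the same order as the simulated ones are returned (q1, q2, q3
#'   per branch).
#' @param n Number of gene trees (default 20000).
#' @param seed Integer seed.
#' @return List with \code{genetrees}, \code{freqs} (list of
#'   \code{quartet_freqs}), \code{table} (data.frame) and, when
#'   empirical frequencies are supplied, \code{concordance}.
#' @export
run_ils_pipeline <- function(tree, clades, empirical = NULL, n = 20000,
                             seed = 1) {
  gts <- simulate_gene_trees(tree, n, seed = seed)
  freqs <- lapply(clades, function(cl) topology_freqs(gts, tree, cl))
  tab <- do.call(rbind, lapply(freqs, function(tf) {
    data.frame(branch_id = tf$branch_id, q1 = tf$freqs[["q1"]],
               q2 = tf$freqs[["q2"]], q3 = tf$freqs[["q3"]],
               n = tf$n_quartets)
  }))
  out <- list(genetrees = gts, freqs = freqs, table = tab)
  if (!is.null(empirical)) {
    sim <- as.vector(t(as.matrix(tab[, c("q1", "q2", "q3")])))
    out$concordance <- concordance(empirical, sim)
  }
  out
}
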
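# Forward simulator: plays an event schedule over annotated genomes,
# mutating CDS along each branch so that expected pairwise Ks equals the
# rate-scaled separation time, and logging every planted homologous pair.

new_genome <- function(species, genes, cds) {
  structure(
    list(species = species,
         loci = split(genes[, c("gene", "rank", "strand")], genes$chrom),
         cds = cds),
    class = "annotated_genome"
  )
}

#' Gene positions of an annotated genome as one table
#'
#' @param genome An \code{annotated_genome}.
#' @return data.frame with columns chrom, rank, strand, gene (0-based
#'   ranks, consecutive within each chromosome).
#' @export
gene_positions <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  chroms <- names(genome$loci)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    d <- genome$loci[[ch]]
    data.frame(chrom = ch, rank = d$rank, strand = d$strand,
               gene = d$gene, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.annotated_genome <- function(x, ...) {
  n <- sum(vapply(x$loci, nrow, integer(1)))
  cat("Annotated genome '", x$species, "': ", length(x$loci),
      " chromosomes, ", n, " genes\n", sep = "")
  invisible(x)
}

# scaled time (in rate-weighted Myr) accumulated by a lineage between
# event age t_ma and the present, given its segment history
scaled_path <- function(hist, t_ma) {
  if (nrow(hist) == 0) return(0)
  overlap <- pmin(hist$from, t_ma) - pmax(hist$to, 0)
  sum(hist$rate * pmax(overlap, 0))
}

#' Simulate genome evolution under a scenario
#'
#' Plays the event schedule from oldest event to the present. Speciations
#' copy the genome into each child lineage (each with its own
#' evolutionary-rate multiplier); WGDs duplicate the chromosome set in
#' place, appending duplicates as new chromosomes and retaining each
#' duplicated gene independently with the stated retention probability.
#' CDS divergence is applied per branch segment so that a pair of genes
#' separated for rate-scaled time tau has expected Ks =
#' \code{2 * ks_per_myr * tau}.
#'
#' @param scenario An \code{\link{evolution_scenario}}.
#' @return List with \code{genomes} (named list of
#'   \code{annotated_genome}, one per extant lineage) and \code{truth}
#'   (the truth log: one row per planted homologous pair, with event id,
#'   type, age, species and expected Ks; realized per-species rate
#'   multipliers are stored in \code{attr(truth, "rates")}).
#' @export
simulate_history <- function(scenario) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  withr::with_seed(scenario$seed, simulate_history_impl(scenario))
}

simulate_history_impl <- function(scenario) {
  k <- scenario$ks_per_myr
  counter <- 0L
  new_ids <- function(n) {
    ids <- sprintf("g%06d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  parent_of <- new.env(parent = emptyenv())
  children_of <- new.env(parent = emptyenv())
  link_event <- new.env(parent = emptyenv())
  link <- function(child, parent, event) {
    assign(child, parent, envir = parent_of)
    assign(child, event, envir = link_event)
    kids <- children_of[[parent]]
    assign(parent, c(kids, child), envir = children_of)
  }

  # ancestral genome on the root lineage
  root <- scenario$events[[1]]$lineage
  n0 <- scenario$chromosomes * scenario$genes_per_chromosome
  ids <- new_ids(n0)
  genes <- data.frame(
    gene = ids,
    chrom = rep(sprintf("chr%d", seq_len(scenario$chromosomes)),
                each = scenario$genes_per_chromosome),
    rank = rep(seq_len(scenario$genes_per_chromosome) - 1L,
               scenario$chromosomes),
    strand = sample(c("+", "-"), n0, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cds <- stats::setNames(
    vapply(seq_len(n0), function(i) random_cds(scenario$cds_codons),
           character(1)),
    ids
  )
  empty_hist <- data.frame(from = numeric(0), to = numeric(0),
                           rate = numeric(0))
  lineages <- list()
  lineages[[root]] <- list(genes = genes, cds = cds, rate = 1,
                           birth = scenario$events[[1]]$time_ma,
                           hist = empty_hist, K = 0, Tchain = 0)

  pair_seeds <- list()   # per event: data.frame(gene_a, gene_b)
  event_meta <- list()
  dup_counter <- 0L
  now <- scenario$events[[1]]$time_ma

  # Divergence bookkeeping: each lineage tracks its cumulative target Ks
  # from the root (K) and the substitution-chain time already applied
  # (Tchain). The chain time is calibrated so that a symmetric pair of
  # lineages split at the root measures an expected pairwise NG86 Ks of
  # exactly 2K; because the calibration curve is mildly nonlinear, pairs
  # split by later events carry a small (few percent) second-order error.
  all_c <- sense_codons()
  half_pair_time <- function(K, w) {
    tgt <- 2 * K
    cap <- 2.9  # stay below the JC saturation bound of the calibration
    if (tgt <= cap) return(0.5 * ks_to_chain_time(tgt, w))
    0.5 * ks_to_chain_time(cap, w) * tgt / cap
  }
  advance <- function(lin, dt) {
    if (dt <= 0 || lin$rate == 0) return(lin)
    lin$K <- lin$K + k * lin$rate * dt
    w <- codon_composition(
      unlist(lapply(lin$cds, split_codons), use.names = FALSE), all_c)
    t_new <- max(half_pair_time(lin$K, w), lin$Tchain)
    lin$cds <- mutate_many(lin$cds, 0, chain_time = t_new - lin$Tchain)
    lin$Tchain <- t_new
    lin
  }

  for (ei in seq_along(scenario$events)) {
    ev <- scenario$events[[ei]]
    dt <- now - ev$time_ma
    lineages <- lapply(lineages, advance, dt = dt)
    now <- ev$time_ma
    if (is.null(lineages[[ev$lineage]])) {
      stop("event ", ei, " (", ev$type, ") references unknown or extinct ",
           "lineage '", ev$lineage, "'")
    }
    eid <- sprintf("E%d_%s", ei, ev$type)
    event_meta[[eid]] <- list(type = ev$type, time_ma = ev$time_ma)
    if (ev$type == "speciation") {
      par <- lineages[[ev$lineage]]
      par$hist <- rbind(par$hist,
                        data.frame(from = par$birth, to = ev$time_ma,
                                   rate = par$rate))
      ng <- nrow(par$genes)
      copies <- matrix(character(0), nrow = ng, ncol = 0)
      for (ci in seq_along(ev$children)) {
        child <- ev$children[[ci]]
        if (!is.null(lineages[[child]])) {
          stop("child lineage '", child, "' already exists")
        }
        cids <- new_ids(ng)
        for (j in seq_len(ng)) link(cids[j], par$genes$gene[j], eid)
        cg <- par$genes
        cg$gene <- cids
        ccds <- stats::setNames(par$cds[par$genes$gene], cids)
        lineages[[child]] <- list(genes = cg, cds = ccds,
                                  rate = ev$rates[[ci]],
                                  birth = ev$time_ma, hist = par$hist,
                                  K = par$K, Tchain = par$Tchain)
        copies <- cbind(copies, cids)
      }
      lineages[[ev$lineage]] <- NULL
      # ortholog pair seeds: same ancestral gene, different child lineages
      seeds <- do.call(rbind, lapply(
        utils::combn(ncol(copies), 2, simplify = FALSE),
        function(pr) data.frame(gene_a = copies[, pr[1]],
                                gene_b = copies[, pr[2]],
                                stringsAsFactors = FALSE)
      ))
      pair_seeds[[eid]] <- seeds
    } else {  # wgd
      lin <- lineages[[ev$lineage]]
      n_copy <- ev$ploidy - 1L
      seed_rows <- list()
      for (cc in seq_len(n_copy)) {
        dup_counter <- dup_counter + 1L
        keep <- stats::runif(nrow(lin$genes)) < ev$retention
        src <- lin$genes[keep, , drop = FALSE]
        if (nrow(src) == 0) next
        cids <- new_ids(nrow(src))
        for (j in seq_len(nrow(src))) link(cids[j], src$gene[j], eid)
        # bind copy sequences and truth pairs to ids while still aligned
        lin$cds <- c(lin$cds, stats::setNames(lin$cds[src$gene], cids))
        seed_rows[[cc]] <- data.frame(gene_a = src$gene, gene_b = cids,
                                      stringsAsFactors = FALSE)
        dup <- src
        dup$gene <- cids
        dup$chrom <- sprintf("%sd%d", src$chrom, dup_counter)
        # recompact ranks within each duplicate chromosome
        dup <- do.call(rbind, lapply(split(dup, dup$chrom), function(d) {
          d <- d[order(d$rank), , drop = FALSE]
          d$rank <- seq_len(nrow(d)) - 1L
          d
        }))
        rownames(dup) <- NULL
        lin$genes <- rbind(lin$genes, dup)
      }
      # pairs among retained copies of the same gene (triplication)
      if (n_copy == 2 && length(seed_rows) == 2) {
        m <- merge(seed_rows[[1]], seed_rows[[2]], by = "gene_a")
        if (nrow(m) > 0) {
          seed_rows[[3]] <- data.frame(gene_a = m$gene_b.x,
                                       gene_b = m$gene_b.y,
                                       stringsAsFactors = FALSE)
        }
      }
      pair_seeds[[eid]] <- do.call(rbind, seed_rows)
      lineages[[ev$lineage]] <- lin
    }
  }

  # final stretch to the present
  lineages <- lapply(lineages, advance, dt = now)
  for (nm in names(lineages)) {
    lin <- lineages[[nm]]
    lineages[[nm]]$hist <- rbind(
      lin$hist, data.frame(from = lin$birth, to = 0, rate = lin$rate))
  }

  genomes <- lapply(names(lineages), function(nm) {
    lin <- lineages[[nm]]
    g <- lin$genes[order(lin$genes$chrom, lin$genes$rank), , drop = FALSE]
    new_genome(nm, g, lin$cds[g$gene])
  })
  names(genomes) <- names(lineages)

  # map extant gene -> species, and resolve descendants of pair seeds
  gene_species <- new.env(parent = emptyenv())
  for (nm in names(genomes)) {
    for (g in names(genomes[[nm]]$cds)) assign(g, nm, envir = gene_species)
  }
  # Extant descendants of `id`, not traversing links created by
  # `skip_event` (those belong to the other side of that event's pairs).
  descendants <- function(id, skip_event) {
    out <- character(0)
    stack <- id
    while (length(stack) > 0) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (!is.null(gene_species[[cur]])) out <- c(out, cur)
      kids <- children_of[[cur]]
      for (kid in kids) {
        if (!identical(link_event[[kid]], skip_event)) {
          stack <- c(stack, kid)
        }
      }
    }
    out
  }

  rows <- list()
  for (eid in names(pair_seeds)) {
    seeds <- pair_seeds[[eid]]
    if (is.null(seeds) || nrow(seeds) == 0) next
    t_ev <- event_meta[[eid]]$time_ma
    for (j in seq_len(nrow(seeds))) {
      da <- descendants(seeds$gene_a[j], eid)
      db <- descendants(seeds$gene_b[j], eid)
      if (length(da) == 0 || length(db) == 0) next
      grid <- expand.grid(gene_a = da, gene_b = db,
                          stringsAsFactors = FALSE)
      grid$event_id <- eid
      grid$event_type <- event_meta[[eid]]$type
      grid$time_ma <- t_ev
      rows[[length(rows) + 1L]] <- grid
    }
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    truth <- data.frame(gene_a = character(0), gene_b = character(0),
                        event_id = character(0), event_type = character(0),
                        time_ma = numeric(0))
  }
  truth$species_a <- vapply(truth$gene_a, function(g) gene_species[[g]],
                            character(1))
  truth$species_b <- vapply(truth$gene_b, function(g) gene_species[[g]],
                            character(1))
  path_of <- lapply(lineages, `[[`, "hist")
  truth$expected_ks <- k * (
    mapply(function(sp, t) scaled_path(path_of[[sp]], t),
           truth$species_a, truth$time_ma) +
    mapply(function(sp, t) scaled_path(path_of[[sp]], t),
           truth$species_b, truth$time_ma)
  )
  truth <- truth[, c("event_id", "event_type", "time_ma", "gene_a",
                     "gene_b", "species_a", "species_b", "expected_ks")]
  rownames(truth) <- NULL
  attr(truth, "rates") <- vapply(lineages, `[[`, numeric(1), "rate")
  class(truth) <- c("truth_log", "data.frame")
  list(genomes = genomes, truth = truth)
}

#' Emit an anchor-pair table from a truth log
#'
#' Produces the homologous anchor pairs that downstream synteny detection
#' consumes: every true planted pair, plus a configurable fraction of
#' random spurious pairs.
#'
#' @param truth A truth log from \code{\link{simulate_history}}.
#' @param noise_fraction Fraction (of the number of true pairs, in
#'   [0, 1)) of spurious uniformly random pairs to add.
#' @param seed Integer seed for the spurious pairs.
#' @param genomes Optional named list of genomes; if given, spurious
#'   pairs are drawn from all their genes, otherwise from genes present
#'   in the truth log.
#' @return data.frame with columns gene_a, gene_b, score.
#' @export
emit_anchor_pairs <- function(truth, noise_fraction = 0, seed = 1,
                              genomes = NULL) {
  stopifnot(noise_fraction >= 0, noise_fraction < 1)
  anchors <- data.frame(gene_a = truth$gene_a, gene_b = truth$gene_b,
                        score = 1, stringsAsFactors = FALSE)
  n_noise <- round(noise_fraction * nrow(anchors))
  if (n_noise > 0) {
    pool <- if (is.null(genomes)) {
      unique(c(truth$gene_a, truth$gene_b))
    } else {
      unlist(lapply(genomes, function(g) names(g$cds)), use.names = FALSE)
    }
    true_key <- paste(anchors$gene_a, anchors$gene_b)
    spur <- withr::with_seed(seed, {
      out <- data.frame(gene_a = character(0), gene_b = character(0))
      while (nrow(out) < n_noise) {
        a <- sample(pool, n_noise, replace = TRUE)
        b <- sample(pool, n_noise, replace = TRUE)
        cand <- data.frame(gene_a = a, gene_b = b,
                           stringsAsFactors = FALSE)
        cand <- cand[cand$gene_a != cand$gene_b &
                       !(paste(cand$gene_a, cand$gene_b) %in% true_key) &
                       !(paste(cand$gene_b, cand$gene_a) %in% true_key), ,
                     drop = FALSE]
        out <- unique(rbind(out, cand))
      }
      out[seq_len(n_noise), , drop = FALSE]
    })
    spur$score <- 1
    anchors <- rbind(anchors, spur)
  }
  rownames(anchors) <- NULL
  anchors
}
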
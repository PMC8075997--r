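# Synonymous-substitution mutator.
#
# Divergence is modelled as a continuous-time Markov chain on the 61 sense
# codons whose only moves are single-nucleotide synonymous changes, all at
# equal rate. The chain is symmetric, hence reversible, and branch lengths
# are additive: mutating for time t1 and then t2 equals mutating for
# t1 + t2, so a pair of sequences that evolved independently for times ta
# and tb from a common ancestor is distributed as one sequence mutated for
# ta + tb. The chain time is calibrated numerically so that the *expected*
# NG86/Jukes-Cantor Ks between input and output equals the requested
# target, multiple hits and within-family saturation included.

syn_rate_matrix <- function() {
  if (!is.null(.codon_cache$Q)) return(.codon_cache$Q)
  cods <- sense_codons()
  n <- length(cods)
  Q <- matrix(0, n, n, dimnames = list(cods, cods))
  for (i in seq_len(n)) {
    for (pos in 1:3) {
      for (nt in setdiff(NUCS, substr(cods[i], pos, pos))) {
        alt <- cods[i]
        substr(alt, pos, pos) <- nt
        if (is_sense(alt) &&
            GENETIC_CODE_STD[[alt]] == GENETIC_CODE_STD[[cods[i]]]) {
          Q[i, alt] <- 1
        }
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  .codon_cache$Q <- Q
  Q
}

syn_eigen <- function() {
  if (is.null(.codon_cache$Qe)) {
    .codon_cache$Qe <- eigen(syn_rate_matrix(), symmetric = TRUE)
  }
  .codon_cache$Qe
}

# Transition probability matrix exp(Q t) of the synonymous chain.
syn_transition <- function(t) {
  e <- syn_eigen()
  P <- e$vectors %*% (t(e$vectors) * exp(e$values * t))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(syn_rate_matrix())
  P
}

# Expected NG86 Sd and S between a codon sampled from `weights` and its
# state after chain time t; returns the implied JC Ks.
expected_ks_at_time <- function(t, weights) {
  cods <- sense_codons()
  P <- syn_transition(t)
  Stab <- syn_sites_table()
  if (is.null(.codon_cache$SDmat)) {
    SD <- matrix(0, length(cods), length(cods), dimnames = list(cods, cods))
    for (a in cods) {
      for (b in cods) {
        if (a != b && GENETIC_CODE_STD[[a]] == GENETIC_CODE_STD[[b]]) {
          SD[a, b] <- pair_diffs_cached(a, b)[["sd"]]
        }
      }
    }
    .codon_cache$SDmat <- SD
  }
  SD <- .codon_cache$SDmat
  e_sd <- sum(weights * rowSums(P * SD))
  e_s <- sum(weights * (Stab + P %*% Stab) / 2)
  p_s <- e_sd / e_s
  if (p_s >= 3 / 4) return(Inf)
  -(3 / 4) * log(1 - (4 / 3) * p_s)
}

# Chain time that yields a given expected NG86 Ks for the supplied codon
# composition. Vectorized over nothing; cached per (rounded) composition.
ks_to_chain_time <- function(target_ks, weights) {
  if (target_ks == 0) return(0)
  upper <- 1
  while (expected_ks_at_time(upper, weights) < target_ks) {
    upper <- upper * 2
    if (upper > 2^12) stop("target_ks ", target_ks, " beyond saturation bound")
  }
  stats::uniroot(function(t) expected_ks_at_time(t, weights) - target_ks,
                 lower = 0, upper = upper, tol = 1e-8)$root
}

#' Mutate a coding sequence to a target synonymous divergence
#'
#' Applies random synonymous substitutions (and, optionally, a small
#' fraction of nonsynonymous ones) so that the expected Nei-Gojobori /
#' Jukes-Cantor Ks between input and output equals \code{target_ks}.
#' Stop codons are never introduced; with \code{nonsyn_fraction = 0} the
#' encoded protein is unchanged.
#'
#' @param seq Codon sequence (character scalar, length divisible by 3, all
#'   codons sense codons).
#' @param target_ks Desired expected Ks in [0, 3]; values above 3 are
#'   rejected because the Jukes-Cantor correction saturates.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param nonsyn_fraction Expected nonsynonymous differences per
#'   nonsynonymous site, as a fraction of \code{target_ks} (default 0).
#' @return The mutated codon sequence (character scalar).
#' @export
mutate_cds <- function(seq, target_ks, seed, nonsyn_fraction = 0) {
  stopifnot(target_ks >= 0, nonsyn_fraction >= 0)
  if (target_ks > 3) {
    stop("target_ks = ", target_ks,
         " exceeds the saturation bound of 3 synonymous substitutions per site")
  }
  cods <- split_codons(toupper(seq))
  if (!all(is_sense(cods))) stop("input contains stop or ambiguous codons")
  if (target_ks == 0 && nonsyn_fraction == 0) return(seq)
  withr::with_seed(seed, {
    out <- if (target_ks > 0) {
      split_codons(mutate_many(paste(cods, collapse = ""), target_ks))
    } else {
      cods
    }
    if (nonsyn_fraction > 0 && target_ks > 0) {
      n_sites <- sum(3 - syn_sites_table()[out])
      m <- stats::rpois(1, nonsyn_fraction * target_ks * n_sites)
      applied <- 0
      while (applied < m) {
        k <- sample.int(length(out), 1)
        pos <- sample.int(3, 1)
        nt <- sample(setdiff(NUCS, substr(out[k], pos, pos)), 1)
        alt <- out[k]
        substr(alt, pos, pos) <- nt
        if (is_sense(alt) &&
            GENETIC_CODE_STD[[alt]] != GENETIC_CODE_STD[[out[k]]]) {
          out[k] <- alt
          applied <- applied + 1
        }
      }
    }
    paste(out, collapse = "")
  })
}

codon_composition <- function(cods, all_c) {
  w <- tabulate(match(cods, all_c), nbins = length(all_c))
  w / sum(w)
}

# Batch synonymous mutation of several CDS by the same target Ks, using
# the caller's RNG state (no seed handling here). Sampling is grouped by
# codon type so cost is O(#codons + 61 sample() calls). `chain_time`,
# when given, applies that much raw chain time instead of calibrating
# from target_ks.
mutate_many <- function(seqs, target_ks, chain_time = NULL) {
  if (is.null(chain_time) && target_ks == 0) return(seqs)
  cods_by_seq <- lapply(seqs, split_codons)
  cods <- unlist(cods_by_seq, use.names = FALSE)
  all_c <- sense_codons()
  idx <- match(cods, all_c)
  if (anyNA(idx)) stop("input contains stop or ambiguous codons")
  t <- if (is.null(chain_time)) {
    ks_to_chain_time(target_ks, codon_composition(cods, all_c))
  } else {
    chain_time
  }
  if (t <= 0) return(seqs)
  P <- syn_transition(t)
  out <- integer(length(idx))
  for (ci in unique(idx)) {
    pos <- which(idx == ci)
    out[pos] <- sample.int(length(all_c), length(pos),
                           replace = TRUE, prob = P[ci, ])
  }
  new_cods <- all_c[out]
  lens <- lengths(cods_by_seq)
  res <- vapply(
    split(new_cods, factor(rep(seq_along(lens), lens), levels = seq_along(lens))),
    paste, character(1), collapse = ""
  )
  names(res) <- names(seqs)
  res
}

#' Codons of the pure fourfold-degenerate families
#'
#' The 20 codons of Gly, Ala, Pro, Thr and Val: every third-position
#' change is synonymous, every first/second-position change is not, so
#' each codon has exactly one NG86 synonymous site and the synonymous
#' substitution process restricted to these families is an exact
#' four-state Jukes-Cantor chain. Sequences built from them accumulate
#' expected NG86/JC Ks exactly linearly in time, which makes planted
#' divergences additive at any depth below saturation.
#'
#' @return Character vector of 20 codons.
#' @export
fourfold_codons <- function() {
  as.vector(outer(c("GG", "GC", "CC", "AC", "GT"), NUCS, paste0))
}

#' Generate a random coding sequence
#'
#' Codons drawn uniformly over the fourfold-degenerate codon set of
#' \code{\link{fourfold_codons}} (the generator's codon model; see the
#' methods vignette for why synonymous divergence is then exactly
#' clock-linear).
#'
#' @param n_codons Number of codons.
#' @return Character scalar CDS.
#' @keywords internal
random_cds <- function(n_codons) {
  paste(sample(fourfold_codons(), n_codons, replace = TRUE), collapse = "")
}
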
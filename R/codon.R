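# Standard genetic code, codon -> one-letter amino acid ("*" = stop).
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

NUCS <- c("A", "C", "G", "T")

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
}

#' Translate a codon sequence
#'
#' @param seq A character scalar of concatenated codons (length divisible
#'   by 3, uppercase A/C/G/T).
#' @return Character scalar of one-letter amino acids ("*" for stops).
#' @export
translate_cds <- function(seq) {
  paste(GENETIC_CODE_STD[split_codons(seq)], collapse = "")
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

is_sense <- function(codon) {
  !is.na(GENETIC_CODE_STD[codon]) & GENETIC_CODE_STD[codon] != "*"
}

# Per-codon synonymous site count: at each position the fraction (of the
# three possible single-nucleotide changes) that are synonymous. Changes to
# stop codons count as nonsynonymous (NG86 convention).
codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_STD[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      aa2 <- GENETIC_CODE_STD[[alt]]
      if (aa2 != "*" && aa2 == aa) s <- s + 1 / 3
    }
  }
  s
}

# cached lookup tables -------------------------------------------------------

.codon_cache <- new.env(parent = emptyenv())

syn_sites_table <- function() {
  if (is.null(.codon_cache$S)) {
    cods <- sense_codons()
    .codon_cache$S <- vapply(cods, codon_syn_sites, numeric(1))
  }
  .codon_cache$S
}

# Synonymous/nonsynonymous differences between two sense codons, averaged
# over all substitution orderings (pathways); pathways passing through a
# stop codon are excluded and the average renormalized over the remainder.
# If every pathway is blocked (does not occur for standard-code sense
# pairs at <=2 differences) all pathways are used.
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- switch(length(pos),
    list(pos),
    list(pos, rev(pos)),
    {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    }
  )
  path_counts <- function(order) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- GENETIC_CODE_STD[[cur]]
      a2 <- GENETIC_CODE_STD[[nxt]]
      if (a2 == "*") return(NULL)  # blocked pathway
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, path_counts)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    # fall back to counting through stops rather than failing outright
    res <- lapply(perms, function(order) {
      cur <- c1
      sd <- nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (GENETIC_CODE_STD[[cur]] == GENETIC_CODE_STD[[nxt]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(res))
  }
  mat <- do.call(rbind, res[ok])
  c(sd = mean(mat[, "sd"]), nd = mean(mat[, "nd"]))
}

pair_diffs_cached <- function(c1, c2) {
  key <- paste0(c1, c2)
  val <- .codon_cache[[key]]
  if (is.null(val)) {
    val <- codon_pair_diffs(c1, c2)
    assign(key, val, envir = .codon_cache)
  }
  val
}

#' Nei-Gojobori site and difference counts for an aligned codon pair
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over all substitution pathways,
#' excluding pathways through stop codons). Codons containing a gap
#' character (\code{-}) or an ambiguous base in either sequence are
#' skipped, as are codons that are stops in either sequence.
#'
#' @param seq_a,seq_b Aligned coding sequences (character scalars, equal
#'   length divisible by 3).
#' @return An object of class \code{ng86_counts}: list with \code{S}
#'   (synonymous sites), \code{N} (nonsynonymous sites), \code{Sd},
#'   \code{Nd} (differences) and \code{codons_used}.
#' @export
ng86_counts <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  }
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  usable <- is_sense(ca) & is_sense(cb)
  ca <- ca[usable]
  cb <- cb[usable]
  if (length(ca) == 0L) stop("no usable codons in alignment")
  Stab <- syn_sites_table()
  S <- sum((Stab[ca] + Stab[cb]) / 2)
  Sd <- Nd <- 0
  diff <- which(ca != cb)
  for (i in diff) {
    d <- pair_diffs_cached(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  structure(
    list(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd,
         codons_used = length(ca)),
    class = "ng86_counts"
  )
}

#' Jukes-Cantor-corrected synonymous divergence (Ks)
#'
#' Applies the Jukes-Cantor multiple-hit correction to the proportion of
#' synonymous differences per synonymous site,
#' \code{ks = -(3/4) * log(1 - (4/3) * Sd/S)}. Values with
#' \code{Sd/S >= 3/4} (correction undefined) or \code{ks > ks_max} are
#' flagged saturated.
#'
#' @param counts An \code{ng86_counts} object.
#' @param ks_max Finite Ks values above this are flagged saturated
#'   (default 3, standard practice for Ks-age distributions).
#' @return Object of class \code{ks_value}: list with \code{ks} and
#'   \code{saturated}.
#' @export
ks_jc <- function(counts, ks_max = 3) {
  if (counts$S <= 0) stop("no synonymous sites (S = 0)")
  p_s <- counts$Sd / counts$S
  if (p_s >= 3 / 4) {
    return(structure(list(ks = NA_real_, saturated = TRUE),
                     class = "ks_value"))
  }
  ks <- -(3 / 4) * log(1 - (4 / 3) * p_s)
  structure(list(ks = ks, saturated = ks > ks_max), class = "ks_value")
}

#' Ks for a pair of aligned coding sequences
#'
#' Convenience wrapper: \code{ks_jc(ng86_counts(a, b))}.
#'
#' @inheritParams ng86_counts
#' @param ks_max Saturation cap passed to \code{\link{ks_jc}}.
#' @return A \code{ks_value} object.
#' @export
ks_pair <- function(seq_a, seq_b, ks_max = 3) {
  ks_jc(ng86_counts(seq_a, seq_b), ks_max = ks_max)
}
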
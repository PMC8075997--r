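# Independent oracles, deliberately written differently from the package
# implementation.

# Genetic code from an independent source when available.
oracle_genetic_code <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      gc <<- if (requireNamespace("Biostrings", quietly = TRUE)) {
        x <- Biostrings::GENETIC_CODE
        stats::setNames(as.character(x), names(x))
      } else {
        wgdils:::GENETIC_CODE_STD
      }
    }
    gc
  }
})

# Brute-force NG86 counts for one codon pair: enumerates every ordering of
# the differing positions recursively, drops orderings that pass through a
# stop codon, and averages synonymous/nonsynonymous step counts over the
# remainder. Site counts enumerate all nine point mutations per codon.
oracle_ng86_codon <- function(c1, c2) {
  gc <- oracle_genetic_code()
  nucs <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    tot <- 0
    for (p in 1:3) {
      for (nt in nucs) {
        if (nt == substr(cod, p, p)) next
        alt <- cod
        substr(alt, p, p) <- nt
        if (gc[[alt]] != "*" && gc[[alt]] == gc[[cod]]) tot <- tot + 1
      }
    }
    tot / 3
  }
  paths <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1L]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") next
      walk(nxt, setdiff(remaining, p),
           sd + (gc[[cur]] == gc[[nxt]]), nd + (gc[[cur]] != gc[[nxt]]))
    }
  }
  dif <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  walk(c1, dif, 0, 0)
  stopifnot(length(paths) > 0)
  steps <- colMeans(do.call(rbind, paths))
  list(S = (syn_sites(c1) + syn_sites(c2)) / 2,
       Sd = steps[1], Nd = steps[2])
}

# Exhaustive best chain over a set of anchor points: enumerates every
# strictly monotonic, gap-bounded sequence by depth-first extension and
# returns the top score with its anchors.
oracle_best_chain <- function(rank_a, rank_b, max_gap, gap_penalty,
                              allow_inversions = TRUE) {
  n <- length(rank_a)
  best <- list(score = -Inf, idx = integer(0))
  for (sign_b in if (allow_inversions) c(1, -1) else 1) {
    rb <- sign_b * rank_b
    extend <- function(idx, score) {
      if (score > best$score ||
          (score == best$score && length(idx) > length(best$idx))) {
        best <<- list(score = score, idx = idx,
                      orient = if (sign_b == 1) "+" else "-")
      }
      last <- idx[length(idx)]
      for (j in seq_len(n)) {
        ga <- rank_a[j] - rank_a[last]
        gb <- rb[j] - rb[last]
        if (ga >= 1 && gb >= 1 && ga <= max_gap && gb <= max_gap) {
          extend(c(idx, j),
                 score + 1 - gap_penalty * ((ga - 1) + (gb - 1)))
        }
      }
    }
    for (s in seq_len(n)) extend(s, 1)
  }
  best
}
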
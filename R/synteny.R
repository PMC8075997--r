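# Collinear (syntenic) block detection by gap-constrained chaining of
# homologous anchor pairs in gene-rank space, DAGchainer-style: a sparse
# dynamic program scores chains (one point per anchor minus a small
# per-rank gap penalty), highest-scoring chains are extracted greedily
# without anchor reuse, and chains shorter than min_block are discarded.

#' Chaining parameters for syntenic block detection
#'
#' @param min_block Minimum number of anchor pairs per reported block
#'   (default 10, the usual "at least 10 colinear genes" reporting rule).
#' @param max_gap Maximum gene-rank gap allowed between consecutive
#'   anchors of a chain, on either genome (default 25).
#' @param allow_inversions Allow antiparallel (inverted) chains
#'   (default TRUE).
#' @param gap_penalty Score deducted per skipped gene rank (default
#'   0.01; anchors score 1 each).
#' @return Object of class \code{chain_params}.
#' @export
chain_params <- function(min_block = 10, max_gap = 25,
                         allow_inversions = TRUE, gap_penalty = 0.01) {
  stopifnot(min_block >= 2, max_gap >= 1, gap_penalty >= 0)
  structure(list(min_block = as.integer(min_block),
                 max_gap = as.integer(max_gap),
                 allow_inversions = isTRUE(allow_inversions),
                 gap_penalty = gap_penalty),
            class = "chain_params")
}

# Best chain in one chromosome-pair point set (ra, rb sorted by ra) for a
# given orientation; returns list(score, idx) or NULL.
chain_dp <- function(ra, rb, max_gap, gap_penalty, orient) {
  n <- length(ra)
  if (orient == "-") rb <- -rb
  ord <- order(ra, rb)
  ra <- ra[ord]
  rb <- rb[ord]
  dp <- rep(1, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ga <- ra[i] - ra[j]
      gb <- rb[i] - rb[j]
      if (ga < 1 || gb < 1 || ga > max_gap || gb > max_gap) next
      cand <- dp[j] + 1 - gap_penalty * ((ga - 1) + (gb - 1))
      if (cand > dp[i]) {
        dp[i] <- cand
        prev[i] <- j
      }
    }
  }
  best <- which.max(dp)
  idx <- integer(0)
  cur <- best
  while (!is.na(cur)) {
    idx <- c(cur, idx)
    cur <- prev[cur]
  }
  list(score = dp[best], idx = ord[idx])
}

#' Detect syntenic blocks by anchor chaining
#'
#' Chains anchor pairs within each chromosome pair into maximal-scoring
#' collinear runs. Anchors may belong to at most one block; chains are
#' extracted greedily by score (ties: longer chain, then lexicographic
#' chromosome order). Self-pairs (a gene with itself) are ignored. For a
#' within-genome comparison pass the same genome twice; each unordered
#' anchor pair is then used once, in canonical orientation.
#'
#' @param anchors data.frame with columns gene_a, gene_b (a score column
#'   is permitted and ignored: every anchor scores 1).
#' @param genome_a,genome_b \code{annotated_genome} objects (identical
#'   for a self-comparison).
#' @param params A \code{\link{chain_params}} object.
#' @return Object of class \code{syntenic_blocks}: list of blocks, each
#'   with genome and chromosome names, orientation, and an \code{anchors}
#'   data.frame (gene_a, gene_b, rank_a, rank_b) ordered along genome a.
#' @export
chain_anchors <- function(anchors, genome_a, genome_b,
                          params = chain_params()) {
  stopifnot(inherits(params, "chain_params"))
  pos_a <- gene_positions(genome_a)
  pos_b <- gene_positions(genome_b)
  self_cmp <- identical(genome_a$species, genome_b$species)
  lookup <- function(tab, genes, side) {
    i <- match(genes, tab$gene)
    if (anyNA(i)) {
      stop("anchor gene not present in genome ", side, ": ",
           paste(unique(genes[is.na(i)]), collapse = ", "))
    }
    tab[i, c("chrom", "rank")]
  }
  a <- anchors[anchors$gene_a != anchors$gene_b, , drop = FALSE]
  if (nrow(a) == 0) return(structure(list(), class = "syntenic_blocks"))
  if (self_cmp) {
    # canonical order so each unordered pair appears once
    pa <- lookup(pos_a, a$gene_a, "a")
    pb <- lookup(pos_a, a$gene_b, "b")
    flip <- pa$chrom > pb$chrom | (pa$chrom == pb$chrom & pa$rank > pb$rank)
    tmp <- a$gene_a[flip]
    a$gene_a[flip] <- a$gene_b[flip]
    a$gene_b[flip] <- tmp
    a <- a[!duplicated(a[, c("gene_a", "gene_b")]), , drop = FALSE]
  }
  pa <- lookup(pos_a, a$gene_a, "a")
  pb <- lookup(pos_b, a$gene_b, "b")
  pts <- data.frame(gene_a = a$gene_a, gene_b = a$gene_b,
                    chrom_a = pa$chrom, rank_a = pa$rank,
                    chrom_b = pb$chrom, rank_b = pb$rank,
                    stringsAsFactors = FALSE)
  groups <- split(pts, paste(pts$chrom_a, pts$chrom_b, sep = "\r"))
  blocks <- list()
  for (g in groups[order(names(groups))]) {
    avail <- rep(TRUE, nrow(g))
    repeat {
      sub <- g[avail, , drop = FALSE]
      if (nrow(sub) < 2) break
      orients <- if (params$allow_inversions) c("+", "-") else "+"
      best <- NULL
      for (o in orients) {
        res <- chain_dp(sub$rank_a, sub$rank_b, params$max_gap,
                        params$gap_penalty, o)
        if (is.null(best) || res$score > best$score ||
            (res$score == best$score &&
               length(res$idx) > length(best$idx))) {
          best <- res
          best$orient <- o
        }
      }
      if (length(best$idx) < 2) break
      chain <- sub[best$idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- structure(
        list(genome_a = genome_a$species, genome_b = genome_b$species,
             chromosome_a = chain$chrom_a[1],
             chromosome_b = chain$chrom_b[1],
             orientation = best$orient, score = best$score,
             anchors = data.frame(gene_a = chain$gene_a,
                                  gene_b = chain$gene_b,
                                  rank_a = chain$rank_a,
                                  rank_b = chain$rank_b,
                                  stringsAsFactors = FALSE),
             ks_values = NULL, median_ks = NA_real_),
        class = "syntenic_block")
      avail[avail][best$idx] <- FALSE
    }
  }
  keep <- vapply(blocks, function(b) nrow(b$anchors) >= params$min_block,
                 logical(1))
  blocks <- blocks[keep]
  if (length(blocks) > 1) {
    sizes <- vapply(blocks, function(b) nrow(b$anchors), integer(1))
    keyf <- vapply(blocks, function(b)
      paste(b$chromosome_a, b$chromosome_b, min(b$anchors$rank_a)),
      character(1))
    blocks <- blocks[order(-sizes, keyf)]
  }
  structure(blocks, class = "syntenic_blocks")
}

#' @export
print.syntenic_blocks <- function(x, ...) {
  cat("Syntenic blocks:", length(x), "\n")
  for (b in utils::head(x, 10)) {
    cat(sprintf("  %s:%s ~ %s:%s [%s] %d anchors, median Ks %s\n",
                b$genome_a, b$chromosome_a, b$genome_b, b$chromosome_b,
                b$orientation, nrow(b$anchors),
                ifelse(is.na(b$median_ks), "-",
                       sprintf("%.3f", b$median_ks))))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Syntenic depth histogram and modal depth ratio
#'
#' Tiles the target genome in windows of \code{window} gene ranks, counts
#' how many syntenic blocks cover each window, and reports the modal
#' nonzero coverage in each direction as a depth ratio (for example 2:1
#' after one unshared whole-genome duplication).
#'
#' @param blocks \code{syntenic_blocks} between exactly two genomes.
#' @param target Name of the target genome.
#' @param window Window size in gene ranks (default 20).
#' @return List with \code{histogram} (table of per-window coverage on
#'   the target), \code{modal} (modal nonzero coverage on the target) and
#'   \code{ratio}, a named ratio other:target of modal depths.
#' @export
syntenic_depth <- function(blocks, target, window = 20) {
  if (length(blocks) == 0) stop("empty block list")
  gens <- unique(unlist(lapply(blocks, function(b)
    c(b$genome_a, b$genome_b))))
  if (!(target %in% gens)) stop("no blocks involve target '", target, "'")
  other <- setdiff(gens, target)
  if (length(other) != 1) {
    stop("blocks must involve the target and exactly one other genome")
  }
  cover_counts <- function(tgt) {
    spans <- list()
    for (b in blocks) {
      sides <- c(b$genome_a, b$genome_b)
      for (s in which(sides == tgt)) {
        rk <- if (s == 1) b$anchors$rank_a else b$anchors$rank_b
        ch <- if (s == 1) b$chromosome_a else b$chromosome_b
        spans[[length(spans) + 1L]] <- c(ch, min(rk), max(rk))
      }
    }
    sp <- data.frame(chrom = vapply(spans, `[`, character(1), 1),
                     lo = as.numeric(vapply(spans, `[`, character(1), 2)),
                     hi = as.numeric(vapply(spans, `[`, character(1), 3)),
                     stringsAsFactors = FALSE)
    counts <- integer(0)
    for (ch in unique(sp$chrom)) {
      s <- sp[sp$chrom == ch, , drop = FALSE]
      top <- max(s$hi)
      starts <- seq(0, top, by = window)
      cnt <- vapply(starts, function(w0)
        sum(s$lo <= w0 + window - 1 & s$hi >= w0), integer(1))
      counts <- c(counts, cnt)
    }
    counts
  }
  ct <- cover_counts(target)
  co <- cover_counts(other)
  modal <- function(x) {
    x <- x[x > 0]
    if (length(x) == 0) return(0L)
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])
  }
  ratio <- c(modal(ct), modal(co))
  names(ratio) <- c(other, target)
  list(histogram = table(ct), modal = modal(ct), ratio = ratio)
}
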